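# mintkit

Computational toolkit for interrogating a neuronal protein interactome
around the Mint (X11/APBA) adaptor proteins and their partner Munc18-1,
combining three pipelines that structural cell-biology labs increasingly
run side by side:

1. **ITC binding thermodynamics** — simulate and fit one-site (1:1)
   isothermal titration calorimetry isotherms and derive the full
   thermodynamic signature of an interaction.
2. **Predicted-complex triage** — turn bundles of AlphaFold2-Multimer
   models of candidate protein pairs into direct-interactor verdicts from
   iPTM scores, inter-chain PAE statistics, cross-model structural
   consistency and interface contact chemistry.
3. **Vesicle-fusion event detection** — detect completed
   pHluorin-unquenching exocytosis events in TIRF movies and compare
   per-cell event densities between conditions nonparametrically.

Every pipeline ships with a seeded synthetic-data generator carrying
machine-readable ground truth, so the whole package builds and tests with
no external data.

## The models

**One-site isotherm.** For total cell-species concentration $M_t$ with $n$
binding sites and total titrant $X_t$, the bound complex concentration is
the physical root of

$$[MX]^2 - (nM_t + X_t + K_d)\,[MX] + nM_t X_t = 0,$$

solved exactly after each injection under the displaced-volume
(perfusion) dilution convention. The heat of injection $i$ is
$q_i = \Delta H \cdot V_0 \cdot \Delta[MX]_i$; least squares over
$(K_d, n, \Delta H)$ is by Levenberg–Marquardt with a multi-start
initialisation. Derived quantities use
$\Delta G = RT\ln K_d$ (with $R = 1.9872\times10^{-3}$ kcal mol⁻¹ K⁻¹) and
$-T\Delta S = \Delta G - \Delta H$, which hold to machine precision by
construction in every fit.

**Triage.** A candidate pair is promoted to `interactor_candidate` when
its across-model mean iPTM is at least 0.3 **and** the pooled off-diagonal
(inter-chain) PAE blocks show a genuine signal (minimum ≤ 10 Å and at
least 1% of entries below 10 Å); all thresholds are configurable.
Cross-model consistency is the median candidate-chain backbone RMSD after
Kabsch superposition on the bait backbone; interface contacts within
4.0 Å are classified hydrophobic / polar (N/O–N/O ≤ 3.5 Å) /
electrostatic (Asp/Glu carboxylate O to Arg/Lys/His side-chain N ≤ 4 Å).

**Fusion events.** Movies (10 Hz, 106 nm pixels) are averaged in
100-frame intervals; puncta are strict local maxima of the
scale-normalised Laplacian-of-Gaussian response; detections are clustered
over $[x, y, t]$ with an anisotropic Chebyshev neighbourhood
(|Δx|,|Δy| ≤ 1 px, |Δt| ≤ 2 intervals, ≥ 3 puncta per cluster); a cluster
that disappears before the final interval is a completed fusion event.
Groups of per-cell densities (events/µm²) are compared with a
Mann–Whitney U test (exact p when $n_a n_b \le 400$ without ties).

## Worked example

```r
library(mintkit)

# a peptide-into-protein titration: 0.7 mM into 50 uM, 20 x 2 uL at 25 C
prot <- itc_protocol()
iso  <- simulate_isotherm(kd = 16.3e-6, n = 1, dh = -8.8, prot,
                          noise_sd = 0.3, seed = 1)
fit  <- itc_fit(iso)
fit
#> One-site ITC binding fit
#>   Kd        = 16.75 uM (se 2.7)
#>   n         = 0.956 (se 0.051)
#>   dH        = -9.093 kcal/mol (se 0.67)
#>   -TdS      = 2.577 kcal/mol
#>   dG        = -6.516 kcal/mol at 298.15 K
```

The fitted Kd of ~16 µM and ΔG of −6.5 kcal/mol recover the generating
parameters; the modest unfavourable −TΔS against a larger favourable ΔH
is the signature of an induced-folding peptide interaction.

```r
# triage a synthetic 3-model bundle with a confidently docked helix
g <- gen_prediction_bundle(triage_scenario(seed = 1))
triage(g$bundle)
#> Triage of 'synthetic_pair': INTERACTOR_CANDIDATE
#>   mean iPTM 0.600 | min inter-chain PAE 5.00 A | frac < 10 A: 1.000
#>   consistency RMSD 0.00 A | 9 interface contacts (3 hydrophobic, 5 polar, 1 electrostatic)

# detect fusion events in a synthetic 300 s TIRF movie
gm  <- gen_movie(random_fusion_schedule(n_events = 10, seed = 7),
                 stimulation_frame = 1L)
res <- detect_fusion_events(gm$movie)
res
#> Fusion-event detection: 164 puncta -> 12 clusters (0 noise puncta)
#>   completed events: 10 | ongoing at end: 2 | intervals: 30
```

All ten scheduled fusion events are recovered and the two persisting
docked vesicles are correctly left uncalled.

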