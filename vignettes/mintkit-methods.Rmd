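---
title: "Models and methods behind mintkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mintkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mintkit)
```

mintkit bundles three pipelines that together support the dissection of a
protein interactome: quantitative binding thermodynamics by isothermal
titration calorimetry (ITC), screening of AlphaFold2-Multimer complex
predictions into direct-interactor verdicts, and detection of vesicle
fusion events in TIRF footage of neurosecretory cells. This vignette
explains the underlying models, the parameters that matter, the numerical
choices, what the synthetic-data generators do and do not emulate, and the
package's known limitations.

## One-site ITC model

### Forward model

An ITC experiment titrates a syringe species (here typically a peptide at
0.7 mM) into a cell species (a protein at 50 µM) and integrates the heat
of each injection. For the 1:1 scheme $M + X \rightleftharpoons MX$ with
stoichiometry $n$ sites per cell-species molecule, the bound concentration
after each injection is the physical root of

$$[MX]^2 - (nM_t + X_t + K_d)[MX] + nM_t X_t = 0,$$

evaluated in the numerically stable form
$[MX] = 2nM_tX_t\,/\,(b + \sqrt{b^2 - 4nM_tX_t})$ with
$b = nM_t + X_t + K_d$, which avoids catastrophic cancellation in the
tight-binding regime.

**Dilution convention.** Injecting volume $v$ into a constant-volume cell
$V_0$ displaces an equal volume of instantaneously mixed contents. We use
the per-injection perfusion bookkeeping: existing total concentrations are
diluted by $V_0/(V_0+v)$ and the injected species arrives at
$c_{syr}\,v/(V_0+v)$. The convention is recorded in every fit report,
because commercial packages differ in this detail and the choice shifts
late-titration heats by a few percent. The heat of injection $i$ is

$$q_i = \Delta H \cdot V_0\cdot\big([MX]_i - d_i\,[MX]_{i-1}\big) + q_0,$$

where $d_i$ is the dilution factor and $q_0$ an optional constant
heat-of-dilution offset (off by default, fittable with `fit_offset =
TRUE`; a first-injection discard flag is likewise available and off by
default, since neither correction is universal practice).

The forward model is verified against an independent equilibrium solver
that bisects on the free-ligand concentration; the two routes agree to
better than $10^{-6}$ relative across randomized parameter sets.

### Fitting

`itc_fit()` minimises squared residuals in heat with Levenberg–Marquardt
on $(\log K_d, \log n, \Delta H)$, making the positivity constraints
implicit. Initialisation uses $n = 1$, $\Delta H$ from the first-injection
heat under the complete-binding assumption, and $K_d$ from the
half-saturation point of the cumulative heat; because the likelihood
surface can be flat in $K_d$ at extreme c-values
($c = n[M]/K_d$), the heuristic start is complemented by a log-spaced
ladder of $K_d$ starts ($10^{-8}$–$10^{-4}$ M) and the best multi-start
solution is kept. Noiseless round trips recover $(K_d, n, \Delta H)$ to
0.1% for $c$ between 1 and 1000, which covers the practically fittable
range; at 2% heat noise the median $K_d$ error across replicates stays
below 10%.

Standard errors come from the Gauss–Newton curvature
$s^2 (J^\top J)^{-1}$ with a central finite-difference Jacobian on the
natural parameter scale. Degenerate data (all-zero heats) yield
`converged = FALSE` with $\Delta H \approx 0$ rather than an error, so
screening loops over many titrations never abort.

### Thermodynamic identities and published-table checks

$\Delta G = RT\ln(K_d/1\,\mathrm{M})$ with
$R = 1.9872\times 10^{-3}$ kcal mol⁻¹ K⁻¹ and
$-T\Delta S = \Delta G - \Delta H$ are populated in every fit, so the
identities hold to $10^{-9}$ kcal/mol by construction. All experiments the
package's bundled reference table describes were run at 25 °C, so
298.15 K is the default temperature everywhere.

Published thermodynamic tables sometimes contain rows whose printed
$\Delta G$ cannot be reconciled with the printed $K_d$ (transcription or
unit slips). `check_dg_consistency()` recomputes $\Delta G$ from each
$K_d$ and flags rows deviating by more than 0.05 kcal/mol — printed
precision — rather than forcing or silently correcting them; in the
bundled table exactly three rows are flagged, and one further row fails
the enthalpy–entropy identity beyond its printed uncertainties
(`check_entropy_consistency()`). Flagged rows are excluded from exact
numerical comparisons and surfaced to the user.

## Predicted-complex triage

### Gating evidence

Screening many candidate pairs with AlphaFold2-Multimer produces, per
pair, a handful of ranked models each carrying an iPTM score, a
per-residue-pair PAE matrix and per-residue pLDDT. Practitioners promote
a pair when the average iPTM is useful (~0.3) *and* the PAE plot shows an
off-diagonal (inter-chain) signal. "Strong signal" is a visual judgment;
mintkit operationalises it as **minimum inter-chain PAE ≤ 10 Å with at
least 1% of inter-chain entries below 10 Å**, both configurable, so the
manual step can be mimicked or tightened. The iPTM gate applies to the
across-model mean (a per-model gate is available via
`triage_thresholds(per_model_iptm = TRUE)`), and PAE matrices are treated
as asymmetric with both off-diagonal blocks pooled — which also makes the
statistics invariant to swapping the bait/candidate labels.

Two further lines of evidence are computed but deliberately *not* gated,
mirroring the two-stage screen-then-inspect workflow: cross-model
consistency and interface contact chemistry. pLDDT is reported but not
gated either, since interface confidence is already captured by iPTM/PAE.

### Consistency and contacts

`model_consistency()` superposes every model pair on the bait-chain
alpha-carbons (one designated reference atom per residue; residues
missing it in either model are skipped) using the Kabsch algorithm —
SVD of the centred covariance with the determinant sign fixed so the
rotation is always proper — then measures the candidate-chain
alpha-carbon RMSD without further fitting, and returns the **median over
pairs**, robust to one divergent model among three. Contacts within
4.0 Å (heavy atoms) are classified electrostatic (Asp/Glu carboxylate O
within 4.0 Å of Arg/Lys/His side-chain N), polar (N/O–N/O ≤ 3.5 Å) or
hydrophobic (carbon–carbon only) — standard structural-biology cutoffs.
Author residue numbering from the input files is preserved; internal
bookkeeping maps (chain, residue) to contiguous PAE indices explicitly.

### Synthetic bundles

`gen_prediction_bundle()` writes per-rank PDB and score-JSON files for an
idealized receptor (a gently curved extended backbone with a repeating
ALA/LEU/LYS/SER/GLU chemistry) and an acidic α-helical partner docked
against it, emulating the helix-on-domain motif geometry typical of
peptide-motif complexes. Docking is adaptive: the helix is nudged until
the closest inter-chain approach sits in the contact range (~3.5 Å), and
generation fails if perturbed chains clash. Synthetic PAE matrices use a
distance-independent constant per block — the simplest structure
satisfying the triage contracts — with a smooth-decay mode for realism
testing. These bundles exercise the readers, the metrics and the verdict
logic; they do not emulate the confidence *statistics* of real AlphaFold
output (pLDDT gradients, PAE texture), so passing tests demonstrate
correct plumbing and arithmetic, not a validated screen of real
predictions.

## Fusion-event detection

### Pipeline

A 300 s acquisition at 10 Hz (3000 frames, 106 nm pixels) is divided into
100-frame intervals and each interval averaged, boosting spot SNR
tenfold against uncorrelated noise while retaining 10 s time resolution.
Puncta are strict 8-neighbourhood local maxima of the scale-normalised
Laplacian-of-Gaussian response at σ = 1.5 px (a diffraction-limited spot
at this pixel size), thresholded at 5 robust (MAD-based) standard
deviations of the response by default — both configurable, since neither
parameter is universal. The LoG kernel is explicitly zero-sum, so a
global intensity offset changes nothing, exactly.

Detections populate an $[x, y, t]$ array with $t$ in interval units and
are clustered density-wise: two puncta are neighbours iff
$|\Delta x| \le 1$, $|\Delta y| \le 1$ **and** $|\Delta t| \le 2$
intervals — the anisotropic Chebyshev box reading of "within one pixel
spatially and two temporally", chosen because it is reproducible without
a metric-scaling convention (a scaled-Euclidean mode exists behind
`detection_config(neighborhood = "euclidean")`). The temporal unit is the
*interval*, since the array's time axis is interval-indexed; clusters are
connected components of the neighbour graph, and components with fewer
than 3 puncta are discarded as noise (a docked vesicle should persist a
few intervals to be credible; `min_cluster_size = 1` disables the
filter). A cluster whose last interval precedes the final one is a
**completed fusion event** with event time at the end of that interval;
clusters alive at the end of the acquisition are ongoing and excluded.

Completed events feed a 10 s-binned cumulative release series (bins
labelled 0–290 s for a 300 s movie) and per-cell evoked densities:
completed events at or after the stimulation time divided by the
footprint area (one 106 nm pixel = 0.011236 µm²). The footprint default
is an Otsu threshold on the time-mean image with largest-component
selection; synthetic movies have no cell outline, so tests pass explicit
masks, and how a real footprint is delineated remains a user decision.
Groups are compared with a Mann–Whitney U test: midrank ties, exact
enumeration p when $n_a n_b \le 400$ without ties, otherwise the normal
approximation with tie and continuity corrections.

The pipeline contains no randomness: identical movie and configuration
give identical events.

### Synthetic movies and what they show

`gen_movie()` renders scheduled Gaussian spots (σ = 1.5 px) on a constant
background with seeded Gaussian (bit-reproducible) or Poisson noise, and
returns ground truth listing the scheduled completed events.
`random_fusion_schedule()` keeps spot centres at least 8 px apart, aligns
lifetimes to interval boundaries, enforces a minimum 3-interval lifetime
and leaves the final interval clear, so scheduled truth and detectable
truth coincide. At SNR 5 (peak over frame noise) the interval-averaged
spots stand ~25 response-sd above the detection threshold and recall and
precision are essentially perfect. Real recordings are harder in every
respect the generator omits: photobleaching, drift, uneven illumination,
vesicles closer than the separation floor, partial-interval lifetimes and
camera-specific noise. Passing the synthetic benchmarks therefore
validates the arithmetic of the pipeline, not its performance envelope on
difficult data.

Problem sizes used by the test-suite benchmarks are the package's own
choices: the detection benchmark runs twenty full-scale movies
(128 × 128 px, 3000 frames); the two-condition cohort study emulates a
rescue experiment with 15 vs 17 cells whose scheduled event rates differ
by 40% (Poisson means 12 vs 7.2 per cell), each cell a compact
64 × 64 px, 400-frame movie averaged in 40-frame intervals so that whole
cohorts of full pipeline runs complete in seconds. The measured group
difference tracks the generative 40% and the Mann–Whitney test rejects at
p < 0.05 in essentially all repetitions at these effect sizes.

## Design choices and limitations

* **Modelling idiom.** The ITC stage is the package's estimator core:
  `itc_fit()` returns a classed object with `print`, `summary`, `coef`,
  `predict`, `residuals`, `plot`, `simulate` and `vcov` methods. Triage
  and fusion detection are deterministic pipelines returning classed
  result objects rather than fitted models.
* **Out of scope.** Multi-site/competitive ITC models and raw power-trace
  integration; running structure prediction or MSA generation;
  energy-based interface scoring; particle tracking beyond density
  clustering, photobleaching correction and super-resolution analysis.
* **Known sensitivities.** The triage thresholds encode a visual
  judgment and should be treated as a screening prior, not a
  significance test; the fusion temporal-neighbourhood unit (intervals,
  not frames) matters for closely spaced events at the same location;
  the Mann–Whitney exact/approximate switch follows group sizes and
  ties, so p-values for large tied datasets are approximate.
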