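# Seeded synthetic isotherms carrying their generating truth.

#' Generate a noisy isotherm with known ground truth
#'
#' Thin seeded wrapper around [simulate_isotherm()] that returns the
#' generating parameters alongside the data, for parameter-recovery
#' studies. With `noise_sd = 0` the result equals the noiseless forward
#' model exactly.
#'
#' @param kd,n,dh True one-site parameters (molar, unitless, kcal/mol).
#' @param protocol An [itc_protocol()]; the default mirrors a
#'   peptide-into-protein titration (0.7 mM into 50 uM).
#' @param noise_sd Gaussian heat noise in ucal (default 0).
#' @param seed Integer seed (default 1).
#' @return List with `isotherm` (an [isotherm()]) and `truth`
#'   (list `kd`, `n`, `dh`).
#' @export
gen_isotherm <- function(kd, n, dh, protocol = itc_protocol(),
                         noise_sd = 0, seed = 1L) {
  iso <- simulate_isotherm(kd, n, dh, protocol, noise_sd = noise_sd,
                           seed = seed)
  list(isotherm = iso, truth = list(kd = kd, n = n, dh = dh))
}
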