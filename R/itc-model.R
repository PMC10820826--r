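# One-site (1:1) binding isotherm forward model.
#
# For each post-injection composition the single-site equilibrium
#   M + X <-> MX,  Kd = [M][X]/[MX]
# with n binding sites per cell-species molecule is solved exactly from the
# quadratic in the bound-complex concentration:
#   [MX]^2 - (n*Mt + Xt + Kd)*[MX] + n*Mt*Xt = 0
# taking the physical root (the smaller one, which lies in
# [0, min(n*Mt, Xt)]). The heat of injection i is the enthalpy times the
# change in bound-complex moles in the cell, accounting for the bound
# complex carried over from injection i-1 after displaced-volume dilution.

# Physical root of the bound-complex quadratic, numerically stable form.
one_site_bound <- function(m_sites, x_total, kd) {
  b <- m_sites + x_total + kd
  disc <- b * b - 4 * m_sites * x_total
  disc[disc < 0] <- 0  # guard tiny negative from roundoff
  2 * m_sites * x_total / (b + sqrt(disc))
}

# Noiseless per-injection heats (ucal) for one-site binding parameters.
one_site_heats <- function(kd, n, dh, protocol, offset = 0) {
  comp <- cell_composition(protocol)
  mx <- one_site_bound(n * comp$m_total, comp$x_total, kd)
  prev <- c(0, mx[-length(mx)])
  d_bound <- mx - prev * comp$dilution
  # kcal/mol * L * mol/L = kcal; 1 kcal = 1e9 ucal
  dh * 1e9 * protocol$cell_volume * d_bound + offset
}

#' Simulate a one-site ITC binding isotherm
#'
#' Forward-simulates the integrated injection heats of a 1:1 (single-site)
#' binding experiment under the displaced-volume dilution convention, with
#' optional zero-mean Gaussian noise. The equilibrium at each post-injection
#' composition is solved exactly (quadratic root); the per-injection heat is
#' the enthalpy times the change in bound-complex moles in the cell.
#'
#' @param kd Dissociation constant in molar (> 0).
#' @param n Binding stoichiometry (sites per cell-species molecule, > 0).
#' @param dh Binding enthalpy in kcal/mol.
#' @param protocol An [itc_protocol()].
#' @param noise_sd Standard deviation of additive Gaussian noise on each
#'   heat, in microcalories (>= 0).
#' @param seed Optional integer seed fixing the noise draw.
#' @param offset Constant per-injection heat-of-dilution offset in
#'   microcalories (default 0).
#' @return An [isotherm()] whose `heats` are in microcalories.
#' @examples
#' prot <- itc_protocol()
#' iso <- simulate_isotherm(kd = 5e-6, n = 1, dh = -10, prot)
#' plot(iso$molar_ratios, iso$heats)
#' @export
simulate_isotherm <- function(kd, n, dh, protocol, noise_sd = 0, seed = NULL,
                              offset = 0) {
  stopifnot(inherits(protocol, "itc_protocol"))
  if (!is.numeric(kd) || length(kd) != 1L || !is.finite(kd) || kd <= 0)
    stop("kd must be a single strictly positive molar concentration")
  if (!is.numeric(n) || length(n) != 1L || !is.finite(n) || n <= 0)
    stop("stoichiometry n must be a single strictly positive number")
  if (!is.numeric(dh) || length(dh) != 1L || !is.finite(dh))
    stop("dh must be a single finite enthalpy in kcal/mol")
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop("noise_sd must be a single non-negative number")
  q <- one_site_heats(kd, n, dh, protocol, offset)
  if (noise_sd > 0) {
    if (!is.null(seed)) set.seed(seed)
    q <- q + stats::rnorm(length(q), sd = noise_sd)
  }
  isotherm(protocol, q)
}
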