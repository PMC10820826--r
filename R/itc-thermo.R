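# Thermodynamic identities used throughout: dG = RT ln(Kd / 1 M) and
# dG = dH + (-TdS), with the gas constant in kcal.

#' @keywords internal
GAS_CONSTANT_KCAL <- 1.9872e-3  # kcal mol^-1 K^-1

#' Gibbs free energy of binding from a dissociation constant
#'
#' Computes `dG = RT * ln(kd / 1 M)` with
#' `R = 1.9872e-3 kcal mol^-1 K^-1`. Negative for sub-molar Kd, zero at the
#' 1 M standard state.
#'
#' @param kd Dissociation constant(s) in molar (> 0); vectorised.
#' @param temperature Absolute temperature in kelvin (default 298.15 K,
#'   i.e. 25 C).
#' @return Free energy in kcal/mol.
#' @examples
#' delta_g_from_kd(16.3e-6)  # ~ -6.53 kcal/mol at 25 C
#' @export
delta_g_from_kd <- function(kd, temperature = 298.15) {
  if (!is.numeric(kd) || any(!is.finite(kd)) || any(kd <= 0))
    stop("kd must be strictly positive (molar)")
  if (!is.numeric(temperature) || any(temperature <= 0))
    stop("temperature must be positive (kelvin)")
  GAS_CONSTANT_KCAL * temperature * log(kd)
}

#' Entropic term of binding
#'
#' Returns `-TdS = dG - dH`, the entropy contribution reported alongside
#' ITC fits.
#'
#' @param dg Free energy in kcal/mol.
#' @param dh Enthalpy in kcal/mol.
#' @return `-TdS` in kcal/mol; vectorised.
#' @export
entropy_term <- function(dg, dh) {
  stopifnot(is.numeric(dg), is.numeric(dh))
  dg - dh
}

#' Fold change in dissociation constant
#'
#' Ratio of a perturbed Kd to a reference Kd, e.g. the fold weakening of an
#' interaction caused by a competing ligand. Accepts fitted models
#' ([itc_fit()] objects, which must have converged) or bare molar Kd values.
#'
#' @param reference Reference condition: an `itc_fit` or a molar Kd.
#' @param perturbed Perturbed condition, same types.
#' @return `kd_perturbed / kd_reference` (dimensionless).
#' @examples
#' fold_change_kd(7.9e-9, 269e-9)  # ~ 34
#' @export
fold_change_kd <- function(reference, perturbed) {
  kd_of <- function(x, role) {
    if (inherits(x, "itc_fit")) {
      if (!x$converged)
        stop(sprintf("%s fit has not converged; fold change undefined", role))
      x$kd
    } else if (is.numeric(x) && length(x) == 1L) {
      x
    } else stop(sprintf("%s must be an itc_fit or a single molar Kd", role))
  }
  kref <- kd_of(reference, "reference")
  kper <- kd_of(perturbed, "perturbed")
  if (!is.finite(kref) || kref <= 0)
    stop("reference kd must be strictly positive")
  kper / kref
}

#' Published one-site binding thermodynamics reference table
#'
#' Returns the package's bundled table of published one-site ITC results for
#' the Mint/Munc18-1 system (Mint peptides binding Munc18-1, allosteric
#' competition between Mint1 and Syntaxin1a, and Mint1 PTB domain binding to
#' TJAP1/APP peptides), as printed: Kd (uM), stoichiometry, dH, -TdS and dG
#' (kcal/mol) with their stated uncertainties where given. Rows where no
#' binding was detected carry `NA` thermodynamics.
#'
#' @return A data.frame with one row per titration.
#' @seealso [check_dg_consistency()]
#' @export
binding_reference_table <- function() {
  path <- system.file("extdata", "binding_thermo_tables.csv",
                      package = "mintkit")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  tab
}

#' Flag internally inconsistent printed thermodynamic rows
#'
#' Published thermodynamic tables occasionally contain rows whose printed
#' dG disagrees with `RT ln(Kd)` computed from the printed Kd (transcription
#' or unit slips). This function recomputes dG from each Kd at the given
#' temperature and flags rows whose printed dG deviates by more than `tol`.
#' Flagged rows should be excluded from any exact numerical comparison and
#' reported, not silently corrected.
#'
#' @param table A data.frame with columns `kd_um` and `dg` (as from
#'   [binding_reference_table()]).
#' @param temperature Kelvin (default 298.15).
#' @param tol Allowed absolute deviation in kcal/mol (default 0.05, i.e.
#'   printed-precision agreement).
#' @return The table with added columns `dg_computed` and `dg_consistent`
#'   (`NA` where Kd or dG is missing).
#' @export
check_dg_consistency <- function(table, temperature = 298.15, tol = 0.05) {
  stopifnot(is.data.frame(table), all(c("kd_um", "dg") %in% names(table)))
  dgc <- rep(NA_real_, nrow(table))
  ok <- !is.na(table$kd_um) & table$kd_um > 0
  dgc[ok] <- delta_g_from_kd(table$kd_um[ok] * 1e-6, temperature)
  table$dg_computed <- dgc
  table$dg_consistent <- ifelse(is.na(dgc) | is.na(table$dg), NA,
                                abs(dgc - table$dg) <= tol)
  table
}

#' Flag printed rows violating the entropy identity
#'
#' Checks `dG - (dH + (-TdS)) = 0` on printed table rows, allowing for the
#' precision the three quantities were rounded to plus any printed
#' uncertainties. As with [check_dg_consistency()], violating rows are
#' flagged for exclusion and reporting, never silently adjusted.
#'
#' @param table A data.frame with columns `dg`, `dh`, `mtds` and (optionally)
#'   `dg_unc`, `dh_unc`, `mtds_unc`.
#' @param rounding Allowance for printed rounding of the three values,
#'   kcal/mol (default 0.06).
#' @return The table with added columns `identity_residual`,
#'   `identity_tol` and `identity_consistent`.
#' @export
check_entropy_consistency <- function(table, rounding = 0.06) {
  stopifnot(is.data.frame(table),
            all(c("dg", "dh", "mtds") %in% names(table)))
  unc <- function(col) {
    if (col %in% names(table)) ifelse(is.na(table[[col]]), 0, table[[col]])
    else 0
  }
  resid <- table$dg - (table$dh + table$mtds)
  tol <- rounding + unc("dg_unc") + unc("dh_unc") + unc("mtds_unc")
  table$identity_residual <- resid
  table$identity_tol <- tol
  table$identity_consistent <- ifelse(is.na(resid), NA,
                                      abs(resid) <= tol + 1e-9)
  table
}
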