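# Nonlinear least-squares fit of the one-site binding isotherm.
#
# The optimiser works on (log Kd, log n, dH[, offset]) so the positivity
# constraints are built into the parameterisation; standard errors are
# reported on the natural scale from the local curvature of the residual
# surface (Gauss-Newton approximation with a finite-difference Jacobian).

#' Fit a one-site binding model to an ITC isotherm
#'
#' Least-squares estimation of the dissociation constant `kd`, stoichiometry
#' `n` and binding enthalpy `dh` of the 1:1 binding scheme, minimising the
#' squared residuals against the noiseless forward model of
#' [simulate_isotherm()]. The free energy `dg = RT ln(kd)` and entropic term
#' `-TdS = dg - dh` are populated from the estimates, so the identities
#' `dg = dh + minus_tds` and `dg = RT ln(kd)` hold to machine precision by
#' construction.
#'
#' Fitting uses Levenberg-Marquardt ([minpack.lm::nls.lm]) from a heuristic
#' start (`n = 1`, `dh` from the first-injection heat assuming complete
#' binding, `kd` from the half-saturation point of the observed curve)
#' plus a log-spaced ladder of alternative `kd` starts; the best of the
#' multi-start solutions is kept. A failed or degenerate optimisation is
#' reported via `converged = FALSE`, never as an error.
#'
#' @param iso An [isotherm()] with at least 5 injections.
#' @param start Optional named list with any of `kd` (molar), `n`, `dh`
#'   (kcal/mol) overriding the automatic initial guess.
#' @param fit_offset Also fit a constant per-injection heat-of-dilution
#'   offset (default `FALSE`).
#' @param discard_first Drop the first injection before fitting (a common
#'   instrument practice; default `FALSE`).
#' @return An object of class `itc_fit` with components `kd` (molar), `n`,
#'   `dh`, `dg`, `minus_tds` (kcal/mol), `offset` (ucal), `se` (named
#'   standard errors), `converged`, `fitted`, `residuals`, `isotherm`,
#'   `dilution_convention` and `temperature`.
#' @examples
#' iso <- simulate_isotherm(kd = 5e-6, n = 1, dh = -10, itc_protocol())
#' fit <- itc_fit(iso)
#' coef(fit)
#' @export
itc_fit <- function(iso, start = NULL, fit_offset = FALSE,
                    discard_first = FALSE) {
  stopifnot(inherits(iso, "isotherm"))
  prot <- iso$protocol
  heats <- iso$heats
  keep <- seq_along(heats)
  if (discard_first) keep <- keep[-1]
  if (length(keep) < 5L)
    stop("one-site fitting needs at least 5 usable injections")

  model_heats <- function(kd, n, dh, offset) {
    one_site_heats(kd, n, dh, prot, offset)[keep]
  }
  obs <- heats[keep]

  result <- list(
    kd = NA_real_, n = NA_real_, dh = NA_real_, dg = NA_real_,
    minus_tds = NA_real_, offset = 0,
    se = c(kd = NA_real_, n = NA_real_, dh = NA_real_),
    converged = FALSE, fitted = rep(NA_real_, length(heats)),
    residuals = rep(NA_real_, length(heats)),
    isotherm = iso, discard_first = discard_first,
    fit_offset = fit_offset,
    dilution_convention = "displaced-volume (perfusion)",
    temperature = prot$temperature
  )
  class(result) <- "itc_fit"

  # Degenerate data: essentially no heat signal anywhere. The model is
  # unidentifiable in kd/n; report dh ~ 0 and converged = FALSE.
  if (max(abs(obs)) < 1e-12 || stats::sd(obs) < 1e-12) {
    result$dh <- 0
    return(result)
  }

  guess <- itc_start_values(obs, prot, keep)
  if (!is.null(start)) {
    if (!is.null(start$kd)) guess$kd <- start$kd
    if (!is.null(start$n)) guess$n <- start$n
    if (!is.null(start$dh)) guess$dh <- start$dh
  }

  resid_fn <- function(par) {
    off <- if (fit_offset) par[4] else 0
    obs - model_heats(exp(par[1]), exp(par[2]), par[3], off)
  }

  kd_starts <- unique(c(guess$kd, 10^seq(-8, -4, by = 1)))
  best <- NULL
  for (kd0 in kd_starts) {
    par0 <- c(log(kd0), log(guess$n), guess$dh)
    if (fit_offset) par0 <- c(par0, 0)
    fit <- tryCatch(
      minpack.lm::nls.lm(par0, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 500, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit) || any(!is.finite(fit$par))) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  if (is.null(best)) return(result)

  kd <- exp(best$par[1]); n <- exp(best$par[2]); dh <- best$par[3]
  offset <- if (fit_offset) best$par[4] else 0
  ok <- best$info %in% 1:4 && is.finite(kd) && kd > 0 && is.finite(n) &&
    n > 0 && is.finite(dh)
  if (!ok) return(result)

  # Curvature-based standard errors on the natural parameter scale.
  theta <- c(kd = kd, n = n, dh = dh)
  if (fit_offset) theta <- c(theta, offset = offset)
  jac <- numeric_jacobian(function(th) {
    off <- if (fit_offset) th[4] else 0
    model_heats(th[1], th[2], th[3], off)
  }, theta)
  dof <- length(obs) - length(theta)
  s2 <- if (dof > 0) best$deviance / dof else NA_real_
  se <- rep(NA_real_, length(theta))
  vc <- tryCatch(s2 * solve(crossprod(jac)), error = function(e) NULL)
  if (!is.null(vc)) {
    dv <- diag(vc)
    se <- ifelse(dv >= 0, sqrt(dv), NA_real_)
  }
  names(se) <- names(theta)

  result$kd <- kd
  result$n <- n
  result$dh <- dh
  result$offset <- offset
  result$dg <- delta_g_from_kd(kd, prot$temperature)
  result$minus_tds <- entropy_term(result$dg, dh)
  result$se <- se
  result$converged <- TRUE
  full_fit <- one_site_heats(kd, n, dh, prot, offset)
  result$fitted <- full_fit
  result$residuals <- heats - full_fit
  result
}

# Heuristic initial values: n = 1; dh from the first usable injection heat
# assuming every injected mole binds; kd from the total titrant
# concentration at which the cumulative heat reaches half its final value.
itc_start_values <- function(obs, prot, keep) {
  v1 <- prot$injection_volumes[keep[1]]
  inj_moles <- prot$syringe_conc * v1
  dh0 <- (obs[1] * 1e-9) / inj_moles  # ucal -> kcal per injected mole
  if (!is.finite(dh0) || dh0 == 0) dh0 <- -1
  cum <- cumsum(obs)
  half <- which(abs(cum) >= 0.5 * abs(cum[length(cum)]))[1]
  comp <- cell_composition(prot)
  kd0 <- comp$x_total[keep[half]] / 4
  if (!is.finite(kd0) || kd0 <= 0) kd0 <- prot$cell_conc / 10
  list(kd = kd0, n = 1, dh = dh0)
}

# Central finite-difference Jacobian of f at theta (rows: observations).
numeric_jacobian <- function(f, theta) {
  f0 <- f(theta)
  jac <- matrix(0, length(f0), length(theta))
  for (j in seq_along(theta)) {
    h <- max(abs(theta[j]), 1e-12) * 1e-6
    up <- theta; up[j] <- up[j] + h
    dn <- theta; dn[j] <- dn[j] - h
    jac[, j] <- (f(up) - f(dn)) / (2 * h)
  }
  jac
}

#' @export
print.itc_fit <- function(x, ...) {
  cat("One-site ITC binding fit\n")
  if (!x$converged) {
    cat("  NOT converged\n")
    if (!is.na(x$dh)) cat(sprintf("  dh ~ %.3g kcal/mol\n", x$dh))
    return(invisible(x))
  }
  cat(sprintf("  Kd        = %.4g uM (se %.2g)\n", x$kd * 1e6,
              x$se["kd"] * 1e6))
  cat(sprintf("  n         = %.3f (se %.2g)\n", x$n, x$se["n"]))
  cat(sprintf("  dH        = %.3f kcal/mol (se %.2g)\n", x$dh, x$se["dh"]))
  cat(sprintf("  -TdS      = %.3f kcal/mol\n", x$minus_tds))
  cat(sprintf("  dG        = %.3f kcal/mol at %.2f K\n", x$dg,
              x$temperature))
  if (x$fit_offset)
    cat(sprintf("  offset    = %.3g ucal/injection\n", x$offset))
  invisible(x)
}

#' @export
summary.itc_fit <- function(object, ...) {
  est <- c(kd = object$kd, n = object$n, dh = object$dh)
  tab <- data.frame(estimate = est,
                    std_error = object$se[names(est)])
  out <- list(coefficients = tab, dg = object$dg,
              minus_tds = object$minus_tds,
              converged = object$converged,
              rss = sum(object$residuals^2, na.rm = TRUE),
              n_injections = length(object$isotherm$heats),
              dilution_convention = object$dilution_convention)
  class(out) <- "summary.itc_fit"
  out
}

#' @export
print.summary.itc_fit <- function(x, ...) {
  cat("One-site ITC binding fit\n")
  cat(sprintf("  converged: %s, %d injections, RSS %.4g ucal^2\n",
              x$converged, x$n_injections, x$rss))
  print(x$coefficients)
  cat(sprintf("  dG = %.3f, -TdS = %.3f kcal/mol\n", x$dg, x$minus_tds))
  cat(sprintf("  dilution convention: %s\n", x$dilution_convention))
  invisible(x)
}

#' @export
coef.itc_fit <- function(object, ...) {
  c(kd = object$kd, n = object$n, dh = object$dh, dg = object$dg,
    minus_tds = object$minus_tds)
}

#' @export
vcov.itc_fit <- function(object, ...) {
  se <- object$se
  vc <- diag(se^2, nrow = length(se), ncol = length(se))
  dimnames(vc) <- list(names(se), names(se))
  vc
}

#' @export
fitted.itc_fit <- function(object, ...) object$fitted

#' @export
residuals.itc_fit <- function(object, ...) object$residuals

#' Predicted injection heats under a fitted one-site model
#'
#' @param object An [itc_fit()].
#' @param protocol Optional [itc_protocol()] to predict for; defaults to the
#'   protocol of the fitted isotherm.
#' @param ... Unused.
#' @return Numeric vector of predicted heats (ucal), one per injection.
#' @export
predict.itc_fit <- function(object, protocol = NULL, ...) {
  if (!object$converged) stop("cannot predict from an unconverged fit")
  if (is.null(protocol)) protocol <- object$isotherm$protocol
  one_site_heats(object$kd, object$n, object$dh, protocol, object$offset)
}

#' Simulate isotherms from a fitted one-site model
#'
#' @param object A converged [itc_fit()].
#' @param nsim Number of isotherms to simulate.
#' @param seed Optional seed.
#' @param noise_sd Gaussian noise sd in ucal; defaults to the residual
#'   standard deviation of the fit.
#' @param ... Unused.
#' @return A list of [isotherm()] objects of length `nsim`.
#' @export
simulate.itc_fit <- function(object, nsim = 1, seed = NULL, noise_sd = NULL,
                             ...) {
  if (!object$converged) stop("cannot simulate from an unconverged fit")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(noise_sd)) noise_sd <- stats::sd(object$residuals)
  lapply(seq_len(nsim), function(i)
    simulate_isotherm(object$kd, object$n, object$dh,
                      object$isotherm$protocol, noise_sd = noise_sd,
                      offset = object$offset))
}

#' Plot observed and fitted ITC heats
#'
#' Draws the integrated injection heats against the post-injection molar
#' ratio, with the fitted one-site curve overlaid.
#'
#' @param x An [itc_fit()].
#' @param ... Passed to [graphics::plot()].
#' @export
plot.itc_fit <- function(x, ...) {
  iso <- x$isotherm
  graphics::plot(iso$molar_ratios, iso$heats, xlab = "molar ratio",
                 ylab = "injection heat (ucal)", pch = 19, ...)
  if (x$converged) {
    graphics::lines(iso$molar_ratios, x$fitted, col = "red3")
    graphics::legend("bottomright", legend = c("observed", "one-site fit"),
                     pch = c(19, NA), lty = c(NA, 1),
                     col = c("black", "red3"), bty = "n")
  }
  invisible(x)
}

#' Write a one-site fit report to JSON and CSV
#'
#' Writes the fitted parameters (`kd_uM`, `n`, `dh_kcal_mol`,
#' `minus_tds_kcal_mol`, `dg_kcal_mol`, standard errors, convergence flag,
#' dilution convention) to a JSON file, and optionally an observed-vs-fitted
#' heats table to CSV.
#'
#' @param fit An [itc_fit()].
#' @param json_path Output JSON path.
#' @param csv_path Optional output CSV path for the heats table.
#' @return Invisibly, the report list.
#' @export
write_itc_report <- function(fit, json_path, csv_path = NULL) {
  stopifnot(inherits(fit, "itc_fit"))
  report <- list(
    kd_uM = fit$kd * 1e6,
    n = fit$n,
    dh_kcal_mol = fit$dh,
    minus_tds_kcal_mol = fit$minus_tds,
    dg_kcal_mol = fit$dg,
    se_kd_uM = unname(fit$se["kd"]) * 1e6,
    se_n = unname(fit$se["n"]),
    se_dh_kcal_mol = unname(fit$se["dh"]),
    offset_ucal = fit$offset,
    converged = fit$converged,
    temperature_K = fit$temperature,
    dilution_convention = fit$dilution_convention
  )
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  if (!is.null(csv_path)) {
    utils::write.csv(
      data.frame(injection = seq_along(fit$isotherm$heats),
                 molar_ratio = fit$isotherm$molar_ratios,
                 heat_ucal = fit$isotherm$heats,
                 fitted_ucal = fit$fitted,
                 residual_ucal = fit$residuals),
      csv_path, row.names = FALSE)
  }
  invisible(report)
}
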