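# Nonlinear least-squares analysis of correlation curves: one-component fit
# for the free labeled antibody, two-component fit (fixed fast dwell time)
# for the immunocomplex mixture, assay extraction and series statistics.
# Levenberg-Marquardt with box bounds via minpack.lm::nls.lm.

fit_weights <- function(curve) {
  if (!is.null(curve$stderr) && all(curve$stderr > 0)) 1 / curve$stderr else
    rep(1, length(curve$g))
}

check_fittable_curve <- function(curve) {
  stopifnot(inherits(curve, "correlation_curve"))
  if (length(curve$lags_s) < 10 ||
      log10(max(curve$lags_s) / min(curve$lags_s)) < 2) {
    abort_domain("curve must have >= 10 lags spanning at least two decades")
  }
  if (!is.null(curve$stderr)) {
    if (max(curve$g) - 1 < 10 * median(curve$stderr)) {
      stop(errorCondition(
        "no signal: curve amplitude below 10x the median noise level",
        class = c("acthfcs_no_signal_error", "acthfcs_error")))
    }
  } else if (max(curve$g) - 1 <= 0) {
    stop(errorCondition("no signal: curve never rises above the baseline",
                        class = c("acthfcs_no_signal_error", "acthfcs_error")))
  }
  invisible(TRUE)
}

# Parameter standard errors from the Gauss-Newton curvature (J'WJ) of the
# weighted least-squares objective at the optimum.
nlslm_stderr <- function(fit) {
  out <- tryCatch({
    covm <- solve(fit$hessian) * fit$deviance / max(1, fit$df.residual)
    sqrt(pmax(diag(covm), 0))
  }, error = function(e) rep(NA_real_, length(fit$par)))
  setNames(out, names(fit$par))
}

amplitude_guess <- function(curve) {
  amp <- curve$g[1] - 1
  if (amp <= 0) amp <- max(curve$g) - 1
  max(1 / max(amp, 1e-6), 1e-3)
}

#' One-component fit of a correlation curve
#'
#' Weighted least-squares fit of [one_component_model()] to a measured curve,
#' estimating the particle number and diffusion time. Weights are the inverse
#' per-lag standard errors when the curve carries them, otherwise uniform.
#' Parameter standard errors come from the Gauss-Newton curvature at the
#' optimum. Non-convergence is flagged, not raised; a curve whose amplitude
#' is below ten times its median noise level raises a "no-signal" error.
#'
#' @param curve a [correlation_curve()] with >= 10 lags spanning two decades.
#' @param structural_parameter fixed axial/radial ratio of the volume.
#' @param init optional named list with starting values `n_particles`,
#'   `tau_d_s`; defaults are derived from the curve amplitude and the lag of
#'   half-decay.
#' @return An object of class `one_component_fit` with fields `n_particles`,
#'   `n_stderr`, `tau_d_s`, `tau_d_stderr`, `residual_norm`, `converged`.
#' @export
fit_one_component <- function(curve, structural_parameter = 5, init = NULL) {
  check_fittable_curve(curve)
  w <- fit_weights(curve)
  if (is.null(init)) {
    amp_n <- amplitude_guess(curve)
    half <- 1 + 0.5 * (curve$g[1] - 1)
    tau0 <- curve$lags_s[which.min(abs(curve$g - half))]
    init <- list(n_particles = amp_n, tau_d_s = max(tau0, min(curve$lags_s)))
  }
  resid_fun <- function(p) {
    w * (one_component_model(curve$lags_s, p[["n_particles"]], p[["tau_d_s"]],
                             structural_parameter) - curve$g)
  }
  fit <- minpack.lm::nls.lm(
    par = c(n_particles = init$n_particles, tau_d_s = init$tau_d_s),
    lower = c(1e-6, 1e-8), upper = c(1e4, 10), fn = resid_fun,
    control = minpack.lm::nls.lm.control(maxiter = 200))
  se <- nlslm_stderr(fit)
  structure(list(n_particles = fit$par[["n_particles"]],
                 n_stderr = se[["n_particles"]],
                 tau_d_s = fit$par[["tau_d_s"]],
                 tau_d_stderr = se[["tau_d_s"]],
                 residual_norm = sqrt(fit$deviance),
                 converged = fit$info %in% 1:4),
            class = "one_component_fit")
}

#' Two-component fit with fixed fast-component diffusion time
#'
#' Fits [two_component_model()] to a measured curve over total particle
#' number N', slow mole fraction Y and slow diffusion time tau_D2, with the
#' fast diffusion time held fixed at the value obtained from one-component
#' fitting of the pure labeled antibody. The slow component is constrained to
#' diffuse no faster than the fixed fast one (tau_D2 in
#' \[tau_D1, 100 tau_D1\]). Three deterministic starts (tau_D2 at 1.5x, 2.5x
#' and 5x tau_D1) guard against local minima; the best (lowest deviance)
#' solution is returned. A solution with tau_D2 pinned at either bound is
#' flagged `component_collapse`.
#'
#' @param curve a [correlation_curve()].
#' @param tau_d1_fixed_s fixed fast-component diffusion time in seconds.
#' @param structural_parameter fixed axial/radial ratio.
#' @param init optional named list with `n_total`, `mole_fraction_y`,
#'   `tau_d2_s` overriding the default multistart.
#' @return An object of class `two_component_fit` with fields `n_total`,
#'   `n_stderr`, `mole_fraction_y`, `y_stderr`, `tau_d2_s`, `tau_d2_stderr`,
#'   `tau_d1_fixed_s`, `residual_norm`, `converged`, `component_collapse`.
#' @export
fit_two_component <- function(curve, tau_d1_fixed_s, structural_parameter = 5,
                              init = NULL) {
  check_positive(tau_d1_fixed_s = tau_d1_fixed_s)
  check_fittable_curve(curve)
  w <- fit_weights(curve)
  lower <- c(n_total = 1e-6, mole_fraction_y = 0, tau_d2_s = tau_d1_fixed_s)
  upper <- c(n_total = 1e4, mole_fraction_y = 1, tau_d2_s = 100 * tau_d1_fixed_s)
  resid_fun <- function(p) {
    w * (two_component_model(curve$lags_s, p[["n_total"]],
                             min(max(p[["mole_fraction_y"]], 0), 1),
                             tau_d1_fixed_s, p[["tau_d2_s"]],
                             structural_parameter) - curve$g)
  }
  starts <- if (!is.null(init)) {
    list(c(n_total = init$n_total, mole_fraction_y = init$mole_fraction_y,
           tau_d2_s = init$tau_d2_s))
  } else {
    amp_n <- amplitude_guess(curve)
    lapply(c(1.5, 2.5, 5), function(f) {
      c(n_total = amp_n, mole_fraction_y = 0.3,
        tau_d2_s = min(f * tau_d1_fixed_s, upper[["tau_d2_s"]]))
    })
  }
  best <- NULL
  for (st in starts) {
    fit <- minpack.lm::nls.lm(par = st, lower = lower, upper = upper,
                              fn = resid_fun,
                              control = minpack.lm::nls.lm.control(maxiter = 300))
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  se <- nlslm_stderr(best)
  tau2 <- best$par[["tau_d2_s"]]
  # a slow component within 25% of the fixed fast dwell time is not
  # separable from it (the Y/tau_D2 ridge is flat there), so the fit carries
  # no usable bound-fraction information
  pinned <- tau2 < 1.25 * tau_d1_fixed_s ||
    (upper[["tau_d2_s"]] - tau2) < 1e-6 * tau_d1_fixed_s
  structure(list(n_total = best$par[["n_total"]],
                 n_stderr = se[["n_total"]],
                 mole_fraction_y = best$par[["mole_fraction_y"]],
                 y_stderr = se[["mole_fraction_y"]],
                 tau_d2_s = tau2,
                 tau_d2_stderr = se[["tau_d2_s"]],
                 tau_d1_fixed_s = tau_d1_fixed_s,
                 residual_norm = sqrt(best$deviance),
                 converged = best$info %in% 1:4,
                 component_collapse = pinned),
            class = "two_component_fit")
}

#' @export
print.two_component_fit <- function(x, ...) {
  cat(sprintf("Two-component FCS fit (tau_D1 fixed at %.1f us)\n",
              x$tau_d1_fixed_s * 1e6))
  cat(sprintf("  N'     = %.4g +/- %.2g\n", x$n_total, x$n_stderr))
  cat(sprintf("  Y      = %.4g +/- %.2g\n", x$mole_fraction_y, x$y_stderr))
  cat(sprintf("  tau_D2 = %.1f +/- %.2g us\n", x$tau_d2_s * 1e6,
              x$tau_d2_stderr * 1e6))
  if (x$component_collapse) cat("  [slow component pinned at a bound]\n")
  invisible(x)
}

#' Extract immunoassay concentrations from a two-component fit
#'
#' Splits the fitted total particle number into immunocomplex (= ACTH)
#' particles Y N' and free labeled antibody particles (1 - Y) N', and
#' converts both to molar concentrations through the calibrated effective
#' volume.
#'
#' @param fit a converged [fit_two_component()] result.
#' @param volume a [confocal_volume()].
#' @return An object of class `assay_result` with fields `n_acth`,
#'   `n_free_igg`, `c_acth_mol_l`, `c_free_igg_mol_l`.
#' @export
extract_assay_result <- function(fit, volume = confocal_volume()) {
  stopifnot(inherits(fit, "two_component_fit"))
  if (!isTRUE(fit$converged)) {
    abort_domain("cannot extract concentrations from an unconverged fit")
  }
  n_acth <- fit$mole_fraction_y * fit$n_total
  n_igg <- (1 - fit$mole_fraction_y) * fit$n_total
  structure(list(n_acth = n_acth, n_free_igg = n_igg,
                 c_acth_mol_l = particles_to_concentration(n_acth, volume$v_eff_l),
                 c_free_igg_mol_l = particles_to_concentration(n_igg, volume$v_eff_l)),
            class = "assay_result")
}

#' @export
print.assay_result <- function(x, ...) {
  cat(sprintf("FCS immunoassay result: c_ACTH = %.3f nM (N = %.3g), free IgG = %.3f nM\n",
              x$c_acth_mol_l * 1e9, x$n_acth, x$c_free_igg_mol_l * 1e9))
  invisible(x)
}

#' Series mean with Student-t confidence half-width
#'
#' Aggregates per-run estimates of a measurement series into a mean and a
#' two-sided Student-t confidence half-width at significance level `alpha`
#' (n - 1 degrees of freedom), the deviation convention used for all series
#' statistics in this package.
#'
#' @param values numeric vector of per-run estimates (length >= 2).
#' @param alpha two-sided significance level (default 0.1, i.e. a 90%
#'   confidence half-width).
#' @return An object of class `series_estimate` with fields `mean`,
#'   `halfwidth`, `n_runs`, `alpha`.
#' @examples
#' aggregate_series(rnorm(50), alpha = 0.1)
#' @export
aggregate_series <- function(values, alpha = 0.1) {
  if (length(values) < 2) abort_domain("need at least 2 values to aggregate")
  if (any(!is.finite(values))) abort_domain("'values' must be finite")
  if (alpha <= 0 || alpha >= 1) abort_domain("'alpha' must lie in (0, 1)")
  n <- length(values)
  hw <- qt(1 - alpha / 2, df = n - 1) * sd(values) / sqrt(n)
  structure(list(mean = mean(values), halfwidth = hw, n_runs = n,
                 alpha = alpha),
            class = "series_estimate")
}

#' @export
print.series_estimate <- function(x, ...) {
  cat(sprintf("%.6g +/- %.3g (Student-t, alpha = %g, n = %d)\n",
              x$mean, x$halfwidth, x$alpha, x$n_runs))
  invisible(x)
}

#' Fit a whole measurement series and aggregate the assay output
#'
#' Runs the two-component fit on every curve of a series (fast diffusion time
#' fixed), extracts the per-run ACTH concentration and aggregates
#' concentration, slow diffusion time and mole fraction with Student-t
#' deviations.
#'
#' @param curves list of [correlation_curve()] objects (one per run).
#' @param tau_d1_fixed_s fixed fast diffusion time (s), from one-component
#'   fitting of the pure labeled antibody.
#' @param volume a [confocal_volume()].
#' @param structural_parameter fixed axial/radial ratio.
#' @param alpha significance level for the series deviations.
#' @details Runs whose two-component fit collapsed (slow dwell time
#'   indistinguishable from the fixed fast one, leaving the bound fraction
#'   unidentified) are excluded from the aggregation, provided at least two
#'   clean runs remain.
#' @return An object of class `assay_series_fit` with `series_estimate`
#'   fields `c_acth` (mol/l), `tau_d2` (s), `y`, a `per_run` data frame and
#'   the count `n_collapsed` of excluded degenerate runs.
#' @export
fit_assay_series <- function(curves, tau_d1_fixed_s,
                             volume = confocal_volume(),
                             structural_parameter = 5, alpha = 0.1) {
  stopifnot(length(curves) >= 2)
  rows <- lapply(curves, function(cur) {
    fit <- fit_two_component(cur, tau_d1_fixed_s, structural_parameter)
    res <- extract_assay_result(fit, volume)
    data.frame(n_total = fit$n_total, y = fit$mole_fraction_y,
               tau_d2_s = fit$tau_d2_s, c_acth_mol_l = res$c_acth_mol_l,
               converged = fit$converged, collapsed = fit$component_collapse)
  })
  per_run <- do.call(rbind, rows)
  use <- if (sum(!per_run$collapsed) >= 2) !per_run$collapsed else
    rep(TRUE, nrow(per_run))
  structure(list(c_acth = aggregate_series(per_run$c_acth_mol_l[use], alpha),
                 tau_d2 = aggregate_series(per_run$tau_d2_s[use], alpha),
                 y = aggregate_series(per_run$y[use], alpha),
                 per_run = per_run, n_collapsed = sum(!use)),
            class = "assay_series_fit")
}

#' @export
print.assay_series_fit <- function(x, ...) {
  cat(sprintf("FCS immunoassay series (n = %d runs)\n", x$c_acth$n_runs))
  cat(sprintf("  c_ACTH = %.3f +/- %.3f nM\n", x$c_acth$mean * 1e9,
              x$c_acth$halfwidth * 1e9))
  cat(sprintf("  tau_D2 = %.1f +/- %.1f us\n", x$tau_d2$mean * 1e6,
              x$tau_d2$halfwidth * 1e6))
  cat(sprintf("  Y      = %.3f +/- %.3f\n", x$y$mean, x$y$halfwidth))
  invisible(x)
}
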