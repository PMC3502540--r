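# CSV dialect for correlation curves and fit reports.

#' Write a correlation curve to CSV
#'
#' Columns `lag_s,g,stderr` (the `stderr` column is omitted when the curve
#' carries none), '.' decimal separator, UTF-8.
#'
#' @param curve a [correlation_curve()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_correlation_csv <- function(curve, path) {
  stopifnot(inherits(curve, "correlation_curve"))
  df <- data.frame(lag_s = curve$lags_s, g = curve$g)
  if (!is.null(curve$stderr)) df$stderr <- curve$stderr
  write.csv(df, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a correlation curve from CSV
#'
#' @param path file with header `lag_s,g` and optional `stderr` column.
#' @param meas_time_s,n_runs acquisition metadata to attach (not stored in
#'   the CSV).
#' @return A [correlation_curve()].
#' @export
read_correlation_csv <- function(path, meas_time_s = 10, n_runs = 50) {
  if (!file.exists(path)) {
    stop(errorCondition(sprintf("file not found: %s", path),
                        class = c("acthfcs_io_error", "acthfcs_error")))
  }
  df <- read.csv(path, fileEncoding = "UTF-8")
  if (!all(c("lag_s", "g") %in% names(df))) {
    stop(errorCondition("correlation CSV must have columns 'lag_s' and 'g'",
                        class = c("acthfcs_io_error", "acthfcs_error")))
  }
  correlation_curve(df$lag_s, df$g,
                    stderr = if ("stderr" %in% names(df)) df$stderr else NULL,
                    meas_time_s = meas_time_s, n_runs = n_runs)
}

#' Write a fit report as CSV
#'
#' One row per fitted parameter with columns `param,estimate,stderr`.
#'
#' @param fit a `one_component_fit` or `two_component_fit`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fit_report <- function(fit, path) {
  if (inherits(fit, "one_component_fit")) {
    df <- data.frame(param = c("n_particles", "tau_d_s"),
                     estimate = c(fit$n_particles, fit$tau_d_s),
                     stderr = c(fit$n_stderr, fit$tau_d_stderr))
  } else if (inherits(fit, "two_component_fit")) {
    df <- data.frame(param = c("n_total", "mole_fraction_y", "tau_d2_s"),
                     estimate = c(fit$n_total, fit$mole_fraction_y, fit$tau_d2_s),
                     stderr = c(fit$n_stderr, fit$y_stderr, fit$tau_d2_stderr))
  } else {
    abort_domain("'fit' must be a one_component_fit or two_component_fit")
  }
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a per-series assay summary as JSON
#'
#' @param series result of [fit_assay_series()].
#' @param path output file path.
#' @param seed optional run seed recorded in the report for reproducibility.
#' @return `path`, invisibly.
#' @export
write_series_json <- function(series, path, seed = NULL) {
  stopifnot(inherits(series, "assay_series_fit"))
  out <- list(
    n_runs = series$c_acth$n_runs,
    alpha = series$c_acth$alpha,
    c_acth_nM = list(mean = series$c_acth$mean * 1e9,
                     halfwidth = series$c_acth$halfwidth * 1e9),
    tau_d2_us = list(mean = series$tau_d2$mean * 1e6,
                     halfwidth = series$tau_d2$halfwidth * 1e6),
    mole_fraction_y = list(mean = series$y$mean,
                           halfwidth = series$y$halfwidth))
  if (!is.null(seed)) out$seed <- seed
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
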