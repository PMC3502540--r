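# Synthetic data standing in for the instrument: direct noisy-curve
# generation from the analytic models, an immunoassay scenario generator
# encoding the sandwich-capture stoichiometry, and a Brownian-dynamics
# photon-trace simulator with a multiple-tau correlator as brute-force
# oracle for the Gaussian-volume model.

#' Immunoassay acquisition protocol
#'
#' The sandwich-assay conditions: labeled and unlabeled anti-ACTH antibody
#' doses (both 60 nM, an excess over the expected analyte), the dwell times
#' of free labeled antibody (220 us) and immunocomplex (483 us), and the
#' acquisition series protocol (50 runs of 10 s each).
#'
#' @param c_labeled_ab_mol_l labeled antibody dose in mol/l.
#' @param c_unlabeled_ab_mol_l unlabeled (capture) antibody dose in mol/l.
#' @param tau_free_s diffusion time of the free labeled antibody (s).
#' @param tau_complex_s diffusion time of the immunocomplex (s); must exceed
#'   `tau_free_s`.
#' @param n_runs runs per series.
#' @param meas_time_s measurement time per run (s).
#' @param volume a [confocal_volume()].
#' @return An object of class `assay_protocol`.
#' @export
assay_protocol <- function(c_labeled_ab_mol_l = 60e-9,
                           c_unlabeled_ab_mol_l = 60e-9,
                           tau_free_s = 220e-6, tau_complex_s = 483e-6,
                           n_runs = 50, meas_time_s = 10,
                           volume = confocal_volume()) {
  check_positive(c_labeled_ab_mol_l = c_labeled_ab_mol_l,
                 c_unlabeled_ab_mol_l = c_unlabeled_ab_mol_l,
                 tau_free_s = tau_free_s, tau_complex_s = tau_complex_s,
                 n_runs = n_runs, meas_time_s = meas_time_s)
  if (tau_complex_s <= tau_free_s) {
    abort_domain("'tau_complex_s' must exceed 'tau_free_s' (bound species diffuse slower)")
  }
  structure(list(c_labeled_ab_mol_l = c_labeled_ab_mol_l,
                 c_unlabeled_ab_mol_l = c_unlabeled_ab_mol_l,
                 tau_free_s = tau_free_s, tau_complex_s = tau_complex_s,
                 n_runs = n_runs, meas_time_s = meas_time_s, volume = volume),
            class = "assay_protocol")
}

#' Bound mole fraction under complete sandwich capture
#'
#' In antibody excess and after full incubation, every ACTH molecule is
#' captured by exactly one labeled antibody, so the slow-component mole
#' fraction is Y = c_ACTH / c_labeled_antibody.
#'
#' @param c_acth_mol_l ACTH concentration in mol/l (0 <= c <= labeled dose).
#' @param protocol an [assay_protocol()].
#' @return Mole fraction Y in \[0, 1\].
#' @examples
#' mole_fraction_from_capture(15e-9, assay_protocol())  # 0.25
#' @export
mole_fraction_from_capture <- function(c_acth_mol_l,
                                       protocol = assay_protocol()) {
  if (!is.finite(c_acth_mol_l) || c_acth_mol_l < 0) {
    abort_domain("'c_acth_mol_l' must be >= 0")
  }
  if (c_acth_mol_l > protocol$c_labeled_ab_mol_l) {
    stop(errorCondition(
      "ACTH exceeds the labeled antibody dose: outside the antibody-excess regime",
      class = c("acthfcs_saturation_error", "acthfcs_error")))
  }
  c_acth_mol_l / protocol$c_labeled_ab_mol_l
}

#' Quasi-logarithmic lag grid
#'
#' Multiple-tau style grid with `channels_per_octave` equally spaced channels
#' per doubling of lag, from `min_s` to `max_s`.
#'
#' @param min_s smallest lag (s).
#' @param max_s largest lag (s).
#' @param channels_per_octave channels per lag doubling.
#' @return Strictly increasing vector of lag times in seconds.
#' @export
default_lag_grid <- function(min_s = 1e-6, max_s = 1, channels_per_octave = 16) {
  check_positive(min_s = min_s, max_s = max_s,
                 channels_per_octave = channels_per_octave)
  n_oct <- ceiling(log2(max_s / min_s))
  lags <- unlist(lapply(seq_len(n_oct) - 1L, function(o) {
    min_s * 2^o * (1 + (seq_len(channels_per_octave) - 1) / channels_per_octave)
  }))
  lags[lags <= max_s * (1 + 1e-12)]
}

#' Generate one noisy synthetic correlation curve
#'
#' Evaluates the two-component model on the lag grid and adds zero-mean
#' Gaussian noise with a lag-dependent standard deviation
#' `noise_scale * ((G(tau) - 1) + sqrt(tau / meas_time))`: short-lag noise is
#' proportional to the correlation amplitude, long lags are noisier because
#' fewer independent fluctuations of that duration fit into one measurement.
#' The generated `stderr` column carries the exact noise SD used.
#'
#' @param n_total total particle number N' in the volume.
#' @param y slow-component mole fraction.
#' @param protocol an [assay_protocol()].
#' @param lags lag grid in seconds.
#' @param noise_scale dimensionless noise amplitude (0 gives the exact model
#'   curve). Default 0.01, calibrated once so that 50-run series at 15 nM
#'   analyte reproduce concentration deviations in the instrument's reported
#'   sub-nanomolar band (~0.2-0.7 nM); see the methods vignette for why the
#'   dwell-time spreads of such i.i.d. noise are tighter than the instrument-reported
#'   across-day deviations.
#' @param seed integer seed; identical seeds give bit-identical curves.
#' @return A [correlation_curve()].
#' @export
generate_correlation_curve <- function(n_total, y, protocol = assay_protocol(),
                                       lags = default_lag_grid(),
                                       noise_scale = 0.01, seed = 1) {
  if (length(lags) == 0) abort_domain("empty lag grid")
  if (noise_scale < 0) abort_domain("'noise_scale' must be >= 0")
  s <- protocol$volume$structural_parameter
  g0 <- two_component_model(lags, n_total, y, protocol$tau_free_s,
                            protocol$tau_complex_s, s)
  sds <- noise_scale * ((g0 - 1) + sqrt(lags / protocol$meas_time_s))
  g <- g0
  if (noise_scale > 0) {
    set.seed(as.integer(seed))
    g <- g0 + rnorm(length(lags), sd = sds)
  }
  correlation_curve(lags, g, stderr = sds,
                    meas_time_s = protocol$meas_time_s,
                    n_runs = protocol$n_runs)
}

#' Generate a full synthetic immunoassay measurement series
#'
#' Encodes the sandwich stoichiometry: the total fluorescent particle number
#' comes from the labeled antibody dose through the effective volume, the
#' slow mole fraction from complete capture of the ACTH present. Per-run
#' seeds are derived deterministically from the master seed.
#'
#' @param c_acth_true_mol_l true ACTH concentration (mol/l).
#' @param protocol an [assay_protocol()].
#' @param noise_scale see [generate_correlation_curve()].
#' @param seed master seed for the series.
#' @param lags lag grid.
#' @return List of `protocol$n_runs` [correlation_curve()] objects.
#' @export
generate_assay_series <- function(c_acth_true_mol_l,
                                  protocol = assay_protocol(),
                                  noise_scale = 0.01, seed = 1,
                                  lags = default_lag_grid()) {
  y <- mole_fraction_from_capture(c_acth_true_mol_l, protocol)
  n_total <- concentration_to_particles(protocol$c_labeled_ab_mol_l,
                                        protocol$volume$v_eff_l)
  set.seed(as.integer(seed))
  run_seeds <- sample.int(.Machine$integer.max - 1L, protocol$n_runs)
  lapply(run_seeds, function(s) {
    generate_correlation_curve(n_total, y, protocol, lags, noise_scale, s)
  })
}

#' Brownian-dynamics simulation configuration
#'
#' Settings for the brute-force photon-trace oracle: particles of one or
#' more species take independent Gaussian steps in a periodic box containing
#' a Gaussian detection profile, and emit Poisson photons proportional to the
#' local excitation intensity.
#'
#' @param box_lengths_um periodic box edge lengths (x, y, z) in micrometers;
#'   validated against the detection volume (>= 10x the matching 1/e^2
#'   radius) at simulation time.
#' @param n_particles integer count per species.
#' @param d_coeffs_cm2_s diffusion coefficient per species (cm^2/s).
#' @param brightness_cps detected counts/s per molecule at the focus center.
#' @param time_step_s integration step and photon bin width (s); default
#'   tau_D,min / 50, the stability bound.
#' @param duration_s total simulated time (s).
#' @param seed integer seed of the simulator's own deterministic RNG.
#' @param init_positions_um optional matrix (sum(n_particles) x 3) of fixed
#'   starting positions; default uniform in the box.
#' @return An object of class `brownian_config`.
#' @export
brownian_config <- function(box_lengths_um = c(1.7, 1.7, 8.8),
                            n_particles = 90L,
                            d_coeffs_cm2_s = 3.7e-7,
                            brightness_cps = 1e5,
                            time_step_s = NULL,
                            duration_s = 100,
                            seed = 1L,
                            init_positions_um = NULL) {
  if (length(box_lengths_um) != 3 || any(box_lengths_um <= 0)) {
    abort_domain("'box_lengths_um' must be three positive lengths")
  }
  if (length(n_particles) != length(d_coeffs_cm2_s) ||
      length(n_particles) != length(brightness_cps)) {
    abort_domain("'n_particles', 'd_coeffs_cm2_s', 'brightness_cps' must align per species")
  }
  if (any(n_particles < 1)) abort_domain("need at least one particle per species")
  if (any(d_coeffs_cm2_s < 0) || any(brightness_cps < 0)) {
    abort_domain("diffusion coefficients and brightness must be >= 0")
  }
  check_positive(duration_s = duration_s)
  structure(list(box_lengths_um = box_lengths_um,
                 n_particles = as.integer(n_particles),
                 d_coeffs_cm2_s = d_coeffs_cm2_s,
                 brightness_cps = brightness_cps,
                 time_step_s = time_step_s, duration_s = duration_s,
                 seed = as.integer(seed),
                 init_positions_um = init_positions_um),
            class = "brownian_config")
}

#' Effective Gaussian detection volume of the simulator
#'
#' The simulator's own effective volume, pi^(3/2) r^2 z of its Gaussian
#' detection profile, in liters. Used for amplitude checks against the
#' simulated traces; it is deliberately independent of the instrument's
#' `v_eff_l` calibration constant.
#'
#' @param volume a [confocal_volume()].
#' @return Effective volume in liters.
#' @export
simulator_effective_volume <- function(volume = confocal_volume()) {
  pi^1.5 * volume$radial_r_um^2 * volume$axial_z_um * 1e-15
}

#' Simulate a photon-count trace by Brownian dynamics
#'
#' Particles take independent Gaussian steps of standard deviation
#' sqrt(2 D dt) per axis with periodic wrapping in the box; the expected
#' count in each time bin is the sum over particles of
#' `brightness * exp(-2x^2/r^2 - 2y^2/r^2 - 2z^2/z_ax^2) * dt`, and emitted
#' counts are Poisson draws. Fully deterministic for a given seed (own
#' counter-free xoshiro256++ generator, independent of R's RNG state).
#'
#' @param config a [brownian_config()].
#' @param volume a [confocal_volume()] defining the detection profile.
#' @return An object of class `photon_trace` with fields `bin_width_s`,
#'   `counts` (integer), `duration_s`.
#' @export
simulate_photon_trace <- function(config, volume = confocal_volume()) {
  stopifnot(inherits(config, "brownian_config"))
  r <- volume$radial_r_um
  z <- volume$axial_z_um
  tol <- 1 - 1e-9
  if (config$box_lengths_um[1] < 10 * r * tol ||
      config$box_lengths_um[2] < 10 * r * tol ||
      config$box_lengths_um[3] < 10 * z * tol) {
    stop(errorCondition(
      "box must be >= 10x the matching detection-volume 1/e^2 radius in every axis",
      class = c("acthfcs_config_error", "acthfcs_error")))
  }
  d_um2_s <- config$d_coeffs_cm2_s * 1e8  # cm^2/s -> um^2/s
  dpos <- config$d_coeffs_cm2_s[config$d_coeffs_cm2_s > 0]
  dt <- config$time_step_s
  if (is.null(dt)) {
    if (length(dpos) == 0) {
      dt <- 1e-5
    } else {
      tau_min <- min(vapply(dpos, diffusion_time_from_coefficient,
                            numeric(1), radial_r_um = r))
      dt <- tau_min / 50
    }
  } else if (length(dpos) > 0) {
    tau_min <- min(vapply(dpos, diffusion_time_from_coefficient,
                          numeric(1), radial_r_um = r))
    if (dt > tau_min / 50 * (1 + 1e-9)) {
      stop(errorCondition("time step exceeds tau_D,min / 50",
                          class = c("acthfcs_config_error", "acthfcs_error")))
    }
  }
  n_bins <- as.integer(floor(config$duration_s / dt))
  species <- rep.int(seq_along(config$n_particles), config$n_particles)
  init <- config$init_positions_um
  if (!is.null(init)) {
    init <- as.matrix(init)
    if (nrow(init) != length(species) || ncol(init) != 3) {
      abort_domain("'init_positions_um' must be a sum(n_particles) x 3 matrix")
    }
  }
  counts <- .Call(C_brownian_trace,
                  as.numeric(config$box_lengths_um),
                  as.numeric(d_um2_s[species]),
                  as.numeric(config$brightness_cps[species]),
                  as.numeric(dt), as.integer(n_bins),
                  as.numeric(r), as.numeric(z),
                  as.integer(config$seed),
                  if (is.null(init)) NULL else as.numeric(t(init)))
  structure(list(bin_width_s = dt, counts = counts,
                 duration_s = n_bins * dt),
            class = "photon_trace")
}

#' @export
print.photon_trace <- function(x, ...) {
  cat(sprintf("Photon trace: %d bins of %.3g us, mean rate %.3g kHz\n",
              length(x$counts), x$bin_width_s * 1e6,
              mean(x$counts) / x$bin_width_s / 1000))
  invisible(x)
}

#' Multiple-tau autocorrelation of a photon trace
#'
#' Computes the normalized estimator G(tau) = <F(t) F(t+tau)> / <F>^2 on a
#' quasi-logarithmic grid: the first octave uses the raw bin width, then the
#' trace is coarsened by summing neighbouring bins every
#' `channels_per_octave` lags, as in hardware multiple-tau correlators.
#' Symmetric normalization (separate direct and delayed monitors) removes
#' the bias from finite trace length. G of a constant signal is identically 1.
#'
#' @param trace a [photon_trace()] with at least 2^10 bins.
#' @param channels_per_octave lag channels per doubling of the bin width.
#' @return A [correlation_curve()] (no stderr column).
#' @export
multiple_tau_autocorrelate <- function(trace, channels_per_octave = 16) {
  stopifnot(inherits(trace, "photon_trace"))
  if (length(trace$counts) < 2^10) {
    abort_domain("trace too short: need at least 2^10 bins")
  }
  m <- as.integer(channels_per_octave)
  if (m < 2) abort_domain("'channels_per_octave' must be >= 2")
  x <- as.numeric(trace$counts)
  width <- trace$bin_width_s
  lag_s <- numeric(0)
  gval <- numeric(0)
  level <- 0L
  repeat {
    n <- length(x)
    ks <- if (level == 0L) seq_len(m) else (m %/% 2 + 1):m
    if (n < max(ks) * 4) break
    for (k in ks) {
      a <- x[1:(n - k)]
      b <- x[(k + 1):n]
      denom <- mean(a) * mean(b)
      if (denom <= 0) next
      lag_s <- c(lag_s, k * width)
      gval <- c(gval, mean(a * b) / denom)
    }
    # coarsen: sum neighbouring bins, double the bin width
    if (n %% 2 == 1) x <- x[-n]
    x <- x[seq(1, length(x), by = 2)] + x[seq(2, length(x), by = 2)]
    width <- width * 2
    level <- level + 1L
  }
  ord <- order(lag_s)
  correlation_curve(lag_s[ord], gval[ord], meas_time_s = trace$duration_s,
                    n_runs = 1)
}
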