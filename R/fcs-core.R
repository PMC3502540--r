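# Closed-form FCS diffusion models, confocal-volume calibration and the
# particle-number <-> concentration conversion used by the immunoassay.

#' Calibrated confocal detection volume
#'
#' Geometry of the Gaussian detection volume of a confocal FCS setup together
#' with the effective-volume calibration constant used for converting particle
#' numbers into molar concentrations. The radial (`radial_r_um`) and axial
#' (`axial_z_um`) dimensions are the 1/e^2 radii of the Gaussian profile; the
#' structural parameter is their axial-to-radial ratio and is held fixed
#' during all curve fitting. The effective volume `v_eff_l` is an independent
#' calibration constant (default 5e-16 l): it is *not* derived from r and z,
#' because the instrument calibration that defines it is a separate
#' measurement (see the methods vignette for the numerical background).
#'
#' @param radial_r_um radial 1/e^2 radius in micrometers (> 0).
#' @param axial_z_um axial 1/e^2 radius in micrometers (> 0).
#' @param structural_parameter dimensionless axial/radial ratio; must agree
#'   with `axial_z_um / radial_r_um` within 5% (instrument software rounds it).
#' @param v_eff_l effective detection volume in liters (> 0).
#' @return An object of class `confocal_volume`.
#' @examples
#' confocal_volume()  # the default rhodamine-calibrated geometry
#' @export
confocal_volume <- function(radial_r_um = 0.17, axial_z_um = 0.88,
                            structural_parameter = 5, v_eff_l = 5e-16) {
  check_positive(radial_r_um = radial_r_um, axial_z_um = axial_z_um,
                 structural_parameter = structural_parameter, v_eff_l = v_eff_l)
  ratio <- axial_z_um / radial_r_um
  if (abs(structural_parameter - ratio) / structural_parameter > 0.05) {
    abort_domain(sprintf(
      "structural_parameter (%.4g) deviates more than 5%% from axial/radial ratio (%.4g)",
      structural_parameter, ratio))
  }
  structure(list(radial_r_um = radial_r_um, axial_z_um = axial_z_um,
                 structural_parameter = structural_parameter,
                 v_eff_l = v_eff_l),
            class = "confocal_volume")
}

#' @export
print.confocal_volume <- function(x, ...) {
  cat("Confocal detection volume\n")
  cat(sprintf("  radial 1/e^2 radius : %.3g um\n", x$radial_r_um))
  cat(sprintf("  axial  1/e^2 radius : %.3g um\n", x$axial_z_um))
  cat(sprintf("  structural parameter: %.3g\n", x$structural_parameter))
  cat(sprintf("  effective volume    : %.3g l\n", x$v_eff_l))
  invisible(x)
}

#' FCS correlation curve
#'
#' Lag times and autocorrelation amplitudes G(tau) for one measurement run,
#' with optional per-lag standard errors and the acquisition protocol
#' metadata (measurement time per run and series length).
#'
#' @param lags_s strictly increasing positive lag times in seconds.
#' @param g autocorrelation values (dimensionless, baseline 1), same length.
#' @param stderr optional per-lag standard errors (>= 0).
#' @param meas_time_s acquisition duration of one run in seconds.
#' @param n_runs number of runs in the series the curve belongs to.
#' @return An object of class `correlation_curve`.
#' @export
correlation_curve <- function(lags_s, g, stderr = NULL, meas_time_s = 10,
                              n_runs = 50) {
  if (length(lags_s) != length(g)) {
    abort_domain("'lags_s' and 'g' must have the same length")
  }
  if (any(!is.finite(lags_s)) || any(lags_s <= 0) || any(diff(lags_s) <= 0)) {
    abort_domain("'lags_s' must be strictly increasing positive times")
  }
  if (any(!is.finite(g))) abort_domain("'g' must be finite")
  if (!is.null(stderr)) {
    if (length(stderr) != length(g) || any(!is.finite(stderr)) || any(stderr < 0)) {
      abort_domain("'stderr' must be finite, non-negative and match 'g' in length")
    }
  }
  check_positive(meas_time_s = meas_time_s, n_runs = n_runs)
  structure(list(lags_s = as.numeric(lags_s), g = as.numeric(g),
                 stderr = if (is.null(stderr)) NULL else as.numeric(stderr),
                 meas_time_s = meas_time_s, n_runs = n_runs),
            class = "correlation_curve")
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("FCS correlation curve: %d lags, %.3g s .. %.3g s, G(first lag) = %.4f\n",
              length(x$lags_s), min(x$lags_s), max(x$lags_s), x$g[1]))
  invisible(x)
}

#' Diffusing species with consistent diffusion coefficient and dwell time
#'
#' Carrier for one diffusing species. When both the diffusion coefficient and
#' the dwell (diffusion) time are given together with a confocal volume, their
#' consistency via tau_D = r^2 / (4 D) is enforced within 1%.
#'
#' @param name species label.
#' @param d_coeff_cm2_s diffusion coefficient in cm^2/s (> 0), optional.
#' @param tau_d_s diffusion time through the volume in seconds (> 0), optional.
#' @param volume optional [confocal_volume()] used for the consistency check.
#' @return An object of class `diffusing_species`.
#' @export
diffusing_species <- function(name, d_coeff_cm2_s = NULL, tau_d_s = NULL,
                              volume = NULL) {
  if (!is.null(d_coeff_cm2_s)) check_positive(d_coeff_cm2_s = d_coeff_cm2_s)
  if (!is.null(tau_d_s)) check_positive(tau_d_s = tau_d_s)
  if (!is.null(d_coeff_cm2_s) && !is.null(tau_d_s) && !is.null(volume)) {
    expected <- diffusion_time_from_coefficient(d_coeff_cm2_s, volume$radial_r_um)
    if (abs(expected - tau_d_s) / expected > 0.01) {
      abort_domain(sprintf(
        "tau_d_s (%.4g s) inconsistent with d_coeff and volume (expect %.4g s)",
        tau_d_s, expected))
    }
  }
  structure(list(name = name, d_coeff_cm2_s = d_coeff_cm2_s,
                 tau_d_s = tau_d_s),
            class = "diffusing_species")
}

#' Diffusion time through the confocal volume from a diffusion coefficient
#'
#' tau_D = r^2 / (4 D), the mean dwell time of a species with diffusion
#' coefficient D in a Gaussian detection volume of radial 1/e^2 radius r
#' (one-photon excitation).
#'
#' @param d_coeff_cm2_s diffusion coefficient in cm^2/s (> 0).
#' @param radial_r_um radial 1/e^2 radius in micrometers (> 0).
#' @return Diffusion time in seconds.
#' @examples
#' # IgG antibody, D = 3.7e-7 cm^2/s in the 0.17-um focus: ~195 us
#' diffusion_time_from_coefficient(3.7e-7, 0.17)
#' @export
diffusion_time_from_coefficient <- function(d_coeff_cm2_s, radial_r_um) {
  check_positive(d_coeff_cm2_s = d_coeff_cm2_s, radial_r_um = radial_r_um)
  r_cm <- radial_r_um * 1e-4
  r_cm^2 / (4 * d_coeff_cm2_s)
}

#' Calibrate the confocal volume from a reference dye measurement
#'
#' Inverts tau_D = r^2 / (4 D) for the radial dimension using the measured
#' dwell time of a dye with known diffusion coefficient (the standard
#' rhodamine 6G calibration), sets the axial dimension through the structural
#' parameter, and stores the supplied effective-volume constant.
#'
#' @param tau_d_measured_s measured dwell time of the calibration dye (s).
#' @param d_known_cm2_s its known diffusion coefficient (cm^2/s).
#' @param structural_parameter axial/radial ratio of the detection volume.
#' @param v_eff_l effective volume calibration constant in liters.
#' @return A [confocal_volume()].
#' @examples
#' calibrate_confocal_volume(25.8e-6, 2.8e-6, structural_parameter = 5.18)
#' @export
calibrate_confocal_volume <- function(tau_d_measured_s, d_known_cm2_s,
                                      structural_parameter = 5,
                                      v_eff_l = 5e-16) {
  check_positive(tau_d_measured_s = tau_d_measured_s,
                 d_known_cm2_s = d_known_cm2_s,
                 structural_parameter = structural_parameter,
                 v_eff_l = v_eff_l)
  r_cm <- sqrt(4 * d_known_cm2_s * tau_d_measured_s)
  r_um <- r_cm * 1e4
  confocal_volume(radial_r_um = r_um,
                  axial_z_um = structural_parameter * r_um,
                  structural_parameter = structural_parameter,
                  v_eff_l = v_eff_l)
}

# Normalized single-species diffusion decay g(tau) for a 3D Gaussian volume.
g_diffusion <- function(tau_s, tau_d_s, structural_parameter) {
  1 / ((1 + tau_s / tau_d_s) *
         sqrt(1 + tau_s / (structural_parameter^2 * tau_d_s)))
}

#' One-component diffusion autocorrelation model
#'
#' G(tau) = 1 + (1/N) (1 + tau/tau_D)^-1 (1 + tau/(s^2 tau_D))^-1/2 for a
#' single species diffusing through a 3D Gaussian detection volume with
#' structural parameter s. The amplitude above the baseline, G(0) - 1, equals
#' 1/N with N the mean particle number in the volume.
#'
#' @param tau_s lag time(s) in seconds (>= 0); vectorized.
#' @param n_particles mean particle number N (> 0).
#' @param tau_d_s diffusion time in seconds (> 0).
#' @param structural_parameter axial/radial ratio (> 0), fixed at 5 by default.
#' @return G(tau), same length as `tau_s`.
#' @examples
#' one_component_model(0, n_particles = 4, tau_d_s = 220e-6)        # 1.25
#' one_component_model(220e-6, 1, 220e-6, structural_parameter = 5) # ~1.4903
#' @export
one_component_model <- function(tau_s, n_particles, tau_d_s,
                                structural_parameter = 5) {
  if (any(!is.finite(tau_s)) || any(tau_s < 0)) {
    abort_domain("'tau_s' must be finite and >= 0")
  }
  check_positive(n_particles = n_particles, tau_d_s = tau_d_s,
                 structural_parameter = structural_parameter)
  1 + g_diffusion(tau_s, tau_d_s, structural_parameter) / n_particles
}

#' Two-component diffusion autocorrelation model
#'
#' G(tau) = 1 + (1/N') ((1 - Y) g1(tau) + Y g2(tau)) with g_i the normalized
#' single-species decays of the fast (free labeled antibody) and slow
#' (immunocomplex) components and Y the slow component's mole fraction.
#' N' = N1 + N2 is the total particle number; the amplitude G(0) - 1 = 1/N'
#' is independent of Y.
#'
#' @param tau_s lag time(s) in seconds (>= 0); vectorized.
#' @param n_total total particle number N' (> 0).
#' @param mole_fraction_y slow-component mole fraction Y in \[0, 1\].
#' @param tau_d1_s fast-component diffusion time (s).
#' @param tau_d2_s slow-component diffusion time (s).
#' @param structural_parameter axial/radial ratio, fixed at 5 by default.
#' @return G(tau), same length as `tau_s`.
#' @examples
#' two_component_model(220e-6, 10, 0.25, 220e-6, 483e-6)  # ~1.0538
#' @export
two_component_model <- function(tau_s, n_total, mole_fraction_y, tau_d1_s,
                                tau_d2_s, structural_parameter = 5) {
  if (any(!is.finite(tau_s)) || any(tau_s < 0)) {
    abort_domain("'tau_s' must be finite and >= 0")
  }
  check_positive(n_total = n_total, tau_d1_s = tau_d1_s, tau_d2_s = tau_d2_s,
                 structural_parameter = structural_parameter)
  if (!is.finite(mole_fraction_y) || mole_fraction_y < 0 || mole_fraction_y > 1) {
    abort_domain("'mole_fraction_y' must lie in [0, 1]")
  }
  g1 <- g_diffusion(tau_s, tau_d1_s, structural_parameter)
  g2 <- g_diffusion(tau_s, tau_d2_s, structural_parameter)
  1 + ((1 - mole_fraction_y) * g1 + mole_fraction_y * g2) / n_total
}

#' Convert a particle number in the confocal volume to molar concentration
#'
#' c = N / (6.023e23 mol^-1 * V_eff). With the default effective volume of
#' 5e-16 l the denominator is 30.115e7, i.e. one particle corresponds to
#' about 3.32 nM.
#'
#' @param n_particles mean particle number (>= 0).
#' @param v_eff_l effective detection volume in liters (> 0).
#' @return Concentration in mol/l.
#' @examples
#' particles_to_concentration(18.07)  # ~60 nM
#' @export
particles_to_concentration <- function(n_particles, v_eff_l = 5e-16) {
  if (any(!is.finite(n_particles)) || any(n_particles < 0)) {
    abort_domain("'n_particles' must be >= 0")
  }
  check_positive(v_eff_l = v_eff_l)
  n_particles / (AVOGADRO * v_eff_l)
}

#' Convert a molar concentration to a particle number in the confocal volume
#'
#' Inverse of [particles_to_concentration()].
#'
#' @param c_mol_l concentration in mol/l (>= 0).
#' @param v_eff_l effective detection volume in liters (> 0).
#' @return Mean particle number.
#' @export
concentration_to_particles <- function(c_mol_l, v_eff_l = 5e-16) {
  if (any(!is.finite(c_mol_l)) || any(c_mol_l < 0)) {
    abort_domain("'c_mol_l' must be >= 0")
  }
  check_positive(v_eff_l = v_eff_l)
  c_mol_l * AVOGADRO * v_eff_l
}
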