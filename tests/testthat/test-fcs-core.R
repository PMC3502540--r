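# Closed-form FCS models, calibration relations and unit conversions.

test_that("diffusion time follows r^2/(4D) with correct unit handling", {
  # IgG antibody: D = 3.7e-7 cm^2/s in the 0.17-um focus
  tau_igg <- diffusion_time_from_coefficient(3.7e-7, 0.17)
  expect_equal(tau_igg, (0.17e-4)^2 / (4 * 3.7e-7), tolerance = 1e-12)
  expect_equal(round(tau_igg * 1e6 / 10) * 10, 200)  # ~195 us, 200 to nearest 10
  # rhodamine 6G: 25.8 us
  expect_equal(diffusion_time_from_coefficient(2.8e-6, 0.17) * 1e6, 25.8,
               tolerance = 2e-3)
  # strictly decreasing in D, increasing in r
  expect_gt(diffusion_time_from_coefficient(1e-7, 0.17),
            diffusion_time_from_coefficient(2e-7, 0.17))
  expect_gt(diffusion_time_from_coefficient(1e-7, 0.2),
            diffusion_time_from_coefficient(1e-7, 0.17))
  expect_error(diffusion_time_from_coefficient(-1, 0.17),
               class = "acthfcs_domain_error")
  expect_error(diffusion_time_from_coefficient(1e-7, 0),
               class = "acthfcs_domain_error")
})

test_that("confocal-volume calibration inverts the dwell-time relation", {
  # the rhodamine calibration reproduces the instrument geometry
  cv <- calibrate_confocal_volume(25.8e-6, 2.8e-6, structural_parameter = 5.18)
  expect_equal(cv$radial_r_um, 0.17, tolerance = 1e-3)
  expect_equal(cv$axial_z_um, 0.88, tolerance = 1e-2)
  # round trip: r -> tau -> r
  for (r in c(0.12, 0.17, 0.25)) {
    tau <- diffusion_time_from_coefficient(2.8e-6, r)
    expect_equal(calibrate_confocal_volume(tau, 2.8e-6, 5.18)$radial_r_um, r,
                 tolerance = 1e-10)
  }
  # square-root law: 4x dwell time doubles the radius
  cv4 <- calibrate_confocal_volume(4 * 25.8e-6, 2.8e-6, 5.18)
  expect_equal(cv4$radial_r_um, 2 * cv$radial_r_um, tolerance = 1e-10)
  # structural-parameter invariant holds on the returned object
  expect_equal(cv$axial_z_um / cv$radial_r_um, cv$structural_parameter,
               tolerance = 1e-10)
  expect_error(calibrate_confocal_volume(0, 2.8e-6), class = "acthfcs_domain_error")
})

test_that("confocal_volume validates the instrument-rounded structural parameter", {
  # 0.88/0.17 = 5.18 is rounded to 5 by the instrument; within the 5% slack
  cv <- confocal_volume(0.17, 0.88, structural_parameter = 5)
  expect_s3_class(cv, "confocal_volume")
  expect_error(confocal_volume(0.17, 0.88, structural_parameter = 4),
               class = "acthfcs_domain_error")
})

test_that("one-component model has the 1/N amplitude and correct shape", {
  expect_identical(one_component_model(0, 4, 220e-6), 1.25)
  # direct substitution at tau = tau_D, N = 1, s = 5
  expect_equal(one_component_model(220e-6, 1, 220e-6, 5),
               1 + 0.5 / sqrt(1 + 1 / 25), tolerance = 1e-12)
  expect_equal(one_component_model(220e-6, 1, 220e-6, 5), 1.49029,
               tolerance = 1e-5)
  # asymptote
  expect_equal(one_component_model(1e6 * 220e-6, 3, 220e-6), 1,
               tolerance = 1e-2)
  # monotone non-increasing in tau for random valid parameters
  set.seed(11)
  for (i in 1:20) {
    n <- runif(1, 0.5, 100)
    tau_d <- 10^runif(1, -5, -2)
    s <- runif(1, 3, 8)
    g <- one_component_model(default_lag_grid(), n, tau_d, s)
    expect_true(all(diff(g) <= 0))
  }
  expect_error(one_component_model(1e-3, -1, 220e-6),
               class = "acthfcs_domain_error")
  expect_error(one_component_model(-1e-3, 1, 220e-6),
               class = "acthfcs_domain_error")
})

test_that("two-component model reduces, mixes and preserves the amplitude", {
  lg <- default_lag_grid()
  # reduction at Y = 0 and Y = 1
  expect_equal(two_component_model(lg, 7, 0, 220e-6, 483e-6, 5),
               one_component_model(lg, 7, 220e-6, 5), tolerance = 1e-14)
  expect_equal(two_component_model(lg, 7, 1, 220e-6, 483e-6, 5),
               one_component_model(lg, 7, 483e-6, 5), tolerance = 1e-14)
  # amplitude independent of Y
  for (y in c(0, 0.25, 0.5, 1)) {
    expect_equal(two_component_model(0, 10, y, 220e-6, 483e-6), 1.1,
                 tolerance = 1e-14)
  }
  # frozen hand-evaluated mixture value
  expect_equal(two_component_model(220e-6, 10, 0.25, 220e-6, 483e-6, 5),
               1.053794, tolerance = 1e-6)
  # degenerate equal-dwell-time mixture collapses to one component for all Y
  set.seed(4)
  for (y in runif(5)) {
    expect_equal(two_component_model(lg, 5, y, 3e-4, 3e-4, 5),
                 one_component_model(lg, 5, 3e-4, 5), tolerance = 1e-14)
  }
  expect_error(two_component_model(1e-3, 10, 1.2, 220e-6, 483e-6),
               class = "acthfcs_domain_error")
})

test_that("particle-number/concentration conversion uses the tabulated conversion constant", {
  # denominator for the default volume is 30.115e7 per mol/l
  expect_equal(1 / particles_to_concentration(1), 30.115e7, tolerance = 1e-12)
  expect_equal(particles_to_concentration(1), 3.32e-9, tolerance = 2e-4)
  expect_identical(particles_to_concentration(0), 0)
  # 60 nM of labeled antibody corresponds to ~18.07 particles
  expect_equal(concentration_to_particles(60e-9), 18.069, tolerance = 1e-4)
  # linearity and 12-significant-digit round trip
  set.seed(2)
  cs <- 10^runif(10, -12, -6)
  expect_equal(particles_to_concentration(concentration_to_particles(cs)), cs,
               tolerance = 1e-12)
  expect_equal(particles_to_concentration(2 * concentration_to_particles(cs)),
               2 * cs, tolerance = 1e-12)
  expect_error(particles_to_concentration(-1), class = "acthfcs_domain_error")
})

test_that("diffusing_species enforces dwell-time/coefficient consistency", {
  vol <- confocal_volume()
  ok <- diffusing_species("IgG", d_coeff_cm2_s = 3.7e-7,
                          tau_d_s = diffusion_time_from_coefficient(3.7e-7, 0.17),
                          volume = vol)
  expect_s3_class(ok, "diffusing_species")
  expect_error(diffusing_species("IgG", d_coeff_cm2_s = 3.7e-7,
                                 tau_d_s = 300e-6, volume = vol),
               class = "acthfcs_domain_error")
})
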