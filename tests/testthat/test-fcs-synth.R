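# Synthetic-data generators, the Brownian-dynamics oracle and the
# multiple-tau correlator.

test_that("complete-capture stoichiometry sets the bound mole fraction", {
  proto <- assay_protocol()
  expect_equal(mole_fraction_from_capture(15e-9, proto), 0.25)
  expect_equal(mole_fraction_from_capture(0, proto), 0)
  # the 22-h CRH response concentration over the 60 nM labeled dose
  expect_equal(mole_fraction_from_capture(17.427e-9, proto), 0.29045)
  expect_error(mole_fraction_from_capture(70e-9, proto),
               class = "acthfcs_saturation_error")
})

test_that("protocol validation enforces the slow-complex ordering", {
  expect_error(assay_protocol(tau_free_s = 483e-6, tau_complex_s = 220e-6),
               class = "acthfcs_domain_error")
})

test_that("lag grid is quasi-logarithmic with doubling octaves", {
  lg <- default_lag_grid(1e-6, 1, 16)
  expect_true(all(diff(lg) > 0))
  expect_equal(lg[1], 1e-6)
  # spacing doubles from one octave to the next
  expect_equal(lg[18] - lg[17], 2 * (lg[2] - lg[1]), tolerance = 1e-12)
  expect_lte(max(lg), 1)
})

test_that("curve generation is exact at zero noise and seed-deterministic", {
  proto <- assay_protocol()
  lg <- default_lag_grid()
  exact <- generate_correlation_curve(18.069, 0.25, proto, lg, noise_scale = 0)
  expect_equal(exact$g,
               two_component_model(lg, 18.069, 0.25, 220e-6, 483e-6, 5),
               tolerance = 1e-14)
  a <- generate_correlation_curve(18.069, 0.25, proto, lg, 0.01, seed = 77)
  b <- generate_correlation_curve(18.069, 0.25, proto, lg, 0.01, seed = 77)
  expect_identical(a$g, b$g)
  c2 <- generate_correlation_curve(18.069, 0.25, proto, lg, 0.01, seed = 78)
  expect_false(identical(a$g, c2$g))
  expect_error(generate_correlation_curve(18, 0.25, proto, numeric(0)),
               class = "acthfcs_domain_error")
})

test_that("assay series carry the antibody-dose amplitude and are reproducible", {
  proto <- small_protocol(n_runs = 5)
  curves <- generate_assay_series(15e-9, proto, noise_scale = 0, seed = 1)
  expect_length(curves, 5)
  # amplitude ~ 1 + 1/18.07 set by the 60 nM labeled antibody dose
  expect_equal(curves[[1]]$g[1] - 1, 1 / 18.069, tolerance = 1e-2)
  s1 <- generate_assay_series(15e-9, proto, seed = 9)
  s2 <- generate_assay_series(15e-9, proto, seed = 9)
  expect_identical(lapply(s1, `[[`, "g"), lapply(s2, `[[`, "g"))
  # a zero-analyte series fits cleanly as a single component
  zero <- generate_assay_series(0, proto, seed = 10)
  f <- fit_one_component(zero[[1]])
  expect_true(f$converged)
  expect_equal(f$tau_d_s, 220e-6, tolerance = 0.05)
})

test_that("brownian simulator handles edge configurations", {
  vol <- confocal_volume()
  dark <- brownian_config(n_particles = 5L, brightness_cps = 0,
                          duration_s = 0.05)
  tr <- simulate_photon_trace(dark, vol)
  expect_true(all(tr$counts == 0))
  # an immobile emitter at the focus gives constant-rate shot noise only
  still <- brownian_config(n_particles = 1L, d_coeffs_cm2_s = 0,
                           brightness_cps = 2e5, time_step_s = 1e-5,
                           duration_s = 2,
                           init_positions_um = matrix(0, 1, 3))
  tr2 <- simulate_photon_trace(still, vol)
  expect_equal(mean(tr2$counts) / 1e-5, 2e5, tolerance = 0.05)
  ac <- multiple_tau_autocorrelate(tr2)
  expect_lt(max(abs(ac$g - 1)), 0.05)
  # determinism
  cfg <- brownian_config(duration_s = 0.02, seed = 3)
  expect_identical(simulate_photon_trace(cfg)$counts,
                   simulate_photon_trace(cfg)$counts)
  # invariant violations
  expect_error(simulate_photon_trace(
    brownian_config(box_lengths_um = c(1, 1, 8.8), duration_s = 0.01)),
    class = "acthfcs_config_error")
  expect_error(simulate_photon_trace(
    brownian_config(time_step_s = 1e-3, duration_s = 0.01)),
    class = "acthfcs_config_error")
})

test_that("multiple-tau estimator is flat for uncorrelated signals", {
  # constant trace
  const <- structure(list(bin_width_s = 1e-5,
                          counts = rep(7L, 2^12), duration_s = 2^12 * 1e-5),
                     class = "photon_trace")
  ac <- multiple_tau_autocorrelate(const)
  expect_true(all(abs(ac$g - 1) < 1e-12))
  expect_true(all(diff(ac$lags_s) > 0))
  # i.i.d. Poisson shot noise is delta-correlated: G(tau > 0) ~ 1
  set.seed(8)
  shot <- structure(list(bin_width_s = 1e-5,
                         counts = rpois(2^16, 2), duration_s = 2^16 * 1e-5),
                    class = "photon_trace")
  ac2 <- multiple_tau_autocorrelate(shot)
  expect_lt(max(abs(ac2$g - 1)), 0.05)
  short <- structure(list(bin_width_s = 1e-5, counts = rep(1L, 100),
                          duration_s = 1e-3), class = "photon_trace")
  expect_error(multiple_tau_autocorrelate(short),
               class = "acthfcs_domain_error")
})

test_that("a short simulated trace already matches the analytic model shape", {
  vol <- confocal_volume()
  cfg <- brownian_config(duration_s = 4, seed = 21)
  tr <- simulate_photon_trace(cfg, vol)
  ac <- multiple_tau_autocorrelate(tr)
  fit <- fit_one_component(ac)
  tau_d <- diffusion_time_from_coefficient(3.7e-7, vol$radial_r_um)
  n_eff <- 90 / prod(cfg$box_lengths_um) *
    simulator_effective_volume(vol) * 1e15
  expect_true(fit$converged)
  expect_equal(fit$tau_d_s, tau_d, tolerance = 0.2)
  expect_equal(fit$n_particles, n_eff, tolerance = 0.2)
})

test_that("correlation-curve CSV dialect round-trips", {
  cur <- generate_correlation_curve(18, 0.25, assay_protocol(),
                                    default_lag_grid(), 0.01, seed = 2)
  path <- tempfile(fileext = ".csv")
  write_correlation_csv(cur, path)
  back <- read_correlation_csv(path)
  expect_equal(back$lags_s, cur$lags_s, tolerance = 1e-12)
  expect_equal(back$g, cur$g, tolerance = 1e-12)
  expect_equal(back$stderr, cur$stderr, tolerance = 1e-12)
  expect_error(read_correlation_csv(tempfile()), class = "acthfcs_io_error")
})
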