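# The two HPA feedback models: structure, steady states, conservation,
# non-negativity and qualitative dose-response behaviour.

test_that("parameter sets validate names, bounds and positivity", {
  p <- hpa_parameters("extended")
  expect_true(all(p$value >= p$lower & p$value <= p$upper))
  expect_error(hpa_parameters("extended", values = c(bogus = 1)),
               class = "acthfcs_domain_error")
  expect_error(hpa_parameters("parsimonious", values = c(k_base = 1e9)),
               class = "acthfcs_domain_error")
})

test_that("scenarios carry the experimental arm definitions", {
  expect_equal(hpa_scenario("crh")$crh_dose_nM, 10)
  expect_equal(hpa_scenario("crh_cortisol")$cortisol_dose_nM, 100)
  expect_equal(hpa_scenario("basal")$t_obs_min, c(0, 1320))
  expect_equal(hpa_scenario("crh")$reference_nM, 15.016)
  expect_error(hpa_scenario("crh", t_obs_min = c(5, 10)),
               class = "acthfcs_domain_error")
})

test_that("right-hand sides reduce to pure production at the origin", {
  pp <- hpa_parameters("parsimonious")
  d <- unlist(parsimonious_rhs(0, c(0, 0), pp, hpa_scenario("basal")))
  expect_equal(d[["acth_ex"]], pp$value[["k_base"]])
  expect_equal(d[["gr"]], pp$value[["k_gr_basal"]])
  pe <- hpa_parameters("extended")
  de <- unlist(extended_rhs(0, rep(0, 11), pe, hpa_scenario("basal")))
  expect_equal(de[["gr_free"]], pe$value[["k_gr_syn"]])
  expect_equal(de[["pomc_mrna"]], pe$value[["k_tx0"]])
  expect_equal(de[["acth_ex"]], 0)
  expect_error(parsimonious_rhs(0, c(-1, 0), pp, hpa_scenario("basal")),
               class = "acthfcs_domain_error")
  expect_error(extended_rhs(0, rep(-1, 11), pe, hpa_scenario("basal")),
               class = "acthfcs_domain_error")
})

test_that("compiled and reference right-hand sides agree along trajectories", {
  for (model in c("parsimonious", "extended")) {
    p <- hpa_parameters(model)
    for (lab in c("crh", "crh_cortisol")) {
      sc <- hpa_scenario(lab)
      a <- simulate_hpa(model, sc, p)
      b <- simulate_hpa(model, sc, p, compiled = FALSE)
      expect_equal(a$pct_change, b$pct_change, tolerance = 1e-6)
    }
  }
})

test_that("steady state has vanishing derivatives and a unique basin", {
  for (model in c("parsimonious", "extended")) {
    p <- hpa_parameters(model)
    ss <- steady_state(model, p)
    expect_lt(attr(ss, "residual_norm"), 1e-10)
    # heuristic-start independence: random perturbed starts converge to the
    # same fixed point
    set.seed(17)
    for (k in 1:3) {
      start <- pmax(as.numeric(ss) * exp(rnorm(length(ss), sd = 1)), 1e-3)
      ss2 <- steady_state(model, p, start = start)
      expect_equal(as.numeric(ss2), as.numeric(ss), tolerance = 1e-6)
    }
  }
})

test_that("membrane-receptor totals are conserved along trajectories", {
  p <- hpa_parameters("extended")
  tr <- simulate_hpa("extended", hpa_scenario("crh_cortisol"), p,
                     t_grid_min = seq(0, 1320, by = 10))
  rc <- tr$states[, "rc_free"] + tr$states[, "rc_bound"]
  rg <- tr$states[, "rg_free"] + tr$states[, "rg_bound"]
  expect_lt(max(abs(rc - rc[1])) / rc[1], 1e-8)
  expect_lt(max(abs(rg - rg[1])) / rg[1], 1e-8)
})

test_that("states remain non-negative in all scenarios", {
  set.seed(23)
  for (model in c("parsimonious", "extended")) {
    base <- hpa_parameters(model)
    for (rep in 1:3) {
      vals <- base$value * exp(rnorm(length(base$value), sd = 0.3))
      vals <- pmin(pmax(vals, base$lower), base$upper)
      p <- hpa_parameters(model, values = vals)
      for (lab in c("basal", "crh", "crh_cortisol")) {
        tr <- simulate_hpa(model, hpa_scenario(lab), p,
                           t_grid_min = seq(0, 1320, by = 30))
        expect_gte(min(tr$states), -1e-12)
      }
    }
  }
})

test_that("integration is converged with respect to tolerances", {
  p <- hpa_parameters("extended")
  sc <- hpa_scenario("crh_cortisol")
  a <- simulate_hpa("extended", sc, p, rtol = 1e-8, atol = 1e-10)
  b <- simulate_hpa("extended", sc, p, rtol = 5e-9, atol = 5e-11)
  rel <- abs(a$acth_nM - b$acth_nM) / pmax(abs(b$acth_nM), 1e-6)
  expect_lt(max(rel), 1e-4)
  # t = 0 only: percent change is exactly zero
  expect_equal(simulate_hpa("extended", sc, p, t_grid_min = 0)$pct_change, 0)
})

test_that("percent change follows the observable convention", {
  expect_equal(percent_change(15.016, 15.016), 0)
  expect_equal(percent_change(1.0748 * 15.016, 15.016), 7.48, tolerance = 1e-10)
  x <- c(10, 15, 20)
  expect_equal(percent_change(2 * x - 15.016, 15.016),
               2 * percent_change(x, 15.016) + 100 * (15.016 - 2 * 15.016 + 15.016) / 15.016)
  expect_error(percent_change(10, -1), class = "acthfcs_domain_error")
})

test_that("CRH stimulates and cortisol suppresses the simulated response", {
  p <- hpa_parameters("extended")
  grid <- c(0, 1, 5, 15, 30, 60, 120, 360, 720, 1320)
  crh <- simulate_hpa("extended", hpa_scenario("crh"), p, grid)
  basal <- simulate_hpa("extended", hpa_scenario("basal"), p, grid)
  both <- simulate_hpa("extended", hpa_scenario("crh_cortisol"), p, grid)
  # CRH raises ACTH above basal, cortisol pulls it back down at all t >= 1
  sel <- grid >= 1
  expect_true(all(crh$pct_change[sel] > basal$pct_change[sel]))
  expect_true(all(both$pct_change[sel] < crh$pct_change[sel]))
  # ACTH rises monotonically under CRH alone
  expect_true(all(diff(crh$acth_nM) > 0))
  # 22-h response is non-increasing in the cortisol dose (0, 50, 100 nM)
  resp <- vapply(c(0, 50, 100), function(dose) {
    sc <- hpa_scenario("crh_cortisol", crh_dose_nM = 10,
                       cortisol_dose_nM = max(dose, 1e-12))
    simulate_hpa("extended", sc, p, c(0, 1320))$acth_nM[2]
  }, numeric(1))
  expect_true(all(diff(resp) < 0))
})

test_that("with fast saturating receptors the extended model approaches a
           parsimonious-style response", {
  # receptor steps made fast and saturating, fast feedback and genomic arm
  # inert; the extended secretory flux then reduces to a constant-production
  # balance that maps onto the parsimonious model with matched basal flux
  ext <- hpa_parameters("extended")
  ev <- ext$value
  ev[["k_on_crhr"]] <- ext$upper[["k_on_crhr"]]
  ev[["k_off_crhr"]] <- ext$lower[["k_off_crhr"]]
  ev[["k_tx_crh"]] <- ext$lower[["k_tx_crh"]]
  ev[["k_sec_crh"]] <- ext$lower[["k_sec_crh"]]
  ev[["k_sec0"]] <- 0.04
  ev[["k_dim"]] <- ext$lower[["k_dim"]]
  pe <- hpa_parameters("extended", values = ev)
  # long-run secretory flux with CRHR saturated: translation of the (slightly
  # CRHR-boosted) transcript equilibrium
  flux_ext <- ev[["k_transl"]] *
    (ev[["k_tx0"]] + ev[["k_tx_crh"]] * ev[["rc_tot"]] /
       (ev[["K_tx"]] + ev[["rc_tot"]])) / ev[["k_mrna_deg"]]
  pars <- hpa_parameters("parsimonious")
  pv <- pars$value
  pv[["k_acth_deg"]] <- pars$lower[["k_acth_deg"]]
  pv[["k_crh"]] <- pars$lower[["k_crh"]]
  pv[["k_crh_dec"]] <- 2
  pv[["k_base"]] <- flux_ext + pv[["k_acth_deg"]] * 15.016
  pp <- hpa_parameters("parsimonious", values = pv)
  grid <- c(0, 1, 5, 15, 30, 60, 120, 360, 720, 1320)
  a <- simulate_hpa("extended", hpa_scenario("crh"), pe, grid)
  b <- simulate_hpa("parsimonious", hpa_scenario("crh"), pp, grid)
  expect_lt(max(abs(a$pct_change - b$pct_change)),
            0.05 * max(abs(b$pct_change)))
})
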