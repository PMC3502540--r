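# The two ODE models of glucocorticoid feedback on ACTH secretion in
# anterior pituitary cells, with scenario handling for the in-vitro
# experiments. Units are minutes and nM throughout. Extracellular CRH and
# cortisol are algebraic inputs dose * exp(-k_dec * t): with the default
# near-zero decay rates this is a clamp (closed culture well), while a
# fitted decay rate represents ligand degradation in the medium.

PARSIMONIOUS_PARAM_NAMES <- c(
  "k_base", "k_crh", "k_acth_deg", "K_i", "k_gr_up", "K_gr",
  "k_gr_basal", "k_gr_deg", "k_crh_dec", "k_cort_dec")

EXTENDED_PARAM_NAMES <- c(
  "k_on_crhr", "k_off_crhr", "k_on_gpcr", "k_off_gpcr", "k_cort_in",
  "k_cort_deg", "k_gr_on", "k_gr_off", "k_gr_syn", "k_gr_deg", "k_dim",
  "k_dn_clear", "k_tx0", "k_tx_crh", "K_tx", "K_rep", "k_mrna_deg",
  "k_transl", "k_sec0", "k_sec_crh", "K_sec_inh", "k_acth_loss",
  "k_crh_dec", "k_cort_dec", "rc_tot", "rg_tot")

PARSIMONIOUS_STATE_NAMES <- c("acth_ex", "gr")
EXTENDED_STATE_NAMES <- c(
  "rc_free", "rc_bound", "rg_free", "rg_bound", "cort_in", "gr_free",
  "gr_cort", "gr_dimer_nuc", "pomc_mrna", "acth_pool", "acth_ex")

# compartment tag per state, extracellular ACTH being the measured observable
EXTENDED_STATE_COMPARTMENTS <- c(
  rc_free = "membrane", rc_bound = "membrane", rg_free = "membrane",
  rg_bound = "membrane", cort_in = "intracellular", gr_free = "intracellular",
  gr_cort = "intracellular", gr_dimer_nuc = "nucleus",
  pomc_mrna = "intracellular", acth_pool = "intracellular",
  acth_ex = "extracellular")

hpa_default_values <- function(model) {
  if (model == "parsimonious") {
    c(k_base = 0.064,     # basal ACTH production, nM/min
      k_crh = 0.11,       # CRH-stimulated production, 1/min per nM CRH
      k_acth_deg = 0.004, # extracellular ACTH turnover, 1/min
      K_i = 500,          # cortisol-GR inhibition constant, nM^2
      k_gr_up = 0.1,      # dimer-driven GR up-regulation, nM/min
      K_gr = 1000,        # half-saturation of GR up-regulation, nM^2
      k_gr_basal = 0.064, # basal GR production, nM/min
      k_gr_deg = 0.004,   # GR turnover, 1/min
      k_crh_dec = 1e-3,   # CRH degradation in the medium, 1/min
      k_cort_dec = 1e-3)  # cortisol degradation in the medium, 1/min
  } else {
    c(k_on_crhr = 0.5,    # CRH-CRHR association, 1/(nM min)
      k_off_crhr = 1,     # CRHR dissociation, 1/min
      k_on_gpcr = 0.5,    # cortisol-GPCR association, 1/(nM min)
      k_off_gpcr = 1,     # GPCR dissociation, 1/min
      k_cort_in = 0.05,   # cortisol membrane passage, 1/min
      k_cort_deg = 0.05,  # intracellular cortisol clearance, 1/min
      k_gr_on = 0.01,     # cortisol-GR binding, 1/(nM min)
      k_gr_off = 0.1,     # GR complex dissociation, 1/min
      k_gr_syn = 0.5,     # GR synthesis, nM/min
      k_gr_deg = 0.05,    # free GR turnover, 1/min
      k_dim = 0.01,       # GR-complex dimerization, 1/(nM min)
      k_dn_clear = 0.005, # nuclear dimer clearance, 1/min
      k_tx0 = 0.01,       # basal POMC transcription, nM/min
      k_tx_crh = 0.02,    # CRHR-stimulated transcription, nM/min
      K_tx = 2,           # CRHR occupancy half-saturation, nM
      K_rep = 5,          # nuclear-dimer repression constant, nM
      k_mrna_deg = 0.01,  # transcript turnover, 1/min
      k_transl = 8.5e-4,  # translation/pool filling, 1/min
      k_sec0 = 4e-4,      # basal secretion rate coefficient, 1/min
      k_sec_crh = 0.02,   # CRHR-stimulated secretion, 1/(nM min)
      K_sec_inh = 3,      # GPCR-occupancy secretion inhibition, nM
      k_acth_loss = 1e-6, # extracellular ACTH loss, 1/min
      k_crh_dec = 1e-4,   # CRH degradation in the medium, 1/min
      k_cort_dec = 1e-4,  # cortisol degradation in the medium, 1/min
      rc_tot = 10,        # total membrane CRHR, nM
      rg_tot = 10)        # total membrane GPCR, nM
  }
}

hpa_default_bounds <- function(model, ref) {
  lower <- ref / 100
  upper <- ref * 100
  special_lower <- c(k_crh_dec = 1e-6, k_cort_dec = 1e-6, k_acth_loss = 1e-8)
  special_upper <- c(k_crh_dec = 2, k_cort_dec = 2, k_acth_loss = 1e-3)
  if (model == "extended") {
    special_lower <- c(special_lower, rc_tot = 1, rg_tot = 1)
    special_upper <- c(special_upper, rc_tot = 100, rg_tot = 100)
  }
  for (nm in names(special_lower)) {
    if (nm %in% names(lower)) lower[nm] <- special_lower[nm]
  }
  for (nm in names(special_upper)) {
    if (nm %in% names(upper)) upper[nm] <- special_upper[nm]
  }
  list(lower = lower, upper = upper)
}

#' Named parameter set of an HPA feedback model
#'
#' Holds the rate and affinity constants of one of the two models together
#' with box bounds (used by the global search) and the reference values that
#' anchor the Tikhonov regularization. Values must lie within their bounds.
#'
#' @param model `"parsimonious"` (four-species genomic-feedback-only model)
#'   or `"extended"` (three-compartment model with membrane CRH and
#'   glucocorticoid receptors).
#' @param values optional named numeric vector overriding some or all
#'   default values.
#' @param lower,upper optional named vectors overriding default bounds.
#' @param ref optional named vector of regularization reference values;
#'   defaults to the package default values.
#' @return An object of class `hpa_parameters` with fields `model`, `value`,
#'   `lower`, `upper`, `ref`.
#' @export
hpa_parameters <- function(model = c("extended", "parsimonious"),
                           values = NULL, lower = NULL, upper = NULL,
                           ref = NULL) {
  model <- match.arg(model)
  value <- hpa_default_values(model)
  bounds <- hpa_default_bounds(model, value)
  ref_full <- value
  if (!is.null(values)) {
    bad <- setdiff(names(values), names(value))
    if (length(bad)) abort_domain(paste("unknown parameter(s):",
                                        paste(bad, collapse = ", ")))
    value[names(values)] <- values
  }
  if (!is.null(lower)) bounds$lower[names(lower)] <- lower
  if (!is.null(upper)) bounds$upper[names(upper)] <- upper
  if (!is.null(ref)) ref_full[names(ref)] <- ref
  if (any(value < bounds$lower - 1e-12) || any(value > bounds$upper + 1e-12)) {
    abort_domain("parameter values must lie within their bounds")
  }
  if (any(bounds$lower <= 0)) {
    abort_domain("all parameter bounds must be strictly positive")
  }
  structure(list(model = model, value = value, lower = bounds$lower,
                 upper = bounds$upper, ref = ref_full),
            class = "hpa_parameters")
}

#' @export
print.hpa_parameters <- function(x, ...) {
  cat(sprintf("HPA %s-model parameter set (%d parameters)\n", x$model,
              length(x$value)))
  print(data.frame(value = x$value, lower = x$lower, upper = x$upper,
                   ref = x$ref))
  invisible(x)
}

#' Experimental scenario for one arm of the in-vitro experiment
#'
#' Doses applied at t = 0 to anterior pituitary cells in a closed well, the
#' observation time grid and the t = 0 extracellular ACTH reference
#' concentration used for percent-change observables.
#'
#' @param label `"basal"` (no doses), `"crh"` (10 nM CRH) or
#'   `"crh_cortisol"` (10 nM CRH + 100 nM cortisol); doses default by label.
#' @param crh_dose_nM,cortisol_dose_nM doses in nM (override the label
#'   defaults).
#' @param t_obs_min increasing observation times in minutes starting at 0.
#' @param reference_nM extracellular ACTH at t = 0 (nM); default 15.016, the
#'   measured basal concentration.
#' @return An object of class `hpa_scenario`.
#' @export
hpa_scenario <- function(label = c("basal", "crh", "crh_cortisol"),
                         crh_dose_nM = NULL, cortisol_dose_nM = NULL,
                         t_obs_min = NULL, reference_nM = 15.016) {
  label <- match.arg(label)
  defaults <- switch(label,
                     basal = c(0, 0),
                     crh = c(10, 0),
                     crh_cortisol = c(10, 100))
  if (is.null(crh_dose_nM)) crh_dose_nM <- defaults[1]
  if (is.null(cortisol_dose_nM)) cortisol_dose_nM <- defaults[2]
  if (crh_dose_nM < 0 || cortisol_dose_nM < 0) abort_domain("doses must be >= 0")
  if (is.null(t_obs_min)) {
    t_obs_min <- if (label == "basal") c(0, 1320) else
      c(0, 1, 5, 15, 30, 60, 120, 1320)
  }
  if (t_obs_min[1] != 0 || any(diff(t_obs_min) <= 0)) {
    abort_domain("'t_obs_min' must be increasing and start at 0")
  }
  check_positive(reference_nM = reference_nM)
  structure(list(label = label, crh_dose_nM = crh_dose_nM,
                 cortisol_dose_nM = cortisol_dose_nM, t_obs_min = t_obs_min,
                 reference_nM = reference_nM),
            class = "hpa_scenario")
}

check_state <- function(state, names_expected) {
  if (length(state) != length(names_expected)) {
    abort_domain(sprintf("state must have %d components", length(names_expected)))
  }
  if (any(state < -1e-8)) abort_domain("negative state")
  invisible(TRUE)
}

scenario_inputs <- function(t, params, scenario) {
  v <- params$value
  list(crh = scenario$crh_dose_nM * exp(-v[["k_crh_dec"]] * t),
       cort = scenario$cortisol_dose_nM * exp(-v[["k_cort_dec"]] * t))
}

#' Right-hand side of the parsimonious HPA model
#'
#' The four-species genomic-feedback model: ACTH production is stimulated
#' linearly by extracellular CRH and repressed by the cortisol-bound
#' glucocorticoid receptor (the dimerizing transcription factor); GR
#' production carries a positive feedback term quadratic in the cortisol-GR
#' complex. In vitro, extracellular CRH and cortisol are inputs (clamped at
#' their doses up to first-order degradation in the medium) and adrenal
#' cortisol production is absent, leaving extracellular ACTH and GR as
#' dynamic states.
#'
#' @param t time in minutes.
#' @param state named or ordered vector `(acth_ex, gr)` in nM (>= 0).
#' @param params an `hpa_parameters` for the parsimonious model.
#' @param scenario an [hpa_scenario()].
#' @return List with the derivative vector, deSolve-style.
#' @export
parsimonious_rhs <- function(t, state, params, scenario) {
  stopifnot(params$model == "parsimonious")
  check_state(state, PARSIMONIOUS_STATE_NAMES)
  v <- params$value
  inp <- scenario_inputs(t, params, scenario)
  A <- state[[1]]; R <- state[[2]]
  occ <- inp$cort * R
  dA <- (v[["k_base"]] + v[["k_crh"]] * inp$crh) / (1 + occ / v[["K_i"]]) -
    v[["k_acth_deg"]] * A
  dR <- v[["k_gr_up"]] * occ^2 / (v[["K_gr"]]^2 + occ^2) + v[["k_gr_basal"]] -
    v[["k_gr_deg"]] * R
  list(setNames(c(dA, dR), PARSIMONIOUS_STATE_NAMES))
}

#' Right-hand side of the extended three-compartment receptor model
#'
#' Compartmental model of an anterior pituitary cell: extracellular CRH
#' binds the membrane CRH receptor (CRHR) and extracellular cortisol the
#' membrane G-protein-coupled receptor (GPCR), both by mass action. Bound
#' CRHR stimulates POMC transcription (saturating) and ACTH secretion
#' (linear); bound GPCR inhibits secretion — the fast non-genomic feedback.
#' Cortisol also passes the membrane, binds the intracellular glucocorticoid
#' receptor, the complex dimerizes and the nuclear dimer represses
#' transcription with a Hill coefficient of 2 — the slow genomic feedback.
#' A releasable ACTH pool is filled from the transcript and secreted into
#' the extracellular space, which accumulates ACTH with a small first-order
#' loss.
#'
#' @param t time in minutes.
#' @param state vector of the 11 states (see `EXTENDED_STATE_NAMES`), nM.
#' @param params an `hpa_parameters` for the extended model.
#' @param scenario an [hpa_scenario()].
#' @return List with the derivative vector, deSolve-style.
#' @export
extended_rhs <- function(t, state, params, scenario) {
  stopifnot(params$model == "extended")
  check_state(state, EXTENDED_STATE_NAMES)
  v <- params$value
  inp <- scenario_inputs(t, params, scenario)
  s <- setNames(as.numeric(state), EXTENDED_STATE_NAMES)

  bind_c <- v[["k_on_crhr"]] * inp$crh * s[["rc_free"]] -
    v[["k_off_crhr"]] * s[["rc_bound"]]
  bind_g <- v[["k_on_gpcr"]] * inp$cort * s[["rg_free"]] -
    v[["k_off_gpcr"]] * s[["rg_bound"]]
  bind_gr <- v[["k_gr_on"]] * s[["cort_in"]] * s[["gr_free"]] -
    v[["k_gr_off"]] * s[["gr_cort"]]

  tx <- (v[["k_tx0"]] + v[["k_tx_crh"]] * s[["rc_bound"]] /
           (v[["K_tx"]] + s[["rc_bound"]])) /
    (1 + (s[["gr_dimer_nuc"]] / v[["K_rep"]])^2)
  sec_rate <- (v[["k_sec0"]] + v[["k_sec_crh"]] * s[["rc_bound"]]) /
    (1 + s[["rg_bound"]] / v[["K_sec_inh"]])
  secretion <- sec_rate * s[["acth_pool"]]

  d <- c(
    rc_free = -bind_c,
    rc_bound = bind_c,
    rg_free = -bind_g,
    rg_bound = bind_g,
    cort_in = v[["k_cort_in"]] * inp$cort - v[["k_cort_deg"]] * s[["cort_in"]] - bind_gr,
    gr_free = v[["k_gr_syn"]] - v[["k_gr_deg"]] * s[["gr_free"]] - bind_gr,
    gr_cort = bind_gr - 2 * v[["k_dim"]] * s[["gr_cort"]]^2,
    gr_dimer_nuc = v[["k_dim"]] * s[["gr_cort"]]^2 -
      v[["k_dn_clear"]] * s[["gr_dimer_nuc"]],
    pomc_mrna = tx - v[["k_mrna_deg"]] * s[["pomc_mrna"]],
    acth_pool = v[["k_transl"]] * s[["pomc_mrna"]] - secretion,
    acth_ex = secretion - v[["k_acth_loss"]] * s[["acth_ex"]])
  list(d)
}

# Closed-form zero-dose fixed point of the cellular states; extracellular
# ACTH is pinned to the scenario reference (it is an accumulating observable
# with no feedback on the cell).
basal_state <- function(params, reference_nM) {
  v <- params$value
  if (params$model == "parsimonious") {
    setNames(c(reference_nM, v[["k_gr_basal"]] / v[["k_gr_deg"]]),
             PARSIMONIOUS_STATE_NAMES)
  } else {
    mrna <- v[["k_tx0"]] / v[["k_mrna_deg"]]
    pool <- v[["k_transl"]] * mrna / v[["k_sec0"]]
    setNames(c(v[["rc_tot"]], 0, v[["rg_tot"]], 0, 0,
               v[["k_gr_syn"]] / v[["k_gr_deg"]], 0, 0, mrna, pool,
               reference_nM),
             EXTENDED_STATE_NAMES)
  }
}

hpa_state_names <- function(model) {
  if (model == "parsimonious") PARSIMONIOUS_STATE_NAMES else EXTENDED_STATE_NAMES
}

hpa_rhs_fun <- function(model) {
  if (model == "parsimonious") parsimonious_rhs else extended_rhs
}

#' Steady state of an HPA model under constant (zero-dose) inputs
#'
#' Finds the fixed point of the cellular dynamics by long integration from a
#' heuristic start followed by a damped Newton polish with a finite-difference
#' Jacobian. Extracellular ACTH is a pure accumulator of the secretory flux
#' (its feedback on the cell is absent and its loss rate is ~0 by default),
#' so it has no equilibrium of its own: it is pinned to the scenario
#' reference concentration and excluded from the residual; all other states
#' are equilibrated to a residual norm below 1e-10.
#'
#' @param model `"extended"` or `"parsimonious"`.
#' @param params an `hpa_parameters`.
#' @param scenario an [hpa_scenario()]; its doses define the constant inputs
#'   (use a zero-dose scenario for the basal state).
#' @param start optional named start vector for the heuristic integration.
#' @return Named state vector of class `hpa_state` with attributes
#'   `residual_norm` and `equilibrated` (logical per state).
#' @export
steady_state <- function(model = c("extended", "parsimonious"), params,
                         scenario = hpa_scenario("basal"), start = NULL) {
  model <- match.arg(model)
  stopifnot(params$model == model)
  nm <- hpa_state_names(model)
  rhs <- hpa_rhs_fun(model)
  # constant inputs: freeze the medium-degradation rates at zero
  frozen <- params
  frozen$value[c("k_crh_dec", "k_cort_dec")] <- 0
  deriv <- function(s) unlist(rhs(0, s, frozen, scenario))

  ex_idx <- match("acth_ex", nm)
  free_idx <- setdiff(seq_along(nm), ex_idx)
  if (is.null(start)) start <- basal_state(params, scenario$reference_nM)
  start <- setNames(pmax(as.numeric(start), 0), nm)
  if (model == "extended") {
    # receptor totals are conserved quantities fixed by the parameter set;
    # project any user-supplied start onto the physical conservation surface
    for (pair in list(c("rc_free", "rc_bound", "rc_tot"),
                      c("rg_free", "rg_bound", "rg_tot"))) {
      tot <- params$value[[pair[3]]]
      cur <- start[pair[1]] + start[pair[2]]
      if (cur > 0) {
        start[pair[1:2]] <- start[pair[1:2]] * tot / cur
      } else {
        start[pair[1]] <- tot
        start[pair[2]] <- 0
      }
    }
  }

  # heuristic: relax by integration first
  traj <- deSolve::ode(y = start, times = c(0, 1e4, 5e4), func = function(t, y, p) {
    d <- deriv(y)
    d[ex_idx] <- 0
    list(d)
  }, parms = NULL, method = "lsoda", rtol = 1e-10, atol = 1e-12)
  s <- setNames(as.numeric(traj[nrow(traj), -1]), nm)
  s[ex_idx] <- scenario$reference_nM

  # damped Newton polish on the equilibrated subset
  for (iter in 1:100) {
    f <- deriv(s)[free_idx]
    if (sqrt(sum(f^2)) < 1e-12) break
    jac <- matrix(0, length(free_idx), length(free_idx))
    for (j in seq_along(free_idx)) {
      h <- max(1e-8, 1e-8 * abs(s[free_idx[j]]))
      sp <- s
      sp[free_idx[j]] <- sp[free_idx[j]] + h
      jac[, j] <- (deriv(sp)[free_idx] - f) / h
    }
    step <- tryCatch(solve(jac, -f), error = function(e)
      tryCatch(solve(jac + 1e-10 * diag(nrow(jac)), -f),
               error = function(e2) NULL))
    if (is.null(step)) break
    lam <- 1
    repeat {
      s_new <- s
      s_new[free_idx] <- pmax(s[free_idx] + lam * step, 0)
      if (sqrt(sum(deriv(s_new)[free_idx]^2)) < sqrt(sum(f^2)) || lam < 1e-4) break
      lam <- lam / 2
    }
    s <- s_new
  }
  res <- sqrt(sum(deriv(s)[free_idx]^2))
  if (res >= 1e-10) {
    stop(errorCondition(sprintf(
      "no steady state found: residual norm %.3g >= 1e-10", res),
      class = c("acthfcs_steady_state_error", "acthfcs_error")))
  }
  structure(s, residual_norm = res,
            equilibrated = setNames(seq_along(nm) %in% free_idx, nm),
            class = c("hpa_state", "numeric"))
}

#' Simulate an HPA model for one experimental scenario
#'
#' Integrates the chosen model from the basal initial state (cellular states
#' at their zero-dose fixed point, extracellular ACTH at the scenario
#' reference concentration) with the scenario doses applied at t = 0, using
#' the stiff-capable lsoda integrator on the package's compiled right-hand
#' sides (relative tolerance 1e-8). Returns the state trajectory plus the
#' extracellular-ACTH observables in nM and as percent change versus the
#' reference.
#'
#' @param model `"extended"` or `"parsimonious"`.
#' @param scenario an [hpa_scenario()].
#' @param params an `hpa_parameters` of matching model.
#' @param t_grid_min output times in minutes (default the scenario's
#'   observation grid); 0 is always included internally.
#' @param rtol,atol integrator tolerances.
#' @param compiled use the compiled rhs (default); `FALSE` integrates the
#'   reference R implementation instead.
#' @param init_state optional initial state overriding the basal default.
#' @return An object of class `hpa_trajectory` with fields `times_min`,
#'   `states` (matrix), `acth_nM`, `pct_change`, `scenario`, `diagnostics`.
#' @export
simulate_hpa <- function(model = c("extended", "parsimonious"), scenario,
                         params, t_grid_min = NULL, rtol = 1e-8, atol = 1e-10,
                         compiled = TRUE, init_state = NULL) {
  model <- match.arg(model)
  stopifnot(inherits(scenario, "hpa_scenario"), params$model == model)
  if (any(params$value < params$lower - 1e-12) ||
      any(params$value > params$upper + 1e-12)) {
    abort_domain("parameter values outside their bounds")
  }
  nm <- hpa_state_names(model)
  if (is.null(t_grid_min)) t_grid_min <- scenario$t_obs_min
  times <- unique(sort(c(0, t_grid_min)))
  if (length(times) == 1) times <- c(0, 1e-6)  # grid {0}: no integration needed
  y0 <- if (is.null(init_state)) basal_state(params, scenario$reference_nM) else
    setNames(as.numeric(init_state), nm)

  out <- if (compiled) {
    pvec <- c(unname(params$value[if (model == "parsimonious")
      PARSIMONIOUS_PARAM_NAMES else EXTENDED_PARAM_NAMES]),
      scenario$crh_dose_nM, scenario$cortisol_dose_nM)
    deSolve::ode(y = y0, times = times,
                 func = paste0("acthfcs_derivs_", model),
                 parms = pvec, dllname = "acthfcs",
                 initfunc = paste0("acthfcs_init_", model),
                 method = "lsoda", rtol = rtol, atol = atol, maxsteps = 50000)
  } else {
    rhs <- hpa_rhs_fun(model)
    deSolve::ode(y = y0, times = times,
                 func = function(t, y, p) rhs(t, y, params, scenario),
                 parms = NULL, method = "lsoda", rtol = rtol, atol = atol,
                 maxsteps = 50000)
  }
  diagn <- attributes(out)[c("istate", "rstate")]
  if (attr(out, "istate")[1] < 0 || nrow(out) < length(times)) {
    stop(errorCondition("ODE integration failed",
                        class = c("acthfcs_integration_error", "acthfcs_error")))
  }
  states <- out[, -1, drop = FALSE]
  colnames(states) <- nm
  keep <- out[, 1] %in% t_grid_min
  states <- states[keep, , drop = FALSE]
  tt <- out[keep, 1]
  acth <- unname(pmax(states[, "acth_ex"], 0))
  structure(list(times_min = tt, states = states, acth_nM = acth,
                 pct_change = percent_change(acth, scenario$reference_nM),
                 scenario = scenario, diagnostics = diagn),
            class = "hpa_trajectory")
}

#' @export
print.hpa_trajectory <- function(x, ...) {
  cat(sprintf("HPA trajectory, scenario '%s': %d time points, ACTH %.3f -> %.3f nM (%+.2f%%)\n",
              x$scenario$label, length(x$times_min), x$acth_nM[1],
              x$acth_nM[length(x$acth_nM)],
              x$pct_change[length(x$pct_change)]))
  invisible(x)
}

#' Percent change of a concentration series versus a reference
#'
#' 100 * (c(t) - reference) / reference, the observable convention of the
#' packaged time-course data.
#'
#' @param x numeric concentration series, or an `hpa_trajectory` (its
#'   extracellular ACTH is used).
#' @param reference reference concentration (> 0), same units as `x`.
#' @return Numeric percent-change series.
#' @export
percent_change <- function(x, reference) {
  check_positive(reference = reference)
  if (inherits(x, "hpa_trajectory")) x <- x$acth_nM
  100 * (x - reference) / reference
}
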