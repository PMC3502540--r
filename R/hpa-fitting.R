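# Tikhonov-regularized parameter estimation for the HPA models: a genetic
# search in log-parameter space followed by bounded local refinement, and
# the parsimonious-vs-extended model comparison across dataset combinations.

#' Fitting dataset for one experimental arm
#'
#' Percent-change time course with per-point deviations, tied to the
#' matching dose scenario.
#'
#' @param label scenario label (`"basal"`, `"crh"`, `"crh_cortisol"`).
#' @param times_min observation times in minutes.
#' @param pct_change measured percent change of extracellular ACTH.
#' @param deviation positive per-point deviations (same units).
#' @param reference_nM reference concentration for percent change.
#' @return An object of class `fit_dataset` with an attached
#'   [hpa_scenario()] and the concentrations implied by the percent changes.
#' @export
fit_dataset <- function(label, times_min, pct_change, deviation,
                        reference_nM = 15.016) {
  if (length(times_min) != length(pct_change) ||
      length(times_min) != length(deviation)) {
    abort_domain("'times_min', 'pct_change', 'deviation' must have equal length")
  }
  if (any(deviation <= 0)) abort_domain("deviations must be > 0")
  scen <- hpa_scenario(label, t_obs_min = unique(sort(c(0, times_min))),
                       reference_nM = reference_nM)
  structure(list(label = label, times_min = times_min,
                 pct_change = pct_change, deviation = deviation,
                 conc_nM = pct_to_concentration(pct_change, reference_nM),
                 scenario = scen),
            class = "fit_dataset")
}

#' Convert percent change back to absolute concentration
#'
#' c = reference * (1 + pct / 100); the inverse of [percent_change()].
#'
#' @param pct_change percent-change values.
#' @param reference_nM reference concentration.
#' @return Concentrations, same units as the reference.
#' @export
pct_to_concentration <- function(pct_change, reference_nM) {
  check_positive(reference_nM = reference_nM)
  reference_nM * (1 + pct_change / 100)
}

#' Build the three packaged FCS fitting datasets
#'
#' Turns the packaged time-course table into the basal, CRH and
#' CRH+cortisol [fit_dataset()]s (FCS percent-change columns with their
#' deviations; the ELISA columns are validation fixtures and are not fitted).
#'
#' @param table2 data frame from [load_table2()].
#' @param reference_nM percent-change reference concentration.
#' @return Named list of three `fit_dataset` objects.
#' @export
table2_fit_datasets <- function(table2 = load_table2(),
                                reference_nM = 15.016) {
  arms <- c("basal", "crh", "crh_cortisol")
  out <- lapply(arms, function(a) {
    sub <- table2[table2$arm == a, ]
    fit_dataset(a, sub$time_min, sub$fcs_pct, sub$fcs_dev, reference_nM)
  })
  setNames(out, arms)
}

simulate_for_dataset <- function(model, values, ds, params_template) {
  p <- params_template
  p$value[names(values)] <- values
  simulate_hpa(model, ds$scenario, p, t_grid_min = ds$times_min)
}

#' Tikhonov-regularized fitting objective
#'
#' Weighted least squares of the model percent change against the data,
#' plus a Tikhonov penalty on the log-distance of the parameters from their
#' reference values:
#' `sum_ds sum_t ((model - data) / deviation)^2 + alpha * sum_j (log p_j - log p_ref_j)^2`.
#' An integration failure yields a large finite penalty (1e8) rather than an
#' error, so global searches can pass through pathological parameter
#' regions.
#'
#' @param values named vector of parameter values (full or partial; the
#'   remainder is taken from `params`).
#' @param model `"extended"` or `"parsimonious"`.
#' @param datasets list of [fit_dataset()]s.
#' @param alpha regularization weight (>= 0).
#' @param params an `hpa_parameters` supplying fixed values, bounds and the
#'   regularization reference.
#' @return Scalar objective value.
#' @export
tikhonov_objective <- function(values, model, datasets, alpha = 1e-3,
                               params = hpa_parameters(model)) {
  if (alpha < 0) abort_domain("'alpha' must be >= 0")
  full <- params$value
  full[names(values)] <- values
  data_term <- 0
  for (ds in datasets) {
    traj <- tryCatch(
      simulate_for_dataset(model, full, ds, params),
      error = function(e) NULL)
    if (is.null(traj) || any(!is.finite(traj$pct_change))) return(1e8)
    mod <- traj$pct_change[match(ds$times_min, traj$times_min)]
    data_term <- data_term + sum(((mod - ds$pct_change) / ds$deviation)^2)
  }
  reg <- alpha * sum((log(full) - log(params$ref))^2)
  data_term + reg
}

# --- genetic search in log-parameter space --------------------------------

ga_search <- function(obj_log, lb, ub, population, generations, seed,
                      patience = 30, ref_log = NULL) {
  set.seed(as.integer(seed))
  d <- length(lb)
  pop <- matrix(runif(population * d, lb, ub), nrow = population, byrow = TRUE)
  if (!is.null(ref_log)) {
    # seed half the population near the reference point
    n_ref <- population %/% 2
    pop[seq_len(n_ref), ] <- matrix(rep(ref_log, n_ref), nrow = n_ref,
                                    byrow = TRUE) +
      matrix(rnorm(n_ref * d, sd = 0.5), nrow = n_ref)
    pop <- pmin(pmax(pop, matrix(lb, population, d, byrow = TRUE)),
                matrix(ub, population, d, byrow = TRUE))
  }
  fitness <- apply(pop, 1, obj_log)
  init_median <- median(fitness)
  best_hist <- numeric(0)
  stall <- 0
  for (gen in seq_len(generations)) {
    ord <- order(fitness)
    elite <- pop[ord[1:2], , drop = FALSE]
    sdm <- 0.4 * (1 - gen / generations) + 0.05
    # tournament selection (size 2)
    i1 <- sample.int(population, population, replace = TRUE)
    i2 <- sample.int(population, population, replace = TRUE)
    winners <- ifelse(fitness[i1] <= fitness[i2], i1, i2)
    parents <- pop[winners, , drop = FALSE]
    mates <- parents[sample.int(population), , drop = FALSE]
    cross <- matrix(runif(population * d) < 0.5, population, d)
    children <- ifelse(cross, parents, mates)
    mut <- matrix(runif(population * d) < 0.2, population, d)
    children <- children + mut * matrix(rnorm(population * d, sd = sdm),
                                        population, d)
    children <- pmin(pmax(children, matrix(lb, population, d, byrow = TRUE)),
                     matrix(ub, population, d, byrow = TRUE))
    children[1:2, ] <- elite
    child_fit <- c(fitness[ord[1:2]], apply(children[-(1:2), , drop = FALSE],
                                            1, obj_log))
    improved <- min(child_fit) < min(fitness) - 1e-9
    pop <- children
    fitness <- child_fit
    best_hist <- c(best_hist, min(fitness))
    stall <- if (improved) 0 else stall + 1
    if (stall >= patience) break
  }
  ibest <- which.min(fitness)
  list(par = pop[ibest, ], value = fitness[ibest], history = best_hist,
       init_median = init_median)
}

#' Global fit of an HPA model to one or more datasets
#'
#' Genetic search over the free parameters in log space within their bounds
#' (tournament selection, uniform crossover, annealed Gaussian mutation,
#' two-member elitism — so the best objective is non-increasing across
#' generations; the search stops early after 30 stalled generations),
#' followed by bounded local refinement (L-BFGS-B) from the best individual.
#' Deterministic for a given seed.
#'
#' @param model `"extended"` or `"parsimonious"`.
#' @param datasets list of [fit_dataset()]s to fit jointly.
#' @param population population size (>= 10).
#' @param generations maximum number of generations.
#' @param alpha Tikhonov regularization weight.
#' @param seed integer seed.
#' @param free character vector of parameter names to fit (default: all);
#'   the rest stay fixed at `params$value`.
#' @param params an `hpa_parameters` with starting values, bounds and
#'   regularization reference.
#' @param local_refine run the local refinement stage (default `TRUE`).
#' @return An object of class `hpa_fit` with fields `params` (best full
#'   parameter set), `objective`, `per_scenario_rms`, `n_evaluations`,
#'   `seed`, `converged`, `history`, `model`, `alpha`.
#' @export
global_fit <- function(model = c("extended", "parsimonious"), datasets,
                       population = 200, generations = 100, alpha = 1e-3,
                       seed = 1, free = NULL,
                       params = hpa_parameters(model), local_refine = TRUE) {
  model <- match.arg(model)
  if (population < 10) abort_domain("'population' must be >= 10")
  if (is.null(free)) free <- names(params$value)
  stopifnot(all(free %in% names(params$value)))
  lb <- log(params$lower[free])
  ub <- log(params$upper[free])
  n_eval <- 0L
  obj_log <- function(lp) {
    n_eval <<- n_eval + 1L
    tikhonov_objective(setNames(exp(lp), free), model, datasets, alpha, params)
  }
  ga <- ga_search(obj_log, lb, ub, population, generations, seed,
                  ref_log = log(params$ref[free]))
  best_lp <- ga$par
  best_val <- ga$value
  converged <- TRUE
  if (local_refine) {
    loc <- tryCatch(
      optim(best_lp, obj_log, method = "L-BFGS-B", lower = lb, upper = ub,
            control = list(maxit = 200)),
      error = function(e) NULL)
    if (!is.null(loc) && loc$value <= best_val) {
      best_lp <- loc$par
      best_val <- loc$value
      converged <- loc$convergence == 0
    }
  }
  best_params <- params
  best_params$value[free] <- exp(best_lp)
  rms <- vapply(datasets, function(ds) {
    traj <- simulate_for_dataset(model, best_params$value, ds, params)
    mod <- traj$pct_change[match(ds$times_min, traj$times_min)]
    sqrt(mean(((mod - ds$pct_change) / ds$deviation)^2))
  }, numeric(1))
  names(rms) <- vapply(datasets, function(ds) ds$label, character(1))
  structure(list(params = best_params, objective = best_val,
                 per_scenario_rms = rms, n_evaluations = n_eval, seed = seed,
                 converged = converged, history = ga$history,
                 init_median = ga$init_median, model = model,
                 alpha = alpha, free = free),
            class = "hpa_fit")
}

#' @export
print.hpa_fit <- function(x, ...) {
  cat(sprintf("HPA %s-model fit: objective %.4g after %d evaluations (seed %d)\n",
              x$model, x$objective, x$n_evaluations, x$seed))
  cat("  per-scenario weighted RMS:",
      paste(sprintf("%s %.3g", names(x$per_scenario_rms), x$per_scenario_rms),
            collapse = ", "), "\n")
  invisible(x)
}

#' Fraction of data points reproduced within their tabulated deviation
#'
#' @param fit an `hpa_fit`.
#' @param datasets the datasets the fraction is evaluated on (default the
#'   ones implied by the fit's scenarios cannot be recovered, so pass them).
#' @return Fraction in \[0, 1\] of time points with
#'   `|model - data| <= deviation`.
#' @export
fraction_within_deviation <- function(fit, datasets) {
  stopifnot(inherits(fit, "hpa_fit"))
  hits <- 0L
  total <- 0L
  for (ds in datasets) {
    traj <- simulate_for_dataset(fit$model, fit$params$value, ds, fit$params)
    mod <- traj$pct_change[match(ds$times_min, traj$times_min)]
    hits <- hits + sum(abs(mod - ds$pct_change) <= ds$deviation)
    total <- total + length(ds$times_min)
  }
  hits / total
}

#' Parsimonious-versus-extended model comparison
#'
#' Fits both models to the CRH-only arm, the CRH+cortisol arm, and all arms
#' jointly, across several seeds, and derives verdict flags from a fixed
#' operational threshold: a fit is "ok" when at least 80% of its time points
#' are reproduced within their tabulated deviations.
#'
#' @param datasets named list from [table2_fit_datasets()] (must contain
#'   `crh` and `crh_cortisol`; `basal` joins the joint fit when present).
#' @param population,generations,alpha search budget and regularization, per
#'   fit.
#' @param seeds integer vector of seeds (default 1:3).
#' @return An object of class `model_comparison` with a `verdicts` data
#'   frame (model, combo, seed, objective, frac_within, ok) and the
#'   underlying `fits` list indexed `fits[[model]][[combo]][[seed index]]`.
#' @export
compare_models <- function(datasets, population = 200, generations = 100,
                           alpha = 1e-3, seeds = 1:3) {
  stopifnot(all(c("crh", "crh_cortisol") %in% names(datasets)))
  combos <- list(crh = datasets["crh"],
                 crh_cortisol = datasets["crh_cortisol"],
                 joint = datasets)
  fits <- list()
  rows <- list()
  for (model in c("parsimonious", "extended")) {
    fits[[model]] <- list()
    for (cn in names(combos)) {
      fits[[model]][[cn]] <- list()
      for (k in seq_along(seeds)) {
        fit <- global_fit(model, combos[[cn]], population, generations,
                          alpha, seed = seeds[k])
        frac <- fraction_within_deviation(fit, combos[[cn]])
        fits[[model]][[cn]][[k]] <- fit
        rows[[length(rows) + 1L]] <- data.frame(
          model = model, combo = cn, seed = seeds[k],
          objective = fit$objective, frac_within = frac, ok = frac >= 0.8)
      }
    }
  }
  verdicts <- do.call(rbind, rows)
  structure(list(verdicts = verdicts, fits = fits,
                 threshold = 0.8, seeds = seeds),
            class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("Model comparison (>= 80% of points within tabulated deviations = ok)\n")
  print(x$verdicts, row.names = FALSE)
  invisible(x)
}

#' Write a model-comparison report as JSON plus residual tables
#'
#' @param comparison a `model_comparison`.
#' @param json_path output JSON path (verdicts and objectives).
#' @param residuals_csv optional CSV path for the per-point residuals of
#'   each joint fit's best seed.
#' @param datasets the datasets the comparison was run on.
#' @return `json_path`, invisibly.
#' @export
write_comparison_report <- function(comparison, json_path, datasets,
                                    residuals_csv = NULL) {
  stopifnot(inherits(comparison, "model_comparison"))
  jsonlite::write_json(list(threshold = comparison$threshold,
                            seeds = comparison$seeds,
                            verdicts = comparison$verdicts),
                       json_path, auto_unbox = TRUE, digits = NA)
  if (!is.null(residuals_csv)) {
    rows <- list()
    for (model in names(comparison$fits)) {
      jf <- comparison$fits[[model]][["joint"]]
      objs <- vapply(jf, function(f) f$objective, numeric(1))
      fit <- jf[[which.min(objs)]]
      for (ds in datasets) {
        traj <- simulate_for_dataset(model, fit$params$value, ds, fit$params)
        mod <- traj$pct_change[match(ds$times_min, traj$times_min)]
        rows[[length(rows) + 1L]] <- data.frame(
          model = model, arm = ds$label, time_min = ds$times_min,
          data_pct = ds$pct_change, model_pct = mod,
          deviation = ds$deviation)
      }
    }
    write.csv(do.call(rbind, rows), residuals_csv, row.names = FALSE)
  }
  invisible(json_path)
}
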