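#' Fit configuration
#'
#' Describes one distribution configuration and the parameters optimized
#' under it. Parameters with reliable experimental values are fixed, not
#' optimized; by default the blood:plasma ratio and the absorption rate
#' constant are free in every configuration (mirroring their typical
#' unavailability), plus `logp` under `rodgers_logp_optimized` or
#' `kp_scalar` under `kp_optimized`.
#'
#' Default bounds: `logp` in \[-2, 7\], `kp_scalar` in \[0.05, 50\]
#' (pre-cap), `ka` in \[0.01, 10\] 1/h, `bp_ratio` in
#' \[1 - hematocrit, 5\] (the lower bound is resolved against the
#' physiology at fit time).
#'
#' @param method `"rodgers_fixed"`, `"rodgers_logp_optimized"` or
#'   `"kp_optimized"`.
#' @param free_params Character vector drawn from
#'   `c("logp", "kp_scalar", "bp_ratio", "ka")`; defaults depend on
#'   `method`. `rodgers_fixed` must not free `logp` or `kp_scalar`;
#'   `rodgers_logp_optimized` must free `logp` and not `kp_scalar`;
#'   `kp_optimized` the reverse.
#' @param bounds Named list of `c(lower, upper)` overrides.
#' @param grid_points_per_dim Coarse-grid resolution (default 8).
#' @param n_descent_starts Number of top-ranked grid points seeding the
#'   descent phase (default 3).
#' @param max_iter Maximum simplex iterations per descent (default 500).
#' @param rel_tol Relative cost-spread convergence tolerance (default 1e-6).
#' @return A `fit_configuration` list.
#' @export
fit_configuration <- function(method = c("rodgers_fixed",
                                         "rodgers_logp_optimized",
                                         "kp_optimized"),
                              free_params = NULL, bounds = list(),
                              grid_points_per_dim = 8,
                              n_descent_starts = 3,
                              max_iter = 500, rel_tol = 1e-6) {
  method <- match.arg(method)
  if (is.null(free_params)) {
    free_params <- switch(method,
      rodgers_fixed = c("bp_ratio", "ka"),
      rodgers_logp_optimized = c("logp", "bp_ratio", "ka"),
      kp_optimized = c("kp_scalar", "bp_ratio", "ka"))
  }
  allowed <- c("logp", "kp_scalar", "bp_ratio", "ka")
  if (!all(free_params %in% allowed)) {
    abort_pbpk(paste0("unknown free parameter(s): ",
                      paste(setdiff(free_params, allowed), collapse = ", ")),
               class = "pbpkfit_config_error")
  }
  bad <- switch(method,
    rodgers_fixed = any(c("logp", "kp_scalar") %in% free_params),
    rodgers_logp_optimized = !("logp" %in% free_params) ||
      "kp_scalar" %in% free_params,
    kp_optimized = !("kp_scalar" %in% free_params) || "logp" %in% free_params)
  if (bad) {
    abort_pbpk(sprintf("free_params %s are inconsistent with method %s",
                       paste(free_params, collapse = "/"), method),
               class = "pbpkfit_config_error")
  }
  default_bounds <- list(logp = c(-2, 7), kp_scalar = c(0.05, 50),
                         ka = c(0.01, 10), bp_ratio = c(NA_real_, 5))
  for (nm in names(bounds)) default_bounds[[nm]] <- bounds[[nm]]
  structure(list(method = method, free_params = free_params,
                 bounds = default_bounds,
                 grid_points_per_dim = grid_points_per_dim,
                 n_descent_starts = n_descent_starts,
                 max_iter = max_iter, rel_tol = rel_tol),
            class = "fit_configuration")
}

# bounds with the B:P floor resolved against the physiology
resolve_bounds <- function(configuration, physiology) {
  b <- configuration$bounds
  if (is.na(b$bp_ratio[1])) b$bp_ratio[1] <- 1 - physiology$hematocrit
  b[configuration$free_params]
}

# parameters searched on a log10 scale
LOG_SCALE_PARAMS <- c("kp_scalar", "ka")

to_search_scale <- function(params) {
  for (nm in intersect(names(params), LOG_SCALE_PARAMS)) {
    params[[nm]] <- log10(params[[nm]])
  }
  params
}
from_search_scale <- function(params) {
  for (nm in intersect(names(params), LOG_SCALE_PARAMS)) {
    params[[nm]] <- 10^params[[nm]]
  }
  params
}

#' Geometric-mean fold-error cost between observed and simulated studies
#'
#' The optimization cost pools, over every dataset and over the three
#' summary exposure metrics Cmax, Tmax and AUC0-t, the absolute log10 fold
#' error of simulated against observed, and returns
#' `10 ^ mean(|log10(pred/obs)|)`. Perfect agreement gives 1; a uniform
#' two-fold error (in either direction) gives 2. Simulated profiles must be
#' sampled at the observed timepoints so both sides of each ratio are
#' computed identically. Metrics with a zero or missing observed value are
#' skipped with a warning.
#'
#' @param observed,simulated Nested dataset tibbles (columns `dataset_id`,
#'   `route`, `dose_ug`, `data`) matched by `dataset_id`; each `data`
#'   element has `time_h`, `conc_ug_per_L`.
#' @return Cost >= 1 (`Inf` when a simulated metric is non-positive while
#'   the observed one is positive; `Inf` with a warning when no metric is
#'   usable).
#' @export
objective_cost <- function(observed, simulated) {
  sim_idx <- match(observed$dataset_id, simulated$dataset_id)
  if (anyNA(sim_idx)) {
    abort_pbpk("simulated datasets do not cover all observed dataset ids",
               class = "pbpkfit_config_error")
  }
  terms <- numeric(0)
  for (i in seq_len(nrow(observed))) {
    od <- observed$data[[i]]
    sd <- simulated$data[[sim_idx[i]]]
    m_obs <- profile_metrics(od)
    m_sim <- profile_metrics(sd)
    if (m_obs$cmax <= 0) {
      # an all-zero observed profile has no usable metrics (its Tmax is an
      # artifact of the scan)
      rlang::warn(sprintf("skipping dataset %s: observed profile is all zero",
                          observed$dataset_id[i]))
      next
    }
    for (m in names(m_obs)) {
      if (!is.finite(m_obs[[m]]) || m_obs[[m]] <= 0) {
        rlang::warn(sprintf(
          "skipping %s for dataset %s: observed value is zero or missing",
          m, observed$dataset_id[i]), .frequency = "once",
          .frequency_id = paste0("pbpkfit_zero_", m))
        next
      }
      terms <- c(terms,
                 if (m_sim[[m]] <= 0) Inf
                 else abs(log10(m_sim[[m]] / m_obs[[m]])))
    }
  }
  if (length(terms) == 0) {
    rlang::warn("no usable metrics; objective cost is undefined (Inf)")
    return(Inf)
  }
  10^mean(terms)
}

profile_metrics <- function(d) {
  i <- which.max(d$conc_ug_per_L)
  list(cmax = d$conc_ug_per_L[i], tmax = d$time_h[i],
       auc_0t = auc_linear_trapezoid(d$time_h, d$conc_ug_per_L))
}

# simulate every dataset arm at its observed timepoints under one
# parameter combination; returns the nested tibble or NULL on solver error
predict_profiles <- function(compound, physiology, method, params, datasets,
                             kp_cap = Inf) {
  compound <- update_compound(compound, params)
  ps <- tryCatch(
    build_partition_set(compound, physiology, method = method,
                        logp_override = params[["logp"]] %||% NULL,
                        kp_scalar = params[["kp_scalar"]] %||% NULL,
                        kp_cap = kp_cap),
    error = function(e) NULL)
  if (is.null(ps)) return(NULL)
  out <- datasets
  for (i in seq_len(nrow(datasets))) {
    times <- datasets$data[[i]]$time_h
    dose <- switch(datasets$route[i],
                   oral = dose_oral(datasets$dose_ug[i]),
                   iv_bolus = dose_iv_bolus(datasets$dose_ug[i]),
                   iv_infusion = dose_iv_infusion(
                     datasets$dose_ug[i],
                     duration_h = datasets$duration_h[i] %||% 1),
                   abort_pbpk(paste0("unknown route: ", datasets$route[i]),
                              class = "pbpkfit_config_error"))
    sim <- tryCatch(
      simulate_pbpk(compound, physiology, ps, dose,
                    t_end = max(times), output_times = times),
      error = function(e) NULL)
    if (is.null(sim)) return(NULL)
    out$data[[i]] <- sim$plasma
  }
  out
}

# closure evaluating the fitting cost at a named parameter vector; the
# observed metrics and dose events are constant across evaluations and
# precomputed once
make_cost_function <- function(compound, physiology, datasets, configuration,
                               kp_cap) {
  force(kp_cap)
  method <- configuration$method
  arms <- lapply(seq_len(nrow(datasets)), function(i) {
    d <- datasets$data[[i]]
    m_obs <- profile_metrics(d)
    dose <- switch(datasets$route[i],
                   oral = dose_oral(datasets$dose_ug[i]),
                   iv_bolus = dose_iv_bolus(datasets$dose_ug[i]),
                   iv_infusion = dose_iv_infusion(
                     datasets$dose_ug[i],
                     duration_h = datasets$duration_h[i] %||% 1),
                   abort_pbpk(paste0("unknown route: ", datasets$route[i]),
                              class = "pbpkfit_config_error"))
    t_end <- max(d$time_h)
    # simulated Cmax/AUC0-t are read at the observed timepoints so both
    # sides of the ratio share the sampling grid; simulated Tmax is read
    # off a dense grid, which resolves the absorption peak far better
    # than a sparse observed design (documented asymmetry). The dense
    # grid starts at the first observed time: nothing earlier is
    # observable, and an IV-bolus peak at t = 0 would otherwise produce a
    # degenerate Tmax ratio
    dense <- seq(min(d$time_h), t_end, length.out = 151)
    grid_times <- sort(unique(c(d$time_h, dense)))
    obs_idx <- match(d$time_h, grid_times)
    list(times = grid_times, obs_idx = obs_idx, dose = dose, t_end = t_end,
         m_obs = m_obs)
  })
  function(params) {
    params <- as.list(params)
    cpd <- update_compound(compound, params)
    ps <- tryCatch(
      build_partition_set(cpd, physiology, method = method,
                          logp_override = params[["logp"]] %||% NULL,
                          kp_scalar = params[["kp_scalar"]] %||% NULL,
                          kp_cap = kp_cap),
      error = function(e) NULL)
    if (is.null(ps)) return(Inf)
    terms <- numeric(0)
    for (arm in arms) {
      if (arm$m_obs$cmax <= 0) next
      sim <- tryCatch(
        simulate_pbpk(cpd, physiology, ps, arm$dose, t_end = arm$t_end,
                      output_times = arm$times),
        error = function(e) NULL)
      if (is.null(sim)) return(Inf)
      conc <- sim$plasma$conc_ug_per_L
      obs_conc <- conc[arm$obs_idx]
      obs_t <- sim$plasma$time_h[arm$obs_idx]
      m_sim <- list(
        cmax = max(obs_conc),
        tmax = sim$plasma$time_h[which.max(conc)],
        auc_0t = auc_linear_trapezoid(obs_t, obs_conc))
      for (m in names(arm$m_obs)) {
        if (!is.finite(arm$m_obs[[m]]) || arm$m_obs[[m]] <= 0) next
        terms <- c(terms,
                   if (m_sim[[m]] <= 0) Inf
                   else abs(log10(m_sim[[m]] / arm$m_obs[[m]])))
      }
    }
    if (length(terms) == 0) return(Inf)
    10^mean(terms)
  }
}

# observed Vdss for the automatic Kp cap: NCA over IV arms, first
# terminal-sufficient estimate
observed_vdss_for_cap <- function(datasets) {
  iv <- datasets[datasets$route %in% c("iv_bolus", "iv_infusion"), ,
                 drop = FALSE]
  for (i in seq_len(nrow(iv))) {
    pk <- tryCatch(
      compute_pk_outputs(iv$data[[i]], iv$dose_ug[i], iv$route[i]),
      error = function(e) NULL)
    if (!is.null(pk) && isTRUE(pk$terminal_sufficient) && !is.na(pk$vdss)) {
      return(pk$vdss)
    }
  }
  NA_real_
}

#' Coarse-grid search over the free parameters
#'
#' Evaluates the fitting cost on a full-factorial grid over the free
#' parameters (`kp_scalar` and `ka` log-spaced, `logp` and `bp_ratio`
#' linearly spaced) and returns every combination ranked by cost. A
#' simulation failure at a grid point scores `Inf` and never aborts the
#' grid. Deterministic given its inputs.
#'
#' @param compound,physiology,datasets As in [fit_compound()].
#' @param configuration A [fit_configuration()].
#' @param kp_cap Kp cap applied inside every evaluation (default: automatic
#'   from observed Vdss, see [auto_kp_cap()]).
#' @return A tibble with one column per free parameter plus `cost`, sorted
#'   by ascending cost; attribute `eval_order` preserves evaluation order.
#' @export
coarse_grid <- function(compound, physiology, datasets, configuration,
                        kp_cap = NULL) {
  bounds <- resolve_bounds(configuration, physiology)
  k <- configuration$grid_points_per_dim
  axes <- lapply(names(bounds), function(nm) {
    b <- bounds[[nm]]
    if (k == 1) {
      return(if (nm %in% LOG_SCALE_PARAMS) sqrt(b[1] * b[2]) else mean(b))
    }
    if (nm %in% LOG_SCALE_PARAMS) logspace(b[1], b[2], k)
    else seq(b[1], b[2], length.out = k)
  })
  names(axes) <- names(bounds)
  grid <- do.call(expand.grid, c(axes, KEEP.OUT.ATTRS = FALSE)) |>
    tibble::as_tibble()
  if (is.null(kp_cap)) {
    kp_cap <- auto_kp_cap(observed_vdss_for_cap(datasets), physiology)
  }
  cost_fn <- make_cost_function(compound, physiology, datasets,
                                configuration, kp_cap)
  costs <- vapply(seq_len(nrow(grid)), function(i) {
    cost_fn(as.list(grid[i, , drop = FALSE]))
  }, numeric(1))
  grid$cost <- costs
  if (all(!is.finite(costs))) {
    abort_pbpk("no feasible grid point: every combination failed",
               class = "pbpkfit_fit_error")
  }
  out <- grid[order(grid$cost), , drop = FALSE]
  attr(out, "eval_order") <- costs
  attr(out, "kp_cap") <- kp_cap
  out
}

#' Simplex descent from one starting combination
#'
#' Derivative-free Nelder-Mead descent in search scale (log10 for
#' `kp_scalar` and `ka`), with proposals clipped to the parameter bounds.
#' Terminates when the relative cost spread of the simplex falls below
#' `rel_tol` or after `max_iter` iterations (then `converged = FALSE`).
#'
#' @inheritParams coarse_grid
#' @param start Named list/vector of starting values (natural scale),
#'   within bounds.
#' @param kp_cap Kp cap applied inside every evaluation.
#' @return A list: `best_params` (named list, natural scale), `best_cost`,
#'   `trajectory` (numeric vector of evaluation costs in order),
#'   `converged`.
#' @export
descend <- function(compound, physiology, datasets, configuration, start,
                    kp_cap = NULL) {
  bounds <- resolve_bounds(configuration, physiology)
  par_names <- names(bounds)
  if (is.null(kp_cap)) {
    kp_cap <- auto_kp_cap(observed_vdss_for_cap(datasets), physiology)
  }
  cost_fn <- make_cost_function(compound, physiology, datasets,
                                configuration, kp_cap)

  lo <- vapply(par_names, function(nm) {
    if (nm %in% LOG_SCALE_PARAMS) log10(bounds[[nm]][1]) else bounds[[nm]][1]
  }, numeric(1))
  hi <- vapply(par_names, function(nm) {
    if (nm %in% LOG_SCALE_PARAMS) log10(bounds[[nm]][2]) else bounds[[nm]][2]
  }, numeric(1))

  trajectory <- numeric(0)
  eval_at <- function(x) {
    # x is on the search scale; clip into bounds before evaluating
    x <- pmin(pmax(x, lo), hi)
    p <- from_search_scale(as.list(stats::setNames(x, par_names)))
    cost <- cost_fn(p)
    trajectory <<- c(trajectory, cost)
    list(x = x, cost = cost)
  }

  x0 <- vapply(par_names, function(nm) {
    v <- start[[nm]]
    if (nm %in% LOG_SCALE_PARAMS) log10(v) else v
  }, numeric(1))
  x0 <- pmin(pmax(x0, lo), hi)

  n <- length(x0)
  # initial simplex: perturb each coordinate by 5% of its search-scale range
  step <- 0.05 * (hi - lo)
  pts <- vector("list", n + 1)
  pts[[1]] <- eval_at(x0)
  for (i in seq_len(n)) {
    xi <- x0
    xi[i] <- if (xi[i] + step[i] <= hi[i]) xi[i] + step[i] else xi[i] - step[i]
    pts[[i + 1]] <- eval_at(xi)
  }

  alpha <- 1; gamma <- 2; rho <- 0.5; sigma <- 0.5
  converged <- FALSE
  for (iter in seq_len(configuration$max_iter)) {
    costs <- vapply(pts, `[[`, numeric(1), "cost")
    ord <- order(costs)
    pts <- pts[ord]
    costs <- costs[ord]
    if (!is.finite(costs[1])) break  # flat/unusable landscape
    spread <- (costs[n + 1] - costs[1]) / max(abs(costs[1]), 1e-12)
    if (is.finite(spread) && spread < configuration$rel_tol) {
      converged <- TRUE
      break
    }
    centroid <- Reduce(`+`, lapply(pts[seq_len(n)], `[[`, "x")) / n
    xr <- eval_at(centroid + alpha * (centroid - pts[[n + 1]]$x))
    if (xr$cost < costs[1]) {
      xe <- eval_at(centroid + gamma * (xr$x - centroid))
      pts[[n + 1]] <- if (xe$cost < xr$cost) xe else xr
    } else if (xr$cost < costs[n]) {
      pts[[n + 1]] <- xr
    } else {
      xc <- eval_at(centroid + rho * (pts[[n + 1]]$x - centroid))
      if (xc$cost < costs[n + 1]) {
        pts[[n + 1]] <- xc
      } else {
        for (i in 2:(n + 1)) {
          pts[[i]] <- eval_at(pts[[1]]$x + sigma * (pts[[i]]$x - pts[[1]]$x))
        }
      }
    }
  }
  costs <- vapply(pts, `[[`, numeric(1), "cost")
  best <- pts[[which.min(costs)]]
  list(best_params = from_search_scale(
         as.list(stats::setNames(best$x, par_names))),
       best_cost = best$cost, trajectory = trajectory,
       converged = converged)
}

#' Fit a compound's free parameters to observed profiles
#'
#' Two-phase optimization under the geometric-mean fold-error cost
#' ([objective_cost()]): a deterministic full-factorial coarse grid over
#' the free parameters, then simplex descent from the top
#' `n_descent_starts` grid combinations; the global best across every
#' evaluation is returned. The Kp cap rule is applied inside every
#' evaluation.
#'
#' @param compound A [compound_profile()] holding the fixed (experimental)
#'   parameter values.
#' @param physiology A [load_physiology()] object.
#' @param datasets Nested observed-dataset tibble (columns `dataset_id`,
#'   `route`, `dose_ug`, `data`), e.g. from [attach_manifest()].
#' @param configuration A [fit_configuration()].
#' @param seed Integer recorded with the result (the search itself is
#'   deterministic).
#' @return A `pbpk_fit` object: `best_params`, `best_cost`, `trajectory`
#'   (tibble `eval`, `cost`, `phase`), `phase_boundary` (last grid-phase
#'   evaluation index), `converged`, `method`, `kp_cap`, `n_datasets`,
#'   `compound_name`, `seed`. Supports [tidy()] and [glance()].
#' @examples
#' \donttest{
#' phys <- load_physiology()
#' study <- generate_study(n_compounds = 1, datasets_per_compound = 2,
#'                         cv = 0, seed = 7)
#' cfg <- fit_configuration("kp_optimized", grid_points_per_dim = 4,
#'                          max_iter = 60)
#' fit <- fit_compound(study$compounds[[1]], phys,
#'                     study$datasets[study$datasets$compound ==
#'                                    study$compounds[[1]]$name, ],
#'                     cfg)
#' glance(fit)
#' }
#' @export
fit_compound <- function(compound, physiology, datasets, configuration,
                         seed = 1L) {
  stopifnot(inherits(configuration, "fit_configuration"))
  if (!is.data.frame(datasets) || nrow(datasets) == 0) {
    abort_pbpk("need at least one observed dataset",
               class = "pbpkfit_fit_error")
  }
  kp_cap <- auto_kp_cap(observed_vdss_for_cap(datasets), physiology)
  if (length(configuration$free_params) == 0) {
    # degenerate configuration: nothing to optimize, a single evaluation
    cost_fn <- make_cost_function(compound, physiology, datasets,
                                  configuration, kp_cap)
    cost <- cost_fn(list())
    return(structure(list(
      best_params = list(), best_cost = cost,
      trajectory = tibble::tibble(eval = 1L, cost = cost, phase = "grid"),
      phase_boundary = 1L, converged = is.finite(cost),
      method = configuration$method, configuration = configuration,
      kp_cap = kp_cap, n_datasets = nrow(datasets),
      compound_name = compound$name, seed = as.integer(seed)),
      class = "pbpk_fit"))
  }
  grid <- coarse_grid(compound, physiology, datasets, configuration,
                      kp_cap = kp_cap)
  grid_costs <- attr(grid, "eval_order")

  n_starts <- min(configuration$n_descent_starts, nrow(grid))
  starts <- grid[seq_len(n_starts), , drop = FALSE]
  traj_cost <- grid_costs
  traj_phase <- rep("grid", length(grid_costs))
  best_cost <- grid$cost[1]
  best_params <- as.list(grid[1, configuration$free_params, drop = FALSE])
  converged <- FALSE
  for (i in seq_len(n_starts)) {
    if (!is.finite(starts$cost[i])) next
    d <- descend(compound, physiology, datasets, configuration,
                 start = as.list(starts[i, configuration$free_params,
                                        drop = FALSE]),
                 kp_cap = kp_cap)
    traj_cost <- c(traj_cost, d$trajectory)
    traj_phase <- c(traj_phase, rep("descent", length(d$trajectory)))
    if (d$best_cost < best_cost) {
      best_cost <- d$best_cost
      best_params <- d$best_params
      converged <- d$converged
    } else if (d$converged && d$best_cost <= best_cost) {
      converged <- TRUE
    }
  }
  structure(list(
    best_params = best_params, best_cost = best_cost,
    trajectory = tibble::tibble(eval = seq_along(traj_cost),
                                cost = traj_cost, phase = traj_phase),
    phase_boundary = length(grid_costs), converged = converged,
    method = configuration$method, configuration = configuration,
    kp_cap = kp_cap, n_datasets = nrow(datasets),
    compound_name = compound$name, seed = as.integer(seed)),
    class = "pbpk_fit")
}

#' @export
print.pbpk_fit <- function(x, ...) {
  cat(sprintf("<pbpk_fit> %s (%s), %d datasets\n", x$compound_name,
              x$method, x$n_datasets))
  cat(sprintf("  best cost %.4f after %d evaluations (%s)\n", x$best_cost,
              nrow(x$trajectory),
              if (x$converged) "converged" else "not converged"))
  p <- unlist(x$best_params)
  cat("  ", paste(sprintf("%s = %.4g", names(p), p), collapse = ", "), "\n")
  invisible(x)
}

#' Fit every compound of a study under one or more configurations
#'
#' Batch runner over compounds (embarrassingly parallel in principle; run
#' sequentially here so results never depend on worker count). Each
#' compound is fitted independently with a seed derived from its index.
#'
#' @param study A [generate_study()] bundle, or a list with elements
#'   `compounds` (list of [compound_profile()]) and `datasets` (nested
#'   tibble with a `compound` column).
#' @param physiology A [load_physiology()] object.
#' @param methods Configurations to run; character subset of the three
#'   method names, or a named list of [fit_configuration()] objects.
#' @param seed Base seed.
#' @param ... Passed to [fit_configuration()] when `methods` is character
#'   (e.g. `grid_points_per_dim`, `max_iter`).
#' @return A tibble with columns `compound`, `method`, `fit` (list of
#'   `pbpk_fit`), `best_cost`, `converged`.
#' @export
fit_study <- function(study, physiology,
                      methods = c("rodgers_fixed", "rodgers_logp_optimized",
                                  "kp_optimized"),
                      seed = 1L, ...) {
  configs <- if (is.character(methods)) {
    stats::setNames(lapply(methods, function(m) fit_configuration(m, ...)),
                    methods)
  } else methods
  rows <- list()
  for (ci in seq_along(configs)) {
    cfg <- configs[[ci]]
    for (i in seq_along(study$compounds)) {
      cpd <- study$compounds[[i]]
      ds <- study$datasets[study$datasets$compound == cpd$name, , drop = FALSE]
      fit <- fit_compound(cpd, physiology, ds, cfg,
                          seed = as.integer(seed) + i)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        compound = cpd$name, method = cfg$method, fit = list(fit),
        best_cost = fit$best_cost, converged = fit$converged)
    }
  }
  dplyr::bind_rows(rows)
}
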