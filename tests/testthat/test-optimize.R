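test_that("the GMFE objective matches its closed-form values", {
  prof <- tibble::tibble(time_h = c(0.5, 1, 2, 4, 8),
                         conc_ug_per_L = c(4, 10, 8, 5, 2))
  obs <- tibble::tibble(dataset_id = "d1", route = "oral", dose_ug = 100,
                        data = list(prof))
  # identity
  expect_equal(objective_cost(obs, obs), 1)
  # uniform two-fold concentration error: Cmax and AUC carry |log10 2|,
  # Tmax is exact, so cost = 2^(2/3)
  sim2 <- obs
  sim2$data[[1]]$conc_ug_per_L <- 2 * prof$conc_ug_per_L
  expect_equal(objective_cost(obs, sim2), 2^(2 / 3), tolerance = 1e-12)
  # an all-zero observed profile contributes no usable metric
  obs0 <- obs
  obs0$data[[1]]$conc_ug_per_L <- rep(0, 5)
  cost0 <- NULL
  expect_warning(expect_warning(cost0 <- objective_cost(obs0, sim2)))
  expect_true(is.infinite(cost0))
  # unmatched ids
  sim_bad <- sim2
  sim_bad$dataset_id <- "other"
  expect_error(objective_cost(obs, sim_bad), class = "pbpkfit_config_error")
})

test_that("fit configurations enforce method/free-parameter coherence", {
  expect_error(fit_configuration("rodgers_fixed", free_params = c("logp")),
               class = "pbpkfit_config_error")
  expect_error(fit_configuration("rodgers_logp_optimized",
                                 free_params = c("bp_ratio")),
               class = "pbpkfit_config_error")
  expect_error(fit_configuration("kp_optimized",
                                 free_params = c("logp", "kp_scalar")),
               class = "pbpkfit_config_error")
  cfg <- fit_configuration("kp_optimized")
  expect_setequal(cfg$free_params, c("kp_scalar", "bp_ratio", "ka"))
  # the B:P floor resolves to 1 - hematocrit at fit time
  b <- pbpkfit:::resolve_bounds(cfg, test_phys())
  expect_equal(b$bp_ratio[1], 1 - test_phys()$hematocrit)
})

# a small noiseless one-arm problem reused by the search tests
make_ka_problem <- function() {
  phys <- test_phys()
  cpd <- neutral_compound(cl_hepatic = 20, ka = 0.7, f_oral = 0.9,
                          bp_ratio = 1.2)
  ps <- flat_partition(3)
  times <- default_design_times("oral")
  sim <- simulate_pbpk(cpd, phys, ps, dose_oral(2e4), t_end = max(times),
                       output_times = times)
  datasets <- tibble::tibble(dataset_id = "arm1", route = "oral",
                             dose_ug = 2e4, data = list(sim$plasma))
  list(phys = phys, cpd = cpd, datasets = datasets, true_ka = 0.7)
}

test_that("coarse grid enumerates, ranks, and matches pointwise costs", {
  prob <- make_ka_problem()
  cfg1 <- fit_configuration("kp_optimized", free_params = c("kp_scalar", "ka"),
                            grid_points_per_dim = 7)
  grid <- coarse_grid(prob$cpd, prob$phys, prob$datasets, cfg1, kp_cap = Inf)
  expect_equal(nrow(grid), 49)
  expect_true(all(diff(grid$cost) >= 0))

  # grid costs agree with an independent evaluation of the objective at
  # the same points
  cost_fn <- pbpkfit:::make_cost_function(prob$cpd, prob$phys, prob$datasets,
                                          cfg1, Inf)
  for (i in c(1, 10, 49)) {
    expect_equal(grid$cost[i],
                 cost_fn(list(kp_scalar = grid$kp_scalar[i],
                              ka = grid$ka[i])),
                 tolerance = 1e-12)
  }

  # the generating kp (= 3; nearest log-spaced grid nodes 1.58 and 5) and
  # ka (= 0.7; nearest nodes 0.316 and 1) bracket the top-ranked point
  expect_true(grid$kp_scalar[1] %in%
                sort(unique(grid$kp_scalar))[4:5])
  expect_true(grid$ka[1] %in% sort(unique(grid$ka))[4:5])

  # one point per dimension degenerates to a single combination
  cfg_single <- fit_configuration("kp_optimized", grid_points_per_dim = 1)
  g1 <- coarse_grid(prob$cpd, prob$phys, prob$datasets, cfg_single,
                    kp_cap = Inf)
  expect_equal(nrow(g1), 1)
})

test_that("simplex descent converges from the optimum and respects bounds", {
  prob <- make_ka_problem()
  cfg <- fit_configuration("kp_optimized", max_iter = 150)
  # start at the generating parameters: the cost sits within the Tmax
  # grid-quantization floor of 1 and the descent cannot leave the basin
  d <- descend(prob$cpd, prob$phys, prob$datasets, cfg,
               start = list(kp_scalar = 3, bp_ratio = 1.2, ka = 0.7),
               kp_cap = Inf)
  expect_true(d$converged)
  expect_lte(d$best_cost, d$trajectory[1] + 1e-12)
  expect_lt(d$best_cost, 1.02)
  expect_true(all(unlist(d$best_params) >=
                    c(0.05, 1 - test_phys()$hematocrit, 0.01) - 1e-12))
})

test_that("fitting a noiseless synthetic compound recovers the truth", {
  phys <- test_phys()
  study <- generate_study(n_compounds = 1, datasets_per_compound = 2,
                          cv = 0, seed = 3)
  cpd <- study$compounds[[1]]
  ds <- study$datasets[study$datasets$compound == cpd$name, ]
  cfg <- fit_configuration("kp_optimized", grid_points_per_dim = 5,
                           max_iter = 250)
  fit <- fit_compound(cpd, phys, ds, cfg, seed = 1)
  tr <- study$truth[1, ]
  # the Tmax term compares a dense simulated grid against the coarse
  # observed samples, so even noiseless recovery carries a quantization
  # bias: amplitude parameters (kp, B:P) within 10%, ka within one
  # sampling-slot ratio of the 12-point log-spaced oral design
  slot <- (48 / 0.25)^(1 / 11)
  expect_lt(abs(fit$best_params$kp_scalar - tr$true_kp) / tr$true_kp, 0.10)
  expect_lt(abs(log(fit$best_params$ka / tr$true_ka)), log(slot))
  expect_lt(abs(fit$best_params$bp_ratio - tr$true_bp) / tr$true_bp, 0.10)
  expect_lt(fit$best_cost, 1.02)

  # trajectory bookkeeping: best cost is the minimum over every
  # evaluation and the phases are contiguous
  expect_equal(fit$best_cost, min(fit$trajectory$cost))
  expect_equal(fit$phase_boundary, 5^3)
  expect_true(all(fit$trajectory$phase[seq_len(fit$phase_boundary)] == "grid"))

  # determinism: identical inputs and seed give identical results
  fit2 <- fit_compound(cpd, phys, ds, cfg, seed = 1)
  expect_identical(fit$best_params, fit2$best_params)
  expect_identical(fit$trajectory, fit2$trajectory)

  # broom-style accessors
  td <- tidy(fit)
  expect_setequal(td$term, c("kp_scalar", "bp_ratio", "ka"))
  expect_equal(glance(fit)$best_cost, fit$best_cost)
})

test_that("degenerate configurations and failure modes are reported", {
  prob <- make_ka_problem()
  # nothing to optimize: a single evaluation
  cfg0 <- fit_configuration("rodgers_fixed", free_params = character(0))
  fit0 <- fit_compound(prob$cpd, prob$phys, prob$datasets, cfg0)
  expect_equal(nrow(fit0$trajectory), 1)
  expect_length(fit0$best_params, 0)

  # rodgers_fixed frees only ka and B:P by default: grid size is k^2
  cfg_rf <- fit_configuration("rodgers_fixed", grid_points_per_dim = 3,
                              max_iter = 30)
  fit_rf <- fit_compound(prob$cpd, prob$phys, prob$datasets, cfg_rf)
  expect_equal(fit_rf$phase_boundary, 9)

  expect_error(fit_compound(prob$cpd, prob$phys, prob$datasets[0, ],
                            fit_configuration("kp_optimized")),
               class = "pbpkfit_fit_error")
})
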