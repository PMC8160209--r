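test_that("mass is conserved with and without elimination", {
  phys <- test_phys()
  ps <- flat_partition(2)

  # zero clearance: everything administered stays in the body
  sim0 <- simulate_pbpk(neutral_compound(), phys, ps, dose_iv_bolus(1000),
                        t_end = 48)
  body <- rowSums(sim0$amounts[, setdiff(colnames(sim0$amounts),
                                         c("eliminated", "unabsorbed"))])
  expect_true(all(abs(body - 1000) < 1e-6 * 1000))
  expect_equal(max(sim0$amounts[, "eliminated"]), 0)

  # with clearance: body + eliminated equals the dose
  cpd <- neutral_compound(cl_hepatic = 20, cl_renal = 5)
  sim1 <- simulate_pbpk(cpd, phys, ps, dose_iv_bolus(1000), t_end = 48)
  expect_lt(sim1$diagnostics$mass_balance_residual, 1e-6)
  expect_gt(sim1$amounts[nrow(sim1$amounts), "eliminated"], 0)

  # infusion arm conserves mass too
  sim2 <- simulate_pbpk(cpd, phys, ps, dose_iv_infusion(1000, duration_h = 2),
                        t_end = 24)
  expect_lt(sim2$diagnostics$mass_balance_residual, 1e-6)
})

test_that("degenerate fast-flow limit matches the one-compartment closed form", {
  phys <- scale_flows(test_phys(), 1000)
  cpd <- neutral_compound(cl_hepatic = 10)
  ps <- build_partition_set(cpd, phys, method = "kp_optimized", kp_scalar = 1)
  V <- sum(phys$tissues$volume_L)
  times <- seq(0.01, 30, length.out = 300)
  sim <- simulate_pbpk(cpd, phys, ps, dose_iv_bolus(1e4), t_end = 30,
                       output_times = times)
  pred <- 1e4 / V * exp(-10 * times / V)
  expect_lt(max(abs(sim$plasma$conc_ug_per_L - pred) / pred), 0.005)
})

test_that("dose linearity and plasma conversion hold exactly", {
  phys <- test_phys()
  cpd <- neutral_compound(bp_ratio = 2, cl_hepatic = 15, ka = 1.2,
                          f_oral = 0.8)
  ps <- flat_partition(3)
  s1 <- simulate_pbpk(cpd, phys, ps, dose_oral(1000), t_end = 24)
  s2 <- simulate_pbpk(cpd, phys, ps, dose_oral(2000), t_end = 24)
  expect_equal(s2$plasma$conc_ug_per_L, 2 * s1$plasma$conc_ug_per_L,
               tolerance = 1e-10)

  # plasma = blood / B:P
  v_ven <- phys$tissues$volume_L[phys$tissues$tissue == "venous_blood"]
  blood_conc <- s1$amounts[, "venous_blood"] / v_ven
  expect_equal(s1$plasma$conc_ug_per_L, blood_conc / 2, tolerance = 1e-12)
  expect_equal(venous_plasma_series(s1, bp_ratio = 1)$conc_ug_per_L,
               blood_conc, tolerance = 1e-12)
})

test_that("oral bioavailability and first-pass behave mechanistically", {
  phys <- test_phys()
  ps <- flat_partition(1)
  # no clearance: absorbed amount tends to F * dose
  cpd <- neutral_compound(ka = 1, f_oral = 0.5)
  sim <- simulate_pbpk(cpd, phys, ps, dose_oral(1000), t_end = 200,
                       output_times = c(0, 1, 10, 200))
  final <- sim$amounts[nrow(sim$amounts), ]
  body <- sum(final[setdiff(names(final), c("eliminated", "unabsorbed"))])
  expect_equal(body, 500, tolerance = 1e-5)
  expect_equal(unname(final["unabsorbed"]), 500, tolerance = 1e-5)

  # negligible hepatic extraction (CL = 0.3 L/h against ~79 L/h hepatic
  # inflow): oral AUCinf ~ F * IV AUCinf
  cpd2 <- neutral_compound(cl_hepatic = 0.3, ka = 1, f_oral = 0.7)
  times <- pbpkfit:::logspace(0.01, 2500, 1500)
  siv <- simulate_pbpk(cpd2, phys, ps, dose_iv_bolus(1000), t_end = 2500,
                       output_times = times)
  sor <- simulate_pbpk(cpd2, phys, ps, dose_oral(1000), t_end = 2500,
                       output_times = times)
  auc_iv <- compute_pk_outputs(siv$plasma, 1000, "iv_bolus")$auc_inf
  auc_or <- compute_pk_outputs(sor$plasma, 1000, "oral")$auc_inf
  expect_equal(auc_or / auc_iv, 0.7, tolerance = 0.02)
})

test_that("NCA AUC0-inf on an IV profile recovers Dose / blood clearance", {
  phys <- test_phys()
  cpd <- neutral_compound(bp_ratio = 1.3, cl_hepatic = 0.75, cl_renal = 0.25)
  ps <- flat_partition(2)
  vd <- analytic_vdss(phys, ps, cpd)
  t_end <- 10 * vd  # ~10 mean residence times at unit total clearance
  # log-spaced sampling resolves the fast distribution phase after the
  # bolus, where a linear trapezoid grid would overestimate the AUC
  times <- pbpkfit:::logspace(0.005, t_end, 2000)
  sim <- simulate_pbpk(cpd, phys, ps, dose_iv_bolus(1e4), t_end = t_end,
                       output_times = times)
  blood <- tibble::tibble(time_h = times,
                          conc_ug_per_L = sim$plasma$conc_ug_per_L *
                            cpd$bp_ratio)
  auc_blood <- compute_pk_outputs(blood, 1e4, "iv_bolus")$auc_inf
  expect_equal(auc_blood, 1e4 / 1, tolerance = 0.01)
})

test_that("analytic Vdss bookkeeping matches its limiting cases", {
  phys <- test_phys()
  cpd <- neutral_compound()
  expect_equal(analytic_vdss(phys, flat_partition(1), cpd),
               sum(phys$tissues$volume_L))
  # vanishing tissue partitioning: only blood remains, referenced to plasma
  tiny <- build_partition_set(cpd, phys, method = "kp_optimized",
                              kp_scalar = 1e-9)
  cpd_bp <- neutral_compound(bp_ratio = 1.4)
  expect_equal(analytic_vdss(phys, tiny, cpd_bp),
               1.4 * phys$blood_volume, tolerance = 1e-6)
})

test_that("fixed-step RK4 parity mode agrees with the exact propagator", {
  phys <- test_phys()
  cpd <- neutral_compound(cl_hepatic = 20, ka = 1, f_oral = 0.9)
  ps <- flat_partition(2)
  times <- seq(0, 2, by = 0.5)
  exact <- simulate_pbpk(cpd, phys, ps, dose_oral(1000), t_end = 2,
                         output_times = times)
  rk4 <- simulate_pbpk(cpd, phys, ps, dose_oral(1000), t_end = 2,
                       output_times = times, solver = "fixed_step",
                       step_h = 1e-3)
  expect_equal(rk4$plasma$conc_ug_per_L, exact$plasma$conc_ug_per_L,
               tolerance = 1e-8)
})

test_that("simulation rejects inconsistent configuration", {
  phys <- test_phys()
  ps <- flat_partition(1)
  # oral dose without an absorption constant
  expect_error(
    simulate_pbpk(neutral_compound(), phys, ps, dose_oral(100), t_end = 10),
    class = "pbpkfit_config_error")
  # missing tissue Kp
  broken <- ps
  broken$kp <- broken$kp[broken$kp$tissue != "liver", ]
  expect_error(
    simulate_pbpk(neutral_compound(), phys, broken, dose_iv_bolus(100),
                  t_end = 10),
    class = "pbpkfit_config_error")
  # output times outside the window
  expect_error(
    simulate_pbpk(neutral_compound(), phys, ps, dose_iv_bolus(100),
                  t_end = 10, output_times = c(0, 20)),
    class = "pbpkfit_config_error")
})
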