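test_that("linear trapezoid reproduces hand-computed golden values", {
  expect_equal(auc_linear_trapezoid(c(0, 1, 2), c(10, 5, 2.5)), 11.25)
  expect_equal(aumc_linear_trapezoid(c(0, 1, 2), c(10, 5, 2.5)), 7.5)
  # constant profile: rectangle
  expect_equal(auc_linear_trapezoid(c(0, 2), c(4, 4)), 8)
  expect_equal(aumc_linear_trapezoid(c(0, 2), c(4, 4)), 8)
  # malformed input
  expect_error(auc_linear_trapezoid(1, 1), class = "pbpkfit_nca_error")
  expect_error(auc_linear_trapezoid(c(0, 0), c(1, 1)),
               class = "pbpkfit_nca_error")
  expect_error(auc_linear_trapezoid(c(0, 1), c(1, -1)),
               class = "pbpkfit_nca_error")
})

test_that("trapezoid AUC converges to the analytic integral under refinement", {
  lambda <- 0.3
  analytic <- 100 / lambda * (1 - exp(-lambda * 24))
  errs <- sapply(c(25, 100, 400), function(n) {
    t <- seq(0, 24, length.out = n)
    abs(auc_linear_trapezoid(t, 100 * exp(-lambda * t)) - analytic)
  })
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3] / analytic, 1e-4)
})

test_that("terminal slope is exact on log-linear data and rejects bad fits", {
  t <- c(0, 1, 2, 4, 6, 8)
  c_exp <- 100 * exp(-0.5 * t)
  ts <- terminal_slope(t, c_exp)
  expect_equal(ts$lambda_z, 0.5, tolerance = 1e-12)
  expect_gte(ts$n_points, 3)

  # rising terminal points: no elimination rate
  rising <- c(100, 50, 20, 10, 20, 40)
  expect_true(is.na(terminal_slope(t, rising)$lambda_z))

  # too few candidates after Tmax
  expect_true(is.na(terminal_slope(c(0, 1, 2), c(10, 8, 5))$lambda_z))

  # noisy mono-exponential: recovered within 15% (fixed seed)
  set.seed(101)
  tt <- c(2, 4, 6, 8, 10)
  cc <- 100 * exp(-0.4 * tt) * exp(rnorm(5, 0, 0.1))
  noisy <- terminal_slope(c(0.5, tt), c(120, cc))
  expect_lt(abs(noisy$lambda_z - 0.4) / 0.4, 0.15)
})

test_that("PK outputs follow the MRT/Vdss formulas and the tie rule", {
  # mono-exponential with AUCinf = 50, AUMCinf = 200 (C0 = 12.5,
  # lambda = 0.25): MRT = 4 h and, for a 100 ug dose, Vdss = 8 L
  t <- seq(0, 60, by = 0.05)
  prof <- tibble::tibble(time_h = t, conc_ug_per_L = 12.5 * exp(-0.25 * t))
  pk <- compute_pk_outputs(prof, dose_ug = 100, route = "iv_bolus")
  expect_equal(pk$auc_inf, 50, tolerance = 1e-4)
  expect_equal(pk$aumc_inf, 200, tolerance = 1e-4)
  expect_equal(pk$mrt, 4, tolerance = 1e-4)
  expect_equal(pk$vdss, 8, tolerance = 1e-4)
  # the identities hold exactly on the computed quantities
  expect_identical(pk$mrt, pk$aumc_inf / pk$auc_inf)
  expect_identical(pk$vdss, 100 * pk$mrt / pk$auc_inf)
  # one-compartment bolus: MRT = 1/lambda_z
  expect_equal(pk$mrt, 1 / pk$lambda_z, tolerance = 0.01)

  # Cmax/Tmax tie broken by the earliest time
  tie <- tibble::tibble(time_h = c(0, 1, 2, 3), conc_ug_per_L = c(1, 5, 5, 2))
  pk_tie <- compute_pk_outputs(tie, dose_ug = 10)
  expect_equal(pk_tie$cmax, 5)
  expect_equal(pk_tie$tmax, 1)
})

test_that("terminal-phase sufficiency gates the extrapolated outputs", {
  # last concentration at half of Cmax over a short window: insufficient
  t <- c(0, 0.5, 1, 1.5, 2)
  short <- tibble::tibble(time_h = t, conc_ug_per_L = 10 * exp(-0.35 * t))
  pk <- compute_pk_outputs(short, dose_ug = 100)
  expect_false(pk$terminal_sufficient)
  expect_true(is.na(pk$mrt))
  expect_true(is.na(pk$vdss))
  expect_true(is.na(pk$auc_inf))

  # plateau followed by a fast terminal phase: the last concentration is
  # still above 0.25 Cmax, but the window spans two terminal half-lives,
  # so the alternative clause grants sufficiency
  t2 <- seq(0, 8, by = 1)
  prof2 <- tibble::tibble(time_h = t2,
                          conc_ug_per_L = c(10, 9.8, 9.6, 9.4, 9.2, 6,
                                            4.5, 3.4, 2.6))
  expect_gt(2.6 / 10, 0.25)  # precondition of this scenario
  pk2 <- compute_pk_outputs(prof2, dose_ug = 100, route = "oral")
  expect_true(pk2$terminal_sufficient)
  expect_equal(pk2$sufficiency_rule, "two_half_lives")
  expect_false(is.na(pk2$mrt))
})

test_that("nca_table maps over a nested dataset table", {
  datasets <- tibble::tibble(
    dataset_id = c("a", "b"),
    route = c("iv_bolus", "oral"),
    dose_ug = c(100, 200),
    data = list(
      tibble::tibble(time_h = 0:5, conc_ug_per_L = 50 * exp(-0.8 * (0:5))),
      tibble::tibble(time_h = 0:5,
                     conc_ug_per_L = c(0, 8, 10, 7, 4, 2))))
  tab <- nca_table(datasets)
  expect_equal(nrow(tab), 2)
  expect_equal(tab$dataset_id, c("a", "b"))
  expect_equal(tab$cmax, c(50, 10))
  expect_equal(tab$tmax, c(0, 2))
})
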