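#' Linear-trapezoidal AUC and AUMC
#'
#' Area under the concentration-time curve and under the first-moment
#' curve, by the linear trapezoidal rule:
#' `AUC = sum (C_i + C_{i+1})/2 * dt`, with the same rule applied to
#' `t * C(t)` for AUMC.
#'
#' @param time_h Strictly increasing observation times, hours.
#' @param conc_ug_per_L Non-negative concentrations, ug/L.
#' @return AUC in ug*h/L; AUMC in ug*h^2/L.
#' @examples
#' auc_linear_trapezoid(c(0, 1, 2), c(10, 5, 2.5))   # 11.25
#' aumc_linear_trapezoid(c(0, 1, 2), c(10, 5, 2.5))  # 7.5
#' @export
auc_linear_trapezoid <- function(time_h, conc_ug_per_L) {
  check_series(time_h, conc_ug_per_L)
  dt <- diff(time_h)
  sum((utils::head(conc_ug_per_L, -1) + utils::tail(conc_ug_per_L, -1)) / 2 * dt)
}

#' @rdname auc_linear_trapezoid
#' @export
aumc_linear_trapezoid <- function(time_h, conc_ug_per_L) {
  check_series(time_h, conc_ug_per_L)
  auc_linear_trapezoid(time_h, time_h * conc_ug_per_L)
}

check_series <- function(time_h, conc_ug_per_L) {
  if (length(time_h) < 2 || length(time_h) != length(conc_ug_per_L)) {
    abort_pbpk("need at least 2 matched (time, concentration) points",
               class = "pbpkfit_nca_error")
  }
  if (any(diff(time_h) <= 0)) {
    abort_pbpk("times must be strictly increasing", class = "pbpkfit_nca_error")
  }
  if (any(conc_ug_per_L < 0) || any(time_h < 0)) {
    abort_pbpk("times and concentrations must be non-negative",
               class = "pbpkfit_nca_error")
  }
  invisible(TRUE)
}

#' Terminal-phase elimination rate constant
#'
#' Log-linear least-squares slope over the last points of the profile.
#' Candidate points are those strictly after Tmax with positive
#' concentration. The fit starts with the last `n_min` points and is
#' extended one point at a time (up to `n_max`) while the regression
#' r-squared improves. Returns `NA` when fewer than `n_min` candidates
#' exist or the fitted slope is not a positive elimination rate.
#'
#' @param time_h,conc_ug_per_L The profile.
#' @param n_min,n_max Minimum / maximum number of terminal points (3 / 6).
#' @return A list with `lambda_z` (1/h, or `NA`), `n_points`, `r_squared`.
#' @export
terminal_slope <- function(time_h, conc_ug_per_L, n_min = 3, n_max = 6) {
  check_series(time_h, conc_ug_per_L)
  tmax <- time_h[which.max(conc_ug_per_L)]
  cand <- which(time_h > tmax & conc_ug_per_L > 0)
  none <- list(lambda_z = NA_real_, n_points = 0L, r_squared = NA_real_)
  if (length(cand) < n_min) return(none)

  fit_n <- function(n) {
    idx <- utils::tail(cand, n)
    x <- time_h[idx]; y <- log(conc_ug_per_L[idx])
    slope <- stats::cov(x, y) / stats::var(x)
    r2 <- suppressWarnings(stats::cor(x, y)^2)
    list(lambda_z = -slope, n_points = n,
         r_squared = if (is.finite(r2)) r2 else NA_real_)
  }
  best <- fit_n(n_min)
  n <- n_min
  while (n < min(n_max, length(cand))) {
    nxt <- fit_n(n + 1)
    if (is.na(nxt$r_squared) || is.na(best$r_squared) ||
        nxt$r_squared <= best$r_squared) break
    best <- nxt
    n <- n + 1
  }
  if (!is.finite(best$lambda_z) || best$lambda_z <= 0) return(none)
  best
}

#' Non-compartmental PK outputs for one profile
#'
#' Computes Cmax and Tmax by scan (ties broken by earliest time), AUC0-t
#' and AUMC0-t by the linear trapezoidal rule, and - when the terminal
#' phase is sufficiently characterized - the extrapolated quantities:
#' `AUC0-inf = AUC0-t + C_last/lambda_z`,
#' `AUMC0-inf = AUMC0-t + C_last*t_last/lambda_z + C_last/lambda_z^2`,
#' `MRT = AUMC0-inf / AUC0-inf` and `Vdss = Dose * MRT / AUC0-inf`.
#'
#' The terminal phase counts as sufficient when the last observed
#' concentration has fallen below `0.25 * Cmax`, or when the time elapsed
#' since Tmax spans at least two terminal half-lives
#' (`t_last - tmax >= 2 ln 2 / lambda_z`); either clause suffices.
#' Extrapolated outputs additionally require a positive `lambda_z` from
#' [terminal_slope()]. After oral dosing MRT and Vdss are still computed
#' from the same formulas (MRT then includes mean absorption time); the
#' `route` column flags this.
#'
#' @param data A data frame with columns `time_h` and `conc_ug_per_L`
#'   (extra columns ignored).
#' @param dose_ug Administered dose, micrograms.
#' @param route Dose route label carried into the output (e.g. `"iv_bolus"`,
#'   `"oral"`).
#' @param dataset_id Optional identifier carried into the output.
#' @return A one-row tibble: `dataset_id`, `route`, `cmax`, `tmax`,
#'   `auc_0t`, `aumc_0t`, `lambda_z`, `n_lambda_points`,
#'   `terminal_sufficient`, `sufficiency_rule`, `auc_inf`, `aumc_inf`,
#'   `mrt`, `vdss`. Extrapolated fields are `NA` when unavailable.
#' @examples
#' prof <- tibble::tibble(time_h = 0:8, conc_ug_per_L = 100 * exp(-0.5 * (0:8)))
#' compute_pk_outputs(prof, dose_ug = 1000, route = "iv_bolus")
#' @export
compute_pk_outputs <- function(data, dose_ug, route = "iv_bolus",
                               dataset_id = NA_character_) {
  time_h <- data$time_h
  conc <- data$conc_ug_per_L
  check_series(time_h, conc)
  assert_number(dose_ug, "dose_ug", lower = 0, closed_lower = FALSE)

  i_max <- which.max(conc)  # which.max takes the first maximum: earliest tie
  cmax <- conc[i_max]
  tmax <- time_h[i_max]
  auc_0t <- auc_linear_trapezoid(time_h, conc)
  aumc_0t <- aumc_linear_trapezoid(time_h, conc)

  ts <- terminal_slope(time_h, conc)
  lambda_z <- ts$lambda_z
  c_last <- conc[length(conc)]
  t_last <- time_h[length(time_h)]

  below_quarter <- c_last < 0.25 * cmax
  two_halflives <- !is.na(lambda_z) && (t_last - tmax) >= 2 * log(2) / lambda_z
  sufficient <- below_quarter || two_halflives
  rule <- if (below_quarter && two_halflives) "both" else
    if (below_quarter) "below_quarter_cmax" else
    if (two_halflives) "two_half_lives" else NA_character_

  auc_inf <- aumc_inf <- mrt <- vdss <- NA_real_
  if (sufficient && !is.na(lambda_z) && c_last > 0) {
    auc_inf <- auc_0t + c_last / lambda_z
    aumc_inf <- aumc_0t + c_last * t_last / lambda_z + c_last / lambda_z^2
    mrt <- aumc_inf / auc_inf
    vdss <- dose_ug * mrt / auc_inf
  }

  tibble::tibble(
    dataset_id = dataset_id, route = route, dose_ug = dose_ug,
    cmax = cmax, tmax = tmax, auc_0t = auc_0t, aumc_0t = aumc_0t,
    lambda_z = lambda_z, n_lambda_points = ts$n_points,
    terminal_sufficient = sufficient, sufficiency_rule = rule,
    auc_inf = auc_inf, aumc_inf = aumc_inf, mrt = mrt, vdss = vdss)
}

#' NCA table for a set of datasets
#'
#' Maps [compute_pk_outputs()] over a nested dataset table (one row per
#' dose arm, profile in a `data` list-column), as produced by
#' [attach_manifest()] or [generate_study()].
#'
#' @param datasets Tibble with columns `dataset_id`, `route`, `dose_ug`,
#'   `data` (list of profile tibbles).
#' @return One row of PK outputs per dataset.
#' @export
nca_table <- function(datasets) {
  purrr::pmap_dfr(
    list(datasets$data, datasets$dose_ug, datasets$route, datasets$dataset_id),
    function(d, dose, route, id) compute_pk_outputs(d, dose, route, id))
}
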