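#' Average and absolute average fold error
#'
#' Geometric accuracy statistics for predicted versus observed PK outputs:
#' `AFE = 10 ^ mean(log10(pred/obs))` measures bias (under- or
#' over-prediction cancels), `AAFE = 10 ^ mean(|log10(pred/obs)|)` measures
#' spread (errors in opposite directions do not cancel). Both equal 1 for
#' perfect prediction and `AAFE >= max(AFE, 1/AFE)` always.
#'
#' @param pred,obs Positive numeric vectors of equal length.
#' @return A single fold value.
#' @examples
#' afe(c(2, 0.5), c(1, 1))   # 1
#' aafe(c(2, 0.5), c(1, 1))  # 2
#' @export
afe <- function(pred, obs) {
  check_fold_pairs(pred, obs)
  10^mean(log10(pred / obs))
}

#' @rdname afe
#' @export
aafe <- function(pred, obs) {
  check_fold_pairs(pred, obs)
  10^mean(abs(log10(pred / obs)))
}

check_fold_pairs <- function(pred, obs) {
  if (length(pred) != length(obs) || length(pred) < 1) {
    abort_pbpk("`pred` and `obs` must have equal length >= 1",
               class = "pbpkfit_metric_error")
  }
  bad <- which(!(pred > 0) | !(obs > 0))
  if (length(bad) > 0) {
    abort_pbpk(sprintf(
      "fold errors need positive values; offending pair(s) at index %s (pred = %s, obs = %s)",
      paste(bad, collapse = ","),
      paste(signif(pred[bad], 3), collapse = ","),
      paste(signif(obs[bad], 3), collapse = ",")),
      class = "pbpkfit_metric_error")
  }
  invisible(TRUE)
}

#' Fold-accuracy summary for one prediction set
#'
#' Percent of predictions within a fold threshold of observed, squared
#' Pearson correlation, and the AAFE contribution used for pooled GMFE.
#'
#' @inheritParams afe
#' @param fold Fold threshold (default 3): a pair counts as "within" when
#'   `pred/obs` lies in `[1/fold, fold]`.
#' @param log_scale Compute the correlation on log10-transformed values
#'   instead of raw values (default `FALSE`, matching a Pearson r-squared
#'   on raw values).
#' @return A one-row tibble: `n`, `afe`, `aafe`, `pct_within_fold`, `r2`
#'   (`NA` when `n < 2`).
#' @export
summary_stats <- function(pred, obs, fold = 3, log_scale = FALSE) {
  check_fold_pairs(pred, obs)
  ratio <- pred / obs
  within <- ratio >= 1 / fold & ratio <= fold
  r2 <- if (length(pred) >= 2) {
    x <- if (log_scale) log10(obs) else obs
    y <- if (log_scale) log10(pred) else pred
    r <- suppressWarnings(stats::cor(x, y))
    if (is.finite(r)) r^2 else NA_real_
  } else NA_real_
  tibble::tibble(n = length(pred), afe = afe(pred, obs),
                 aafe = aafe(pred, obs),
                 pct_within_fold = 100 * mean(within), r2 = r2)
}

# PK outputs scored in the accuracy report; the extrapolated ones respect
# the terminal-phase exclusion rule
REPORT_METRICS <- c("cmax", "tmax", "auc_0t", "aumc_0t", "auc_inf", "mrt",
                    "vdss")
EXTRAPOLATED_METRICS <- c("auc_inf", "mrt", "vdss")

#' Pair observed and predicted PK outputs for scoring
#'
#' Joins two [nca_table()] results by `dataset_id` and pivots the scored PK
#' outputs to long form, carrying the *observed* terminal-phase sufficiency
#' flag (the exclusion rule applies to observed data).
#'
#' @param observed_pk,predicted_pk Tibbles from [nca_table()] /
#'   [compute_pk_outputs()].
#' @param configuration Label recorded in the `configuration` column.
#' @return Long tibble: `dataset_id`, `configuration`, `metric`,
#'   `observed`, `predicted`, `observed_terminal_sufficient`.
#' @export
pk_pairs <- function(observed_pk, predicted_pk, configuration = "model") {
  missing_ids <- setdiff(observed_pk$dataset_id, predicted_pk$dataset_id)
  if (length(missing_ids) > 0) {
    abort_pbpk(paste0("predictions missing for dataset(s): ",
                      paste(missing_ids, collapse = ", ")),
               class = "pbpkfit_report_error")
  }
  obs_long <- observed_pk |>
    dplyr::select(dplyr::all_of(c("dataset_id", "terminal_sufficient",
                                  REPORT_METRICS))) |>
    tidyr::pivot_longer(dplyr::all_of(REPORT_METRICS), names_to = "metric",
                        values_to = "observed") |>
    dplyr::rename(observed_terminal_sufficient = "terminal_sufficient")
  pred_long <- predicted_pk |>
    dplyr::select(dplyr::all_of(c("dataset_id", REPORT_METRICS))) |>
    tidyr::pivot_longer(dplyr::all_of(REPORT_METRICS), names_to = "metric",
                        values_to = "predicted")
  obs_long |>
    dplyr::inner_join(pred_long, by = c("dataset_id", "metric")) |>
    dplyr::mutate(configuration = configuration, .after = "dataset_id")
}

#' Accuracy report across configurations
#'
#' Builds the per-metric, per-configuration accuracy grid (AFE, AAFE,
#' percent within 3-fold, Pearson r-squared, n) plus a pooled GMFE per
#' configuration. Datasets whose *observed* profile lacks a sufficiently
#' characterized terminal phase are excluded from the extrapolated rows
#' (AUC0-inf, MRT, Vdss) but retained everywhere else; pairs with a
#' missing observed or predicted value are dropped from their row.
#'
#' @param pairs A long tibble as produced by [pk_pairs()] (rows from
#'   several configurations can be bound together).
#' @param fold Fold threshold for the percent-within column (default 3).
#' @param log_scale_r2 Compute r-squared on log10 values (default `FALSE`).
#' @return An `accuracy_report`: list with `table` (metric x configuration
#'   grid) and `gmfe` (tibble `configuration`, `gmfe`, `n_pairs`).
#' @export
accuracy_report <- function(pairs, fold = 3, log_scale_r2 = FALSE) {
  required <- c("dataset_id", "configuration", "metric", "observed",
                "predicted", "observed_terminal_sufficient")
  missing_cols <- setdiff(required, names(pairs))
  if (length(missing_cols) > 0) {
    abort_pbpk(paste0("pairs table missing columns: ",
                      paste(missing_cols, collapse = ", ")),
               class = "pbpkfit_report_error")
  }
  usable <- pairs |>
    dplyr::filter(!(.data$metric %in% EXTRAPOLATED_METRICS) |
                    .data$observed_terminal_sufficient) |>
    dplyr::filter(is.finite(.data$observed), is.finite(.data$predicted),
                  .data$observed > 0, .data$predicted > 0)
  tab <- usable |>
    dplyr::group_by(.data$metric, .data$configuration) |>
    dplyr::reframe(summary_stats(.data$predicted, .data$observed,
                                 fold = fold, log_scale = log_scale_r2)) |>
    dplyr::mutate(metric = factor(.data$metric, levels = REPORT_METRICS)) |>
    dplyr::arrange(.data$metric, .data$configuration) |>
    dplyr::mutate(metric = as.character(.data$metric))
  gmfe <- usable |>
    dplyr::group_by(.data$configuration) |>
    dplyr::summarise(
      gmfe = 10^mean(abs(log10(.data$predicted / .data$observed))),
      n_pairs = dplyr::n())
  structure(list(table = tab, gmfe = gmfe, fold = fold),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat("<accuracy_report>\n")
  print(x$table, n = Inf)
  cat("pooled GMFE per configuration:\n")
  print(x$gmfe, n = Inf)
  invisible(x)
}

#' Compare two sets of tissue partition coefficients
#'
#' Ordinary least-squares regression of `log10 Kp` from one method on
#' another for a given tissue, across compounds, plus the mean absolute
#' fold difference `10 ^ mean(|log10(Kp_b / Kp_a)|)`. Used to quantify how
#' far an optimized effective Kp drifts from the mechanistic prediction.
#'
#' @param set_a,set_b Lists of [build_partition_set()] objects paired by
#'   compound (same order, equal length).
#' @param tissue Tissue name to compare.
#' @return A one-row tibble: `tissue`, `n`, `slope`, `intercept`, `r2`,
#'   `mean_abs_fold_difference`. Regression fields are `NA` with fewer
#'   than 2 pairs.
#' @export
kp_method_comparison <- function(set_a, set_b, tissue) {
  if (length(set_a) != length(set_b) || length(set_a) < 1) {
    abort_pbpk("`set_a` and `set_b` must be non-empty and paired",
               class = "pbpkfit_metric_error")
  }
  kp_a <- vapply(set_a, function(s) kp_vector(s)[[tissue]], numeric(1))
  kp_b <- vapply(set_b, function(s) kp_vector(s)[[tissue]], numeric(1))
  if (any(kp_a <= 0) || any(kp_b <= 0)) {
    abort_pbpk("partition coefficients must be positive",
               class = "pbpkfit_metric_error")
  }
  la <- log10(kp_a); lb <- log10(kp_b)
  fold <- 10^mean(abs(lb - la))
  if (length(la) >= 2 && stats::var(la) > 0) {
    fit <- stats::lm(lb ~ la)
    r <- suppressWarnings(stats::cor(la, lb))
    tibble::tibble(tissue = tissue, n = length(la),
                   slope = unname(stats::coef(fit)[2]),
                   intercept = unname(stats::coef(fit)[1]),
                   r2 = if (is.finite(r)) r^2 else NA_real_,
                   mean_abs_fold_difference = fold)
  } else {
    tibble::tibble(tissue = tissue, n = length(la), slope = NA_real_,
                   intercept = NA_real_, r2 = NA_real_,
                   mean_abs_fold_difference = fold)
  }
}
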