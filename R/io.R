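#' Read and write concentration-time CSV files
#'
#' The interchange format for observed or simulated profiles is a long CSV
#' with columns `dataset_id`, `time_h`, `conc_ug_per_L`, accompanied by a
#' JSON manifest describing each dose arm (`dataset_id`, `compound`,
#' `route`, `dose_ug`, optional `subject`). Reading validates the header,
#' rejects negative concentrations and duplicate `(dataset_id, time)`
#' rows (with the offending line number), and sorts each series by time.
#'
#' @param path CSV file path.
#' @return A long tibble `dataset_id`, `time_h`, `conc_ug_per_L`.
#' @export
read_concentration_csv <- function(path) {
  x <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("dataset_id", "time_h", "conc_ug_per_L")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort_pbpk(paste0("concentration CSV missing columns: ",
                      paste(missing_cols, collapse = ", "),
                      " (units are declared in the header names)"),
               class = "pbpkfit_load_error")
  }
  bad <- which(!is.finite(x$time_h) | !is.finite(x$conc_ug_per_L) |
                 x$time_h < 0 | x$conc_ug_per_L < 0)
  if (length(bad) > 0) {
    abort_pbpk(sprintf("malformed row at line %d: negative or missing value",
                       bad[1] + 1L), class = "pbpkfit_load_error")
  }
  dup <- duplicated(x[, c("dataset_id", "time_h")])
  if (any(dup)) {
    abort_pbpk(sprintf("duplicate timestamp at line %d (dataset %s, t = %g h)",
                       which(dup)[1] + 1L, x$dataset_id[which(dup)[1]],
                       x$time_h[which(dup)[1]]),
               class = "pbpkfit_load_error")
  }
  x |>
    dplyr::select(dplyr::all_of(required)) |>
    dplyr::arrange(.data$dataset_id, .data$time_h)
}

#' @rdname read_concentration_csv
#' @param datasets Either a long tibble (`dataset_id`, `time_h`,
#'   `conc_ug_per_L`) or a nested dataset tibble with a `data` list-column.
#' @export
write_concentration_csv <- function(datasets, path) {
  long <- if ("data" %in% names(datasets)) {
    tidyr::unnest(
      dplyr::select(datasets, dplyr::all_of(c("dataset_id", "data"))),
      "data")
  } else datasets
  readr::write_csv(long[, c("dataset_id", "time_h", "conc_ug_per_L")], path)
  invisible(path)
}

#' Combine a concentration table with its dose-arm manifest
#'
#' @param conc Long tibble from [read_concentration_csv()].
#' @param manifest Tibble (or list read from the manifest JSON) with
#'   columns `dataset_id`, `compound`, `route`, `dose_ug`.
#' @return Nested dataset tibble: one row per dataset with the profile in
#'   a `data` list-column, the shape consumed by [fit_compound()] and
#'   [nca_table()].
#' @export
attach_manifest <- function(conc, manifest) {
  manifest <- tibble::as_tibble(manifest)
  required <- c("dataset_id", "compound", "route", "dose_ug")
  missing_cols <- setdiff(required, names(manifest))
  if (length(missing_cols) > 0) {
    abort_pbpk(paste0("manifest missing columns: ",
                      paste(missing_cols, collapse = ", ")),
               class = "pbpkfit_load_error")
  }
  missing_ids <- setdiff(unique(conc$dataset_id), manifest$dataset_id)
  if (length(missing_ids) > 0) {
    abort_pbpk(paste0("manifest missing dataset(s): ",
                      paste(missing_ids, collapse = ", ")),
               class = "pbpkfit_load_error")
  }
  nested <- conc |>
    dplyr::group_by(.data$dataset_id) |>
    dplyr::arrange(.data$time_h, .by_group = TRUE) |>
    tidyr::nest(data = c("time_h", "conc_ug_per_L")) |>
    dplyr::ungroup()
  manifest |>
    dplyr::inner_join(nested, by = "dataset_id")
}

#' Write or read a study bundle on disk
#'
#' A [generate_study()] bundle is materialized as the same CSV + manifest
#' format the fitting pipeline reads, plus the hidden truth record in a
#' separate `truth.csv` that fitting entry points refuse to read.
#'
#' @param study A `study_bundle`.
#' @param dir Output directory (created if needed).
#' @return `write_study_bundle()` returns `dir` invisibly;
#'   `read_study_datasets()` returns the nested dataset tibble.
#' @export
write_study_bundle <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_concentration_csv(study$datasets, file.path(dir, "concentrations.csv"))
  manifest <- study$datasets[, c("dataset_id", "compound", "route", "dose_ug")]
  jsonlite::write_json(
    list(seed = study$seed, noise = study$noise, mechanism = study$mechanism,
         datasets = manifest),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    pretty = TRUE)
  readr::write_csv(study$truth, file.path(dir, "truth.csv"))
  for (cpd in study$compounds) {
    write_compound_config(
      cpd, file.path(dir, paste0(cpd$name, "_compound.json")))
  }
  invisible(dir)
}

#' @rdname write_study_bundle
#' @export
read_study_datasets <- function(dir) {
  conc <- read_concentration_csv(file.path(dir, "concentrations.csv"))
  m <- jsonlite::read_json(file.path(dir, "manifest.json"),
                           simplifyVector = TRUE)
  attach_manifest(conc, m$datasets)
}

#' Write a fit report
#'
#' Persists a [fit_compound()] result as a JSON summary (best parameters,
#' cost, convergence, seed, Kp cap) plus the full evaluation trajectory as
#' CSV for convergence plotting.
#'
#' @param fit A `pbpk_fit`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_fit_report <- function(fit, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  base <- file.path(dir, paste0(fit$compound_name, "_", fit$method))
  jsonlite::write_json(
    list(compound = fit$compound_name, method = fit$method,
         best_params = fit$best_params, best_cost = fit$best_cost,
         converged = fit$converged, phase_boundary = fit$phase_boundary,
         n_evaluations = nrow(fit$trajectory), kp_cap = fit$kp_cap,
         n_datasets = fit$n_datasets, seed = fit$seed),
    paste0(base, "_fit.json"), auto_unbox = TRUE, digits = NA, pretty = TRUE)
  readr::write_csv(fit$trajectory, paste0(base, "_trajectory.csv"))
  invisible(dir)
}

#' Write an accuracy report
#'
#' @param report An [accuracy_report()].
#' @param dir Output directory; writes `accuracy_table.csv` (the
#'   metric-by-configuration grid) and `accuracy_summary.json` (pooled
#'   GMFE per configuration).
#' @return `dir`, invisibly.
#' @export
write_accuracy_report <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  readr::write_csv(report$table, file.path(dir, "accuracy_table.csv"))
  jsonlite::write_json(list(fold = report$fold, gmfe = report$gmfe),
                       file.path(dir, "accuracy_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
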