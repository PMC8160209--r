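#' Score fitted configurations against observed data
#'
#' For every fit, re-simulates each of the compound's dose arms at the
#' observed timepoints under the fitted parameters, runs the same
#' non-compartmental analysis on observed and simulated profiles, and
#' assembles the fold-error accuracy grid across configurations (see
#' [accuracy_report()]).
#'
#' @param fits A tibble from [fit_study()] (columns `compound`, `method`,
#'   `fit`), or a list of `pbpk_fit` objects.
#' @param compounds Named list of [compound_profile()] objects (names =
#'   compound names), or a `study_bundle`.
#' @param datasets Nested observed-dataset tibble with a `compound`
#'   column; taken from the bundle when `compounds` is a `study_bundle`.
#' @param physiology A [load_physiology()] object.
#' @param fold Fold threshold for the report (default 3).
#' @return An `accuracy_report` with one configuration per distinct fit
#'   method; attribute `"pairs"` holds the long observed/predicted table.
#' @export
evaluate_fits <- function(fits, compounds, datasets = NULL,
                          physiology = load_physiology(), fold = 3) {
  if (inherits(compounds, "study_bundle")) {
    datasets <- datasets %||% compounds$datasets
    compounds <- compounds$compounds
  }
  if (!is.data.frame(fits)) {
    fits <- tibble::tibble(
      compound = vapply(fits, `[[`, character(1), "compound_name"),
      method = vapply(fits, `[[`, character(1), "method"),
      fit = fits)
  }
  names(compounds) <- vapply(compounds, `[[`, character(1), "name")
  missing_cpds <- setdiff(fits$compound, names(compounds))
  if (length(missing_cpds) > 0) {
    abort_pbpk(paste0("no compound profile for fitted compound(s): ",
                      paste(missing_cpds, collapse = ", ")),
               class = "pbpkfit_report_error")
  }
  pairs <- list()
  for (i in seq_len(nrow(fits))) {
    f <- fits$fit[[i]]
    cpd <- compounds[[fits$compound[i]]]
    ds <- datasets[datasets$compound == cpd$name, , drop = FALSE]
    if (nrow(ds) == 0) {
      abort_pbpk(paste0("no observed datasets for compound ", cpd$name),
                 class = "pbpkfit_report_error")
    }
    pred <- predict_profiles(cpd, physiology, f$method, f$best_params, ds,
                             kp_cap = f$kp_cap)
    if (is.null(pred)) {
      abort_pbpk(paste0("simulation failed at fitted parameters for ",
                        cpd$name, " / ", f$method),
                 class = "pbpkfit_report_error")
    }
    obs_pk <- nca_table(ds)
    pred_pk <- nca_table(pred)
    pairs[[i]] <- pk_pairs(obs_pk, pred_pk, configuration = f$method)
  }
  pairs <- dplyr::bind_rows(pairs)
  rep <- accuracy_report(pairs, fold = fold)
  attr(rep, "pairs") <- pairs
  rep
}
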