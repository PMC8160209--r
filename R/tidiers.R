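#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a PBPK fit
#'
#' `tidy()` returns one row per fitted parameter; `glance()` returns a
#' one-row model summary (cost, convergence, evaluation counts).
#'
#' @param x A `pbpk_fit` from [fit_compound()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.pbpk_fit <- function(x, ...) {
  if (length(x$best_params) == 0) {
    return(tibble::tibble(term = character(), estimate = numeric()))
  }
  tibble::tibble(term = names(x$best_params),
                 estimate = unlist(x$best_params, use.names = FALSE))
}

#' @rdname tidy.pbpk_fit
#' @export
glance.pbpk_fit <- function(x, ...) {
  tibble::tibble(compound = x$compound_name, method = x$method,
                 best_cost = x$best_cost, converged = x$converged,
                 n_evaluations = nrow(x$trajectory),
                 phase_boundary = x$phase_boundary,
                 n_datasets = x$n_datasets, kp_cap = x$kp_cap,
                 seed = x$seed)
}

#' Tidy an accuracy report
#'
#' `tidy()` returns the metric-by-configuration grid; `glance()` the
#' pooled GMFE per configuration.
#'
#' @param x An [accuracy_report()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.accuracy_report <- function(x, ...) x$table

#' @rdname tidy.accuracy_report
#' @export
glance.accuracy_report <- function(x, ...) x$gmfe
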