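#' Ionization specifications
#'
#' A compound's ionization class decides which Rodgers-Rowland equation
#' applies. Moderate-to-strong monoprotic bases (basic pKa >= 7) partition
#' into acidic phospholipids and use the class-1 equation; acids, weak
#' bases, neutrals and (class-2) zwitterions associate with tissue proteins
#' and use the class-2 equation.
#'
#' @param pka Acid or base dissociation constant (pH units).
#' @param pka_acid,pka_base The two dissociation constants of a zwitterion.
#' @return A list of class `ionization_spec` with fields `cls`, `pka_acid`,
#'   `pka_base`.
#' @name ionization
NULL

new_ionization <- function(cls, pka_acid = NA_real_, pka_base = NA_real_) {
  structure(list(cls = cls, pka_acid = pka_acid, pka_base = pka_base),
            class = "ionization_spec")
}

#' @rdname ionization
#' @export
ionization_neutral <- function() new_ionization("neutral")

#' @rdname ionization
#' @export
ionization_acid <- function(pka) {
  assert_number(pka, "pka")
  new_ionization("monoprotic_acid", pka_acid = pka)
}

#' @rdname ionization
#' @export
ionization_base <- function(pka) {
  assert_number(pka, "pka")
  if (pka >= 7) new_ionization("monoprotic_base_strong", pka_base = pka)
  else new_ionization("monoprotic_base_weak", pka_base = pka)
}

#' @rdname ionization
#' @export
ionization_zwitterion <- function(pka_acid, pka_base) {
  assert_number(pka_acid, "pka_acid")
  assert_number(pka_base, "pka_base")
  new_ionization("zwitterion", pka_acid = pka_acid, pka_base = pka_base)
}

#' @export
print.ionization_spec <- function(x, ...) {
  cat("<ionization_spec>", x$cls)
  if (!is.na(x$pka_acid)) cat(sprintf(" pKa_acid=%.2f", x$pka_acid))
  if (!is.na(x$pka_base)) cat(sprintf(" pKa_base=%.2f", x$pka_base))
  cat("\n")
  invisible(x)
}

#' Create a compound parameter record
#'
#' Bundles the drug-specific physicochemical and pharmacokinetic parameters
#' consumed by partition prediction, simulation and optimization.
#'
#' @param name Compound identifier.
#' @param logp Octanol-water log10 partition coefficient.
#' @param ionization An [ionization_acid()], [ionization_base()],
#'   [ionization_neutral()] or [ionization_zwitterion()] spec.
#' @param fup Fraction unbound in plasma, in (0, 1].
#' @param bp_ratio Whole-blood to plasma concentration ratio (> 0).
#' @param cl_hepatic Hepatic clearance, L/h. Hepatic metabolism and biliary
#'   elimination are lumped into this single parameter.
#' @param cl_renal Renal clearance, L/h.
#' @param ka First-order oral absorption rate constant, 1/h. Required (> 0)
#'   only when oral doses are simulated.
#' @param f_oral Fraction of an oral dose reaching portal blood (absorbed
#'   fraction times gut escape), in (0, 1]. First-pass hepatic loss is *not*
#'   part of `f_oral`; it emerges mechanistically from the portal topology.
#' @return A list of class `compound_profile`.
#' @examples
#' compound_profile("midazolam-like", logp = 3.2,
#'                  ionization = ionization_base(6.0), fup = 0.02,
#'                  bp_ratio = 0.66, cl_hepatic = 25, cl_renal = 0,
#'                  ka = 1.5, f_oral = 0.9)
#' @export
compound_profile <- function(name, logp, ionization, fup, bp_ratio,
                             cl_hepatic, cl_renal = 0, ka = NA_real_,
                             f_oral = 1) {
  stopifnot(is.character(name), length(name) == 1L)
  assert_number(logp, "logp")
  if (!inherits(ionization, "ionization_spec")) {
    abort_pbpk("`ionization` must be an ionization_spec",
               class = "pbpkfit_domain_error")
  }
  assert_number(fup, "fup", lower = 0, upper = 1, closed_lower = FALSE)
  assert_number(bp_ratio, "bp_ratio", lower = 0, closed_lower = FALSE)
  assert_number(cl_hepatic, "cl_hepatic", lower = 0)
  assert_number(cl_renal, "cl_renal", lower = 0)
  if (!is.na(ka)) assert_number(ka, "ka", lower = 0, closed_lower = FALSE)
  assert_number(f_oral, "f_oral", lower = 0, upper = 1, closed_lower = FALSE)
  structure(list(name = name, logp = logp, ionization = ionization,
                 fup = fup, bp_ratio = bp_ratio, cl_hepatic = cl_hepatic,
                 cl_renal = cl_renal, ka = ka, f_oral = f_oral),
            class = "compound_profile")
}

#' @export
print.compound_profile <- function(x, ...) {
  cat(sprintf("<compound_profile> %s\n", x$name))
  cat(sprintf("  logP %.2f, %s, fup %.3g, B:P %.3g\n",
              x$logp, x$ionization$cls, x$fup, x$bp_ratio))
  cat(sprintf("  CL hepatic %.3g L/h, CL renal %.3g L/h, ka %s 1/h, F %.2f\n",
              x$cl_hepatic, x$cl_renal,
              if (is.na(x$ka)) "NA" else sprintf("%.3g", x$ka), x$f_oral))
  invisible(x)
}

# replace selected parameters (used by the optimizer)
update_compound <- function(compound, params) {
  for (nm in names(params)) {
    if (nm == "logp") compound$logp <- params[[nm]]
    else if (nm %in% c("bp_ratio", "ka")) compound[[nm]] <- params[[nm]]
  }
  compound
}

#' Read or write a compound configuration file
#'
#' Compound parameters travel as a small JSON document mirroring the
#' [compound_profile()] fields, with ionization expressed as
#' `{"class": ..., "pka_acid": ..., "pka_base": ...}` and an optional
#' `doses` list (fields `route`, `amount_ug`, `start_time_h`,
#' `duration_h`).
#'
#' @param path File path.
#' @param compound A `compound_profile`.
#' @param doses Optional dose-event tibble (see [dose_iv_bolus()]).
#' @return `read_compound_config()` returns a list with elements `compound`
#'   and `doses` (a tibble, possibly empty); `write_compound_config()`
#'   returns `path` invisibly.
#' @export
read_compound_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ion <- switch(x$ionization$class,
    neutral = ionization_neutral(),
    monoprotic_acid = ionization_acid(x$ionization$pka_acid),
    monoprotic_base_strong = ,
    monoprotic_base_weak = ionization_base(x$ionization$pka_base),
    zwitterion = ionization_zwitterion(x$ionization$pka_acid,
                                       x$ionization$pka_base),
    abort_pbpk(paste0("unknown ionization class: ", x$ionization$class),
               class = "pbpkfit_load_error")
  )
  compound <- compound_profile(
    name = x$name, logp = x$logp, ionization = ion, fup = x$fup,
    bp_ratio = x$bp_ratio, cl_hepatic = x$cl_hepatic,
    cl_renal = x$cl_renal %||% 0, ka = x$ka %||% NA_real_,
    f_oral = x$f_oral %||% 1)
  doses <- if (!is.null(x$doses)) tibble::as_tibble(x$doses) else
    tibble::tibble(route = character(), amount_ug = numeric(),
                   start_time_h = numeric(), duration_h = numeric())
  list(compound = compound, doses = doses)
}

#' @rdname read_compound_config
#' @export
write_compound_config <- function(compound, path, doses = NULL) {
  x <- list(
    name = compound$name, logp = compound$logp,
    ionization = list(class = compound$ionization$cls,
                      pka_acid = compound$ionization$pka_acid,
                      pka_base = compound$ionization$pka_base),
    fup = compound$fup, bp_ratio = compound$bp_ratio,
    cl_hepatic = compound$cl_hepatic, cl_renal = compound$cl_renal,
    ka = compound$ka, f_oral = compound$f_oral)
  if (!is.null(doses)) x$doses <- doses
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  invisible(path)
}
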