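# internal helpers shared across modules

`%||%` <- function(x, y) if (is.null(x)) y else x

abort_pbpk <- function(msg, class = "pbpkfit_error") {
  rlang::abort(msg, class = class)
}

# log10-spaced sequence, endpoints included
logspace <- function(from, to, n) {
  stopifnot(from > 0, to > 0)
  10^seq(log10(from), log10(to), length.out = n)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

assert_number <- function(x, name, lower = -Inf, upper = Inf,
                          closed_lower = TRUE, closed_upper = TRUE) {
  ok <- is_number(x) &&
    (if (closed_lower) x >= lower else x > lower) &&
    (if (closed_upper) x <= upper else x < upper)
  if (!ok) {
    abort_pbpk(sprintf("`%s` must be a single finite number in %s%g, %g%s (got %s)",
                       name,
                       if (closed_lower) "[" else "(", lower, upper,
                       if (closed_upper) "]" else ")",
                       paste(format(x), collapse = ", ")),
               class = "pbpkfit_domain_error")
  }
  invisible(x)
}

# tissue compartments that carry a partition coefficient (everything but the
# two blood compartments); lung is a tissue here
TISSUE_COMPARTMENTS <- c("lung", "adipose", "bone", "brain", "gut", "heart",
                         "kidney", "liver", "muscle", "skin", "spleen",
                         "rest_of_body")
BLOOD_COMPARTMENTS <- c("venous_blood", "arterial_blood")
ALL_COMPARTMENTS <- c(BLOOD_COMPARTMENTS, TISSUE_COMPARTMENTS)

# tissues whose venous outflow drains portally into the liver
PORTAL_TISSUES <- c("gut", "spleen")
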