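#' Load a subject physiology table
#'
#' Reads a per-tissue physiology CSV (organ volumes, blood flows, tissue
#' composition) together with a JSON sidecar of whole-body quantities
#' (cardiac output, hematocrit, plasma pH, blood volume, body weight,
#' plasma and red-blood-cell composition) and returns a validated
#' `subject_physiology` object.
#'
#' The 14-compartment roster is fixed: venous and arterial blood, lung, and
#' twelve perfused tissues (adipose, bone, brain, gut, heart, kidney, liver,
#' muscle, skin, spleen, rest-of-body). The liver row's `flow_L_per_h` is the
#' hepatic *arterial* flow only; gut and spleen drain portally into the
#' liver, so total hepatic inflow is the sum of the three. Loading fails if
#' any compartment is missing, any volume or flow is non-positive, the lung
#' flow does not equal cardiac output, or the non-lung tissue flows do not
#' sum to cardiac output (relative tolerance 1e-6).
#'
#' @param path Path to the physiology CSV with columns
#'   `tissue, volume_L, flow_L_per_h, f_ew, f_iw, f_nl, f_np, ap_mg_per_g,
#'   ph_iw, protein_ratio`. Composition columns may be `NA` for the two
#'   blood compartments.
#' @param globals_path Path to the JSON sidecar. Defaults to the file named
#'   like `path` with `_globals.json` substituted for `.csv`, falling back
#'   to the bundled human-adult sidecar.
#' @return A `subject_physiology` object: a list with elements `tissues`
#'   (a tibble, one row per compartment), `cardiac_output`, `hematocrit`,
#'   `plasma_ph`, `blood_volume`, `body_weight`, `plasma_composition`
#'   (list: `f_nl`, `f_np`) and `blood_cells` (list: `f_ew`, `f_iw`,
#'   `f_nl`, `f_np`, `ap_mg_per_g`, `ph_iw`).
#' @examples
#' phys <- load_physiology()
#' phys$cardiac_output
#' @export
load_physiology <- function(path = NULL, globals_path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "human_adult_physiology.csv",
                        package = "pbpkfit", mustWork = TRUE)
  }
  if (is.null(globals_path)) {
    cand <- sub("\\.csv$", "_globals.json", path)
    globals_path <- if (file.exists(cand)) cand else
      system.file("extdata", "human_adult_globals.json",
                  package = "pbpkfit", mustWork = TRUE)
  }
  tissues <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  required_cols <- c("tissue", "volume_L", "flow_L_per_h", "f_ew", "f_iw",
                     "f_nl", "f_np", "ap_mg_per_g", "ph_iw", "protein_ratio")
  missing_cols <- setdiff(required_cols, names(tissues))
  if (length(missing_cols) > 0) {
    abort_pbpk(paste0("physiology table missing columns: ",
                      paste(missing_cols, collapse = ", ")),
               class = "pbpkfit_load_error")
  }
  g <- jsonlite::read_json(globals_path, simplifyVector = TRUE)

  missing_tissues <- setdiff(ALL_COMPARTMENTS, tissues$tissue)
  if (length(missing_tissues) > 0) {
    abort_pbpk(paste0("missing tissue: ", paste(missing_tissues, collapse = ", ")),
               class = "pbpkfit_load_error")
  }
  tissues <- tissues[match(ALL_COMPARTMENTS, tissues$tissue), , drop = FALSE]

  bad <- tissues$tissue[tissues$volume_L <= 0 | !is.finite(tissues$volume_L)]
  if (length(bad) > 0) {
    abort_pbpk(paste0("non-positive volume: ", paste(bad, collapse = ", ")),
               class = "pbpkfit_load_error")
  }
  bad <- tissues$tissue[tissues$flow_L_per_h <= 0 | !is.finite(tissues$flow_L_per_h)]
  if (length(bad) > 0) {
    abort_pbpk(paste0("non-positive flow: ", paste(bad, collapse = ", ")),
               class = "pbpkfit_load_error")
  }

  co <- g$cardiac_output_L_per_h
  assert_number(co, "cardiac_output_L_per_h", lower = 0, closed_lower = FALSE)
  perfused <- setdiff(TISSUE_COMPARTMENTS, "lung")
  flow_sum <- sum(tissues$flow_L_per_h[tissues$tissue %in% perfused])
  if (abs(flow_sum - co) > 1e-6 * co) {
    abort_pbpk(sprintf(
      "flow balance violated: non-lung tissue flows sum to %.6g L/h but cardiac output is %.6g L/h",
      flow_sum, co), class = "pbpkfit_load_error")
  }
  lung_flow <- tissues$flow_L_per_h[tissues$tissue == "lung"]
  if (abs(lung_flow - co) > 1e-6 * co) {
    abort_pbpk("flow balance violated: lung flow must equal cardiac output",
               class = "pbpkfit_load_error")
  }

  comp_cols <- c("f_ew", "f_iw", "f_nl", "f_np")
  tt <- tissues[tissues$tissue %in% TISSUE_COMPARTMENTS, ]
  fr <- as.matrix(tt[, comp_cols])
  if (any(fr < 0 | fr > 1) || any(rowSums(fr) > 1 + 1e-9)) {
    abort_pbpk("tissue composition fractions must lie in [0,1] and sum to at most 1",
               class = "pbpkfit_load_error")
  }
  if (any(tt$ph_iw < 6 | tt$ph_iw > 8)) {
    abort_pbpk("intracellular pH outside [6, 8]", class = "pbpkfit_load_error")
  }

  hct <- g$hematocrit
  assert_number(hct, "hematocrit", lower = 0, upper = 1,
                closed_lower = FALSE, closed_upper = FALSE)

  phys <- structure(list(
    tissues = tibble::as_tibble(tissues),
    cardiac_output = co,
    hematocrit = hct,
    plasma_ph = g$plasma_ph,
    blood_volume = g$blood_volume_L,
    body_weight = g$body_weight_kg,
    plasma_composition = as.list(g$plasma_composition),
    blood_cells = as.list(g$blood_cells)
  ), class = "subject_physiology")
  phys
}

#' @export
print.subject_physiology <- function(x, ...) {
  cat("<subject_physiology>\n")
  cat(sprintf("  %d compartments, cardiac output %.1f L/h, hematocrit %.2f, body weight %.0f kg\n",
              nrow(x$tissues), x$cardiac_output, x$hematocrit, x$body_weight))
  print(x$tissues, n = 5)
  invisible(x)
}

# named volume / flow / Kp lookup helpers
tissue_volume <- function(physiology, tissue) {
  physiology$tissues$volume_L[match(tissue, physiology$tissues$tissue)]
}
tissue_flow <- function(physiology, tissue) {
  physiology$tissues$flow_L_per_h[match(tissue, physiology$tissues$tissue)]
}

# composition row as a plain list (class-dispatch input for the Rodgers
# equations)
tissue_composition <- function(physiology, tissue) {
  row <- physiology$tissues[physiology$tissues$tissue == tissue, ]
  if (nrow(row) != 1) {
    abort_pbpk(paste0("unknown tissue: ", tissue), class = "pbpkfit_domain_error")
  }
  list(f_ew = row$f_ew, f_iw = row$f_iw, f_nl = row$f_nl, f_np = row$f_np,
       ap_mg_per_g = row$ap_mg_per_g, ph_iw = row$ph_iw,
       protein_ratio = row$protein_ratio)
}

#' Pre-fit consistency checks for a compound against a physiology
#'
#' Applies the data-curation rules used before any fit: total clearance must
#' stay below cardiac output, the blood:plasma ratio cannot fall below
#' `1 - hematocrit` (a drug fully excluded from red cells still occupies the
#' plasma fraction of blood), and an *observed* non-compartmental Vdss, when
#' supplied, cannot be smaller than blood volume. Validation never raises:
#' it returns a report, empty when every rule passes.
#'
#' @param compound A [compound_profile()].
#' @param physiology A [load_physiology()] object.
#' @param observed_vdss Optional observed steady-state volume of
#'   distribution (L) from non-compartmental analysis of observed data.
#' @return A tibble with columns `rule`, `message`, `value`, `bound`;
#'   zero rows when the compound passes all checks.
#' @examples
#' phys <- load_physiology()
#' cpd <- compound_profile("ok", logp = 2, ionization = ionization_neutral(),
#'                         fup = 0.5, bp_ratio = 1, cl_hepatic = 20,
#'                         cl_renal = 5)
#' validate_compound(cpd, phys)
#' @export
validate_compound <- function(compound, physiology, observed_vdss = NULL) {
  stopifnot(inherits(compound, "compound_profile"),
            inherits(physiology, "subject_physiology"))
  out <- list()
  cl_total <- compound$cl_hepatic + compound$cl_renal
  if (cl_total >= physiology$cardiac_output) {
    out[[length(out) + 1L]] <- tibble::tibble(
      rule = "cl_vs_co",
      message = sprintf("total clearance %.3g L/h is not below cardiac output %.3g L/h",
                        cl_total, physiology$cardiac_output),
      value = cl_total, bound = physiology$cardiac_output)
  }
  bp_floor <- 1 - physiology$hematocrit
  if (compound$bp_ratio < bp_floor) {
    out[[length(out) + 1L]] <- tibble::tibble(
      rule = "bp_floor",
      message = sprintf("blood:plasma ratio %.3g is below the physiological floor 1 - hematocrit = %.3g",
                        compound$bp_ratio, bp_floor),
      value = compound$bp_ratio, bound = bp_floor)
  }
  if (!is.null(observed_vdss) && !is.na(observed_vdss) &&
      observed_vdss < physiology$blood_volume) {
    out[[length(out) + 1L]] <- tibble::tibble(
      rule = "vdss_floor",
      message = sprintf("observed Vdss %.3g L is below blood volume %.3g L",
                        observed_vdss, physiology$blood_volume),
      value = observed_vdss, bound = physiology$blood_volume)
  }
  if (length(out) == 0) {
    tibble::tibble(rule = character(), message = character(),
                   value = numeric(), bound = numeric())
  } else {
    dplyr::bind_rows(out)
  }
}
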