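#' Tissue:plasma partition coefficients
#'
#' Mechanistic prediction of the unbound tissue:plasma partition coefficient
#' (Kpu) from tissue composition, following the Rodgers-Rowland treatment of
#' ionization. Two closed forms exist: class 1 for moderate-to-strong
#' monoprotic bases (basic pKa >= 7), where intracellular binding is to
#' acidic phospholipids, and class 2 for acids, weak bases, neutrals and
#' zwitterions, where extracellular binding is to tissue proteins. The total
#' partition coefficient is `Kp = Kpu * fup`.
#'
#' For adipose the neutral-lipid term uses a vegetable-oil:water partition
#' coefficient, `log10 P_vo:w = 1.115 * logP - 1.35`, instead of the
#' octanol-water value; octanol over-represents partitioning into storage
#' fat. The neutral-phospholipid term keeps the octanol scale.
#'
#' @name partition
NULL

# octanol P and the neutral-lipid-term P, which differs only for adipose
lipid_partition_coefs <- function(logp, adipose = FALSE) {
  p <- 10^logp
  p_nl <- if (adipose) 10^(1.115 * logp - 1.35) else p
  list(p = p, p_nl = p_nl)
}

#' @rdname partition
#' @param compound A [compound_profile()]; must be a moderate-to-strong
#'   monoprotic base for `kpu_class1_base()` and any other class for
#'   `kpu_class2()`.
#' @param tissue A tissue composition: a list with fields `f_ew`, `f_iw`,
#'   `f_nl`, `f_np`, `ap_mg_per_g`, `ph_iw`, `protein_ratio` (see
#'   `tissue_composition()` rows of a loaded physiology).
#' @param ka_ap Association constant for acidic phospholipids, from
#'   [kaap_from_blood()]. Must be >= 0.
#' @param plasma_ph Plasma pH.
#' @param adipose Use the vegetable-oil scale for the neutral-lipid term.
#' @return Unbound tissue:plasma partition coefficient (dimensionless, > 0).
#' @export
kpu_class1_base <- function(compound, tissue, ka_ap, plasma_ph,
                            adipose = FALSE) {
  if (compound$ionization$cls != "monoprotic_base_strong") {
    abort_pbpk(sprintf(
      "kpu_class1_base applies to moderate-to-strong monoprotic bases, not %s",
      compound$ionization$cls), class = "pbpkfit_class_error")
  }
  if (!is_number(ka_ap) || ka_ap < 0) {
    abort_pbpk("`ka_ap` must be >= 0", class = "pbpkfit_domain_error")
  }
  pka <- compound$ionization$pka_base
  lp <- lipid_partition_coefs(compound$logp, adipose = adipose)
  ion_iw <- 10^(pka - tissue$ph_iw)   # ionized:neutral ratio, cell water
  ion_p <- 10^(pka - plasma_ph)       # ionized:neutral ratio, plasma
  tissue$f_ew +
    (1 + ion_iw) / (1 + ion_p) * tissue$f_iw +
    ka_ap * tissue$ap_mg_per_g * ion_iw / (1 + ion_p) +
    (lp$p_nl * tissue$f_nl + (0.3 * lp$p + 0.7) * tissue$f_np) / (1 + ion_p)
}

#' Acidic-phospholipid association constant from blood partitioning
#'
#' For class-1 bases the acidic-phospholipid association constant `KaAP` is
#' not measured directly; it is back-calculated from the observed
#' blood:plasma ratio. The unbound red-cell:plasma partition coefficient is
#' `Kpu_BC = (B:P - (1 - Hct)) / (Hct * fup)`; substituting the red-cell
#' composition into the class-1 equation and solving for `KaAP` gives the
#' constant, clamped at zero when red-cell partitioning is fully explained
#' by water and lipids.
#'
#' @inheritParams kpu_class1_base
#' @param blood_cells Red-blood-cell composition list (`f_ew`, `f_iw`,
#'   `f_nl`, `f_np`, `ap_mg_per_g`, `ph_iw`), e.g. `physiology$blood_cells`.
#' @param hematocrit Hematocrit fraction in (0, 1).
#' @return `KaAP` >= 0.
#' @export
kaap_from_blood <- function(compound, blood_cells, hematocrit, plasma_ph) {
  if (compound$ionization$cls != "monoprotic_base_strong") {
    abort_pbpk(sprintf(
      "kaap_from_blood applies to moderate-to-strong monoprotic bases, not %s",
      compound$ionization$cls), class = "pbpkfit_class_error")
  }
  bp <- compound$bp_ratio
  if (bp <= 1 - hematocrit) {
    abort_pbpk(sprintf(
      "no cell partitioning: B:P = %.3g does not exceed 1 - hematocrit = %.3g",
      bp, 1 - hematocrit), class = "pbpkfit_domain_error")
  }
  kpu_bc <- (bp - (1 - hematocrit)) / (hematocrit * compound$fup)
  pka <- compound$ionization$pka_base
  lp <- lipid_partition_coefs(compound$logp)
  ion_bc <- 10^(pka - blood_cells$ph_iw)
  ion_p <- 10^(pka - plasma_ph)
  base_terms <- (blood_cells$f_ew %||% 0) +
    (1 + ion_bc) / (1 + ion_p) * blood_cells$f_iw +
    (lp$p_nl * blood_cells$f_nl + (0.3 * lp$p + 0.7) * blood_cells$f_np) /
      (1 + ion_p)
  ka_ap <- (kpu_bc - base_terms) * (1 + ion_p) /
    (blood_cells$ap_mg_per_g * ion_bc)
  max(ka_ap, 0)
}

# intracellular (X) and plasma (Y) ionized:neutral ratios for class 2
class2_ionization_ratios <- function(ionization, ph_iw, plasma_ph) {
  switch(ionization$cls,
    monoprotic_acid = list(
      x = 10^(ph_iw - ionization$pka_acid),
      y = 10^(plasma_ph - ionization$pka_acid)),
    monoprotic_base_weak = list(
      x = 10^(ionization$pka_base - ph_iw),
      y = 10^(ionization$pka_base - plasma_ph)),
    neutral = list(x = 0, y = 0),
    zwitterion = list(
      x = 10^(ionization$pka_base - ph_iw) + 10^(ph_iw - ionization$pka_acid),
      y = 10^(ionization$pka_base - plasma_ph) +
        10^(plasma_ph - ionization$pka_acid)),
    abort_pbpk(sprintf(
      "kpu_class2 applies to acids, weak bases, neutrals and zwitterions, not %s",
      ionization$cls), class = "pbpkfit_class_error")
  )
}

#' @rdname partition
#' @param fup Fraction unbound in plasma, (0, 1].
#' @param plasma_composition Plasma neutral-lipid fractions, a list with
#'   `f_nl` and `f_np` (e.g. `physiology$plasma_composition`). The
#'   tissue-protein association is back-calculated from `fup` net of
#'   plasma-lipid partitioning and scaled to tissue by the tissue:plasma
#'   binding-protein ratio, clamped at zero.
#' @export
kpu_class2 <- function(compound, tissue, plasma_ph, fup,
                       plasma_composition = list(f_nl = 0, f_np = 0),
                       adipose = FALSE) {
  assert_number(fup, "fup", lower = 0, upper = 1, closed_lower = FALSE)
  r <- class2_ionization_ratios(compound$ionization, tissue$ph_iw, plasma_ph)
  lp <- lipid_partition_coefs(compound$logp, adipose = adipose)
  lp_p <- lipid_partition_coefs(compound$logp) # plasma lipids: octanol scale
  plasma_lipid_term <- (lp_p$p * plasma_composition$f_nl +
    (0.3 * lp_p$p + 0.7) * plasma_composition$f_np) / (1 + r$y)
  ka_pr_plasma <- max(1 / fup - 1 - plasma_lipid_term, 0)
  tissue$f_ew +
    (1 + r$x) / (1 + r$y) * tissue$f_iw +
    (lp$p_nl * tissue$f_nl + (0.3 * lp$p + 0.7) * tissue$f_np) / (1 + r$y) +
    ka_pr_plasma * (tissue$protein_ratio %||% 0)
}

# dispatch to the right Kpu equation for one tissue
kpu_for_tissue <- function(compound, physiology, tissue_name, ka_ap = NULL) {
  comp <- tissue_composition(physiology, tissue_name)
  adipose <- identical(tissue_name, "adipose")
  if (compound$ionization$cls == "monoprotic_base_strong") {
    if (is.null(ka_ap)) {
      ka_ap <- kaap_from_blood(compound, physiology$blood_cells,
                               physiology$hematocrit, physiology$plasma_ph)
    }
    kpu_class1_base(compound, comp, ka_ap, physiology$plasma_ph,
                    adipose = adipose)
  } else {
    kpu_class2(compound, comp, physiology$plasma_ph, compound$fup,
               plasma_composition = physiology$plasma_composition,
               adipose = adipose)
  }
}

#' Build the per-tissue partition set for a simulation
#'
#' Produces total tissue:plasma partition coefficients (`Kp = Kpu * fup`)
#' for the twelve tissue compartments under one of three configurations:
#'
#' * `rodgers_fixed` - Rodgers-Rowland prediction from the compound's own
#'   (measured) logP;
#' * `rodgers_logp_optimized` - the same equations driven by an optimized
#'   `logp_override`;
#' * `kp_optimized` - a single effective `kp_scalar` applied to every
#'   tissue compartment (eliminating organs included), bypassing the
#'   mechanistic equations.
#'
#' The physiological cap rule ([apply_kp_cap()]) is applied before the set
#' is returned.
#'
#' @param compound A [compound_profile()].
#' @param physiology A [load_physiology()] object.
#' @param method One of `"rodgers_fixed"`, `"rodgers_logp_optimized"`,
#'   `"kp_optimized"`.
#' @param logp_override Optimized logP (required for
#'   `rodgers_logp_optimized`).
#' @param kp_scalar Effective global Kp (required for `kp_optimized`).
#' @param kp_cap Cap applied to every Kp; `Inf` disables. See
#'   [auto_kp_cap()].
#' @return A `partition_set`: list with `kp` (tibble `tissue`, `kp`),
#'   `method`, `capped` (tissue names replaced by the cap), `kp_cap_value`.
#' @examples
#' phys <- load_physiology()
#' cpd <- compound_profile("drug", logp = 2, ionization = ionization_base(9.4),
#'                         fup = 0.3, bp_ratio = 1.2, cl_hepatic = 30)
#' build_partition_set(cpd, phys, method = "rodgers_fixed")
#' @export
build_partition_set <- function(compound, physiology,
                                method = c("rodgers_fixed",
                                           "rodgers_logp_optimized",
                                           "kp_optimized"),
                                logp_override = NULL, kp_scalar = NULL,
                                kp_cap = Inf) {
  method <- match.arg(method)
  if (method == "kp_optimized") {
    assert_number(kp_scalar, "kp_scalar", lower = 0, closed_lower = FALSE)
    kp <- tibble::tibble(tissue = TISSUE_COMPARTMENTS,
                         kp = rep(kp_scalar, length(TISSUE_COMPARTMENTS)))
  } else {
    if (method == "rodgers_logp_optimized") {
      assert_number(logp_override, "logp_override")
      compound$logp <- logp_override
    }
    ka_ap <- if (compound$ionization$cls == "monoprotic_base_strong") {
      kaap_from_blood(compound, physiology$blood_cells,
                      physiology$hematocrit, physiology$plasma_ph)
    } else NULL
    kpu <- vapply(TISSUE_COMPARTMENTS, function(tn)
      kpu_for_tissue(compound, physiology, tn, ka_ap = ka_ap), numeric(1))
    kp <- tibble::tibble(tissue = TISSUE_COMPARTMENTS,
                         kp = unname(kpu) * compound$fup)
  }
  set <- structure(list(kp = kp, method = method, capped = character(0),
                        kp_cap_value = kp_cap), class = "partition_set")
  apply_kp_cap(set, kp_cap)
}

#' Cap implausibly large partition coefficients
#'
#' Mechanistic Kp predictions can blow up for very lipophilic compounds;
#' values above the cap are replaced by the cap (truncation) and the
#' affected tissues recorded.
#'
#' @param partition_set A `partition_set` from [build_partition_set()].
#' @param cap Positive cap; `Inf` disables capping.
#' @return The partition set with `kp` truncated at `cap` and `capped`
#'   listing the replaced tissues.
#' @export
apply_kp_cap <- function(partition_set, cap) {
  stopifnot(inherits(partition_set, "partition_set"))
  if (!is.numeric(cap) || length(cap) != 1L || is.na(cap) || cap <= 0) {
    abort_pbpk("`cap` must be a positive number (Inf disables)",
               class = "pbpkfit_domain_error")
  }
  over <- partition_set$kp$kp > cap
  partition_set$capped <- union(partition_set$capped,
                                partition_set$kp$tissue[over])
  partition_set$kp$kp[over] <- cap
  partition_set$kp_cap_value <- cap
  partition_set
}

#' Automatic Kp cap from an observed distribution volume
#'
#' When an observed non-compartmental Vdss is available the cap is
#' `max(50, 5 * Vdss_obs / V_body)`, keeping the model's total distribution
#' volume within about five times the observed one; without an observed
#' Vdss the cap defaults to 50.
#'
#' @param observed_vdss Observed Vdss (L), or `NULL`/`NA`.
#' @param physiology A [load_physiology()] object (supplies the total
#'   modeled volume).
#' @return A positive cap value.
#' @export
auto_kp_cap <- function(observed_vdss, physiology) {
  v_body <- sum(physiology$tissues$volume_L)
  if (is.null(observed_vdss) || is.na(observed_vdss)) return(50)
  max(50, 5 * observed_vdss / v_body)
}

#' @export
print.partition_set <- function(x, ...) {
  cat(sprintf("<partition_set> method = %s, cap = %s\n", x$method,
              if (is.finite(x$kp_cap_value)) format(x$kp_cap_value) else "none"))
  if (length(x$capped) > 0) {
    cat("  capped:", paste(x$capped, collapse = ", "), "\n")
  }
  print(x$kp, n = Inf)
  invisible(x)
}

# named Kp vector lookup
kp_vector <- function(partition_set) {
  stats::setNames(partition_set$kp$kp, partition_set$kp$tissue)
}
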