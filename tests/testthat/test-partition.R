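# Frozen oracle values below were hand-evaluated from the closed-form
# equations (spreadsheet-style literal arithmetic, independent of the
# implementation's dispatch and helpers).

test_that("class-1 base equation reproduces worked values and limits", {
  phys <- test_phys()
  strong_base <- compound_profile("base", logp = 2,
                                  ionization = ionization_base(9.4),
                                  fup = 0.3, bp_ratio = 1.2, cl_hepatic = 10)

  # equal intra/extracellular pH cancels the ionization ratio:
  # Kpu = f_ew + f_iw with no lipid/phospholipid terms
  tis <- bare_tissue(f_ew = 0.2, f_iw = 0.5, ph_iw = 7.4)
  cpd_eq <- compound_profile("b0", logp = 0,
                             ionization = ionization_base(9.4), fup = 1,
                             bp_ratio = 1.2, cl_hepatic = 0)
  expect_equal(kpu_class1_base(cpd_eq, tis, ka_ap = 0, plasma_ph = 7.4),
               0.7)

  # neutral limit (pKa -> -inf): ionization ratios -> 1, phospholipid
  # binding term -> 0, lipid terms undamped
  neutral_limit <- pbpkfit:::new_ionization("monoprotic_base_strong",
                                            pka_base = -40)
  cpd_n <- strong_base
  cpd_n$ionization <- neutral_limit
  tis2 <- bare_tissue(f_ew = 0.2, f_iw = 0.5, f_nl = 0.05, f_np = 0.01,
                      ap_mg_per_g = 2)
  p <- 10^cpd_n$logp
  expect_equal(kpu_class1_base(cpd_n, tis2, ka_ap = 3, plasma_ph = 7.4),
               0.2 + 0.5 + p * 0.05 + (0.3 * p + 0.7) * 0.01,
               tolerance = 1e-12)

  # worked muscle value with KaAP back-calculated from blood (frozen oracle)
  ka_ap <- kaap_from_blood(strong_base, phys$blood_cells, phys$hematocrit,
                           phys$plasma_ph)
  expect_equal(ka_ap, 5.20846478360674, tolerance = 1e-12)
  muscle <- pbpkfit:::tissue_composition(phys, "muscle")
  expect_equal(kpu_class1_base(strong_base, muscle, ka_ap, phys$plasma_ph),
               21.5220584562624, tolerance = 1e-12)

  # wrong class dispatch and domain errors
  expect_error(kpu_class1_base(neutral_compound(), muscle, 1, 7.4),
               class = "pbpkfit_class_error")
  expect_error(kpu_class1_base(strong_base, muscle, -1, 7.4),
               class = "pbpkfit_domain_error")
})

test_that("blood-derived phospholipid affinity handles edge cases", {
  phys <- test_phys()
  # B:P exactly at the plasma fraction: no red-cell partitioning
  at_floor <- compound_profile("f", logp = 1, ionization = ionization_base(9),
                               fup = 0.5, bp_ratio = 1 - phys$hematocrit,
                               cl_hepatic = 0)
  expect_error(kaap_from_blood(at_floor, phys$blood_cells, phys$hematocrit,
                               phys$plasma_ph),
               "no cell partitioning", class = "pbpkfit_domain_error")

  # B:P = 1, Hct = 0.45, fup = 1 gives Kpu_BC = (1 - 0.55)/0.45 = 1
  unit <- compound_profile("u", logp = 1, ionization = ionization_base(9),
                           fup = 1, bp_ratio = 1, cl_hepatic = 0)
  kpu_bc <- (unit$bp_ratio - (1 - 0.45)) / (0.45 * unit$fup)
  expect_equal(kpu_bc, 1)

  # Kpu_BC below the water/lipid terms: affinity clamps to zero
  weakly <- compound_profile("w", logp = 3, ionization = ionization_base(9),
                             fup = 1, bp_ratio = 0.56, cl_hepatic = 0)
  expect_equal(kaap_from_blood(weakly, phys$blood_cells, 0.45, 7.4), 0)
})

test_that("class-2 equation reproduces worked values and pH symmetries", {
  phys <- test_phys()
  # neutral, fup = 1, no plasma lipids: Kpu is the sum of water and lipid
  # partition contributions (frozen hand value 0.76 at logP = 0)
  tis <- bare_tissue(f_ew = 0.2, f_iw = 0.5, f_nl = 0.05, f_np = 0.01)
  expect_equal(kpu_class2(neutral_compound(), tis, plasma_ph = 7.4, fup = 1),
               0.76, tolerance = 1e-12)

  # acid with pKa = both pH values: X = Y = 1, lipid term halved
  acid_eq <- compound_profile("ae", logp = 0, ionization = ionization_acid(7.4),
                              fup = 1, bp_ratio = 0.6, cl_hepatic = 0)
  tis_eq <- bare_tissue(f_ew = 0, f_iw = 0, f_nl = 0.1, f_np = 0,
                        ph_iw = 7.4)
  expect_equal(kpu_class2(acid_eq, tis_eq, plasma_ph = 7.4, fup = 1),
               0.1 / 2, tolerance = 1e-12)

  # worked gut value for an acid with protein binding back-calculated
  # from fup (frozen oracle)
  acid <- compound_profile("a", logp = 2, ionization = ionization_acid(4),
                           fup = 0.1, bp_ratio = 0.6, cl_hepatic = 10)
  gut <- pbpkfit:::tissue_composition(phys, "gut")
  expect_equal(kpu_class2(acid, gut, phys$plasma_ph, 0.1,
                          phys$plasma_composition),
               1.89486262642275, tolerance = 1e-12)

  expect_error(kpu_class2(acid, gut, 7.4, fup = 0),
               class = "pbpkfit_domain_error")
  strong <- compound_profile("s", logp = 1, ionization = ionization_base(9),
                             fup = 1, bp_ratio = 1.2, cl_hepatic = 0)
  expect_error(kpu_class2(strong, gut, 7.4, fup = 1),
               class = "pbpkfit_class_error")
})

test_that("class-1 and class-2 agree in the forced-neutral limit", {
  # with all ionization pushed to the neutral limit and the binding terms
  # silenced the two closed forms must coincide
  tis <- bare_tissue(f_ew = 0.25, f_iw = 0.45, f_nl = 0.04, f_np = 0.02)
  for (logp in c(-1, 0, 1.7, 3)) {
    base_lim <- compound_profile("b", logp = logp,
                                 ionization = pbpkfit:::new_ionization(
                                   "monoprotic_base_strong", pka_base = -40),
                                 fup = 1, bp_ratio = 1, cl_hepatic = 0)
    neut <- neutral_compound(logp = logp)
    k1 <- kpu_class1_base(base_lim, tis, ka_ap = 0, plasma_ph = 7.4)
    k2 <- kpu_class2(neut, tis, plasma_ph = 7.4, fup = 1)
    expect_equal(k1, k2, tolerance = 1e-9)
  }
})

test_that("partition sets honor method semantics, Kp = Kpu * fup, and caps", {
  phys <- test_phys()
  # direct-Kp configuration: one scalar for every tissue compartment
  ps <- build_partition_set(neutral_compound(), phys,
                            method = "kp_optimized", kp_scalar = 3.2)
  expect_equal(nrow(ps$kp), 12)
  expect_true(all(ps$kp$kp == 3.2))
  expect_length(ps$capped, 0)

  # Kp = Kpu * fup on a mechanistic build
  fup <- 0.5
  cpd <- neutral_compound(logp = 1, fup = fup)
  ps_m <- build_partition_set(cpd, phys, method = "rodgers_fixed")
  gut_kpu <- kpu_class2(cpd, pbpkfit:::tissue_composition(phys, "gut"),
                        phys$plasma_ph, fup, phys$plasma_composition)
  expect_equal(ps_m$kp$kp[ps_m$kp$tissue == "gut"], gut_kpu * fup,
               tolerance = 1e-12)
  expect_true(all(ps_m$kp$kp > 0))

  # logP override: adipose partitioning increases with lipophilicity
  lo <- build_partition_set(cpd, phys, method = "rodgers_logp_optimized",
                            logp_override = 0)
  hi <- build_partition_set(cpd, phys, method = "rodgers_logp_optimized",
                            logp_override = 5)
  expect_gt(hi$kp$kp[hi$kp$tissue == "adipose"],
            lo$kp$kp[lo$kp$tissue == "adipose"])

  # cap rule: truncation with provenance; disabled cap is the identity
  capped <- apply_kp_cap(ps_m, 2)
  expect_true(all(capped$kp$kp <= 2))
  expect_setequal(capped$capped,
                  ps_m$kp$tissue[ps_m$kp$kp > 2])
  uncapped <- apply_kp_cap(ps_m, Inf)
  expect_equal(uncapped$kp, ps_m$kp)
  expect_length(uncapped$capped, 0)

  # automatic cap
  expect_equal(auto_kp_cap(NULL, phys), 50)
  expect_equal(auto_kp_cap(NA, phys), 50)
  v_body <- sum(phys$tissues$volume_L)
  expect_equal(auto_kp_cap(20 * v_body, phys), 100)
  expect_equal(auto_kp_cap(1, phys), 50)
})

test_that("Kp is monotone non-decreasing in logP for lipid-bearing tissues", {
  phys <- test_phys()
  logps <- seq(-2, 7, by = 0.5)
  # class-2 compounds: the full build (protein term included) is monotone
  for (cls in list(ionization_neutral(), ionization_acid(4.5))) {
    kp_by_tissue <- sapply(logps, function(lp) {
      cpd <- compound_profile("m", logp = lp, ionization = cls, fup = 0.5,
                              bp_ratio = 1.2, cl_hepatic = 0)
      ps <- build_partition_set(cpd, phys, method = "rodgers_fixed")
      stats::setNames(ps$kp$kp, ps$kp$tissue)
    })
    expect_true(all(apply(kp_by_tissue, 1, function(x) all(diff(x) >= -1e-12))),
                info = cls$cls)
  }
  # class-1 equation at a fixed phospholipid affinity (re-deriving KaAP
  # from B:P at each logP deflates the affinity as lipids explain more of
  # the red-cell partitioning, which legitimately breaks monotonicity)
  tissues <- setdiff(phys$tissues$tissue, c("venous_blood", "arterial_blood"))
  for (tn in tissues) {
    comp <- pbpkfit:::tissue_composition(phys, tn)
    kpu <- sapply(logps, function(lp) {
      cpd <- compound_profile("b", logp = lp,
                              ionization = ionization_base(9.5), fup = 0.5,
                              bp_ratio = 1.2, cl_hepatic = 0)
      kpu_class1_base(cpd, comp, ka_ap = 4, plasma_ph = phys$plasma_ph,
                      adipose = tn == "adipose")
    })
    expect_true(all(diff(kpu) >= -1e-12), info = tn)
  }
})
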