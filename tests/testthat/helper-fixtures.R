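# shared fixtures: bundled physiology is loaded once per test run
test_phys <- local({
  phys <- NULL
  function() {
    if (is.null(phys)) phys <<- load_physiology()
    phys
  }
})

# neutral compound with unit binding ratios: the simplest simulatable drug
neutral_compound <- function(name = "neutral", logp = 0, fup = 1,
                             bp_ratio = 1, cl_hepatic = 0, cl_renal = 0,
                             ka = NA_real_, f_oral = 1) {
  compound_profile(name, logp = logp, ionization = ionization_neutral(),
                   fup = fup, bp_ratio = bp_ratio, cl_hepatic = cl_hepatic,
                   cl_renal = cl_renal, ka = ka, f_oral = f_oral)
}

# a hand-specified tissue composition used in worked examples
bare_tissue <- function(f_ew = 0.2, f_iw = 0.5, f_nl = 0, f_np = 0,
                        ap_mg_per_g = 0, ph_iw = 7.0, protein_ratio = 0) {
  list(f_ew = f_ew, f_iw = f_iw, f_nl = f_nl, f_np = f_np,
       ap_mg_per_g = ap_mg_per_g, ph_iw = ph_iw,
       protein_ratio = protein_ratio)
}

# physiology variant with every tissue flow scaled (degenerate well-mixed
# limit when the factor is large)
scale_flows <- function(phys, factor) {
  phys$tissues$flow_L_per_h <- phys$tissues$flow_L_per_h * factor
  phys$cardiac_output <- phys$cardiac_output * factor
  phys
}

# uniform-Kp partition set without touching the Rodgers machinery
flat_partition <- function(kp = 1) {
  build_partition_set(neutral_compound(), test_phys(),
                      method = "kp_optimized", kp_scalar = kp)
}

# write a modified copy of the bundled physiology CSV and return its path
write_modified_physiology <- function(mutate_fn) {
  src <- system.file("extdata", "human_adult_physiology.csv",
                     package = "pbpkfit")
  tab <- readr::read_csv(src, show_col_types = FALSE)
  tab <- mutate_fn(tab)
  dst <- withr::local_tempfile(fileext = ".csv",
                               .local_envir = parent.frame())
  readr::write_csv(tab, dst)
  dst
}
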