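#' Sample a synthetic compound library
#'
#' Draws structurally plausible small-molecule parameter sets spanning the
#' ionization classes, each carrying a hidden *truth* record used only by
#' the data generator (never by fitting code). Measured logP is the true
#' value plus a measurement/translation error (sd 0.75 log units, clipped
#' to \[-2, 7\]), emulating the imperfect octanol-to-in-vivo translation
#' that motivates optimizing distribution parameters in the first place.
#'
#' Sampling ranges: true logP ~ U\[-1, 5\]; pKa by class (acid U\[3, 6\],
#' strong base U\[7.5, 10.5\], weak base U\[4, 7\], zwitterion one of
#' each); fup ~ U\[0.01, 1\]; hepatic clearance U\[5, 60\] L/h and renal
#' U\[0, 10\] L/h (total well below cardiac output); true B:P ~ U\[0.8, 2\]
#' (above the `1 - hematocrit` floor); true ka ~ LogU\[0.1, 3\] 1/h; oral
#' fraction reaching portal blood U\[0.5, 1\]; true effective global Kp ~
#' LogU\[0.5, 20\]. Every sampled compound passes [validate_compound()].
#'
#' @param n Number of compounds (>= 1).
#' @param class_mix Named proportions over the five ionization classes
#'   (must sum to 1).
#' @param seed Integer seed.
#' @param physiology Physiology used for validation (default bundled human
#'   adult).
#' @return A list with `compounds` (list of [compound_profile()], measured
#'   parameters only) and `truth` (tibble of hidden true parameters, one
#'   row per compound).
#' @export
sample_compound_library <- function(n,
                                    class_mix = c(monoprotic_acid = 0.25,
                                                  monoprotic_base_strong = 0.25,
                                                  monoprotic_base_weak = 0.20,
                                                  neutral = 0.15,
                                                  zwitterion = 0.15),
                                    seed = 1L,
                                    physiology = load_physiology()) {
  if (n < 1) abort_pbpk("`n` must be >= 1", class = "pbpkfit_domain_error")
  classes <- c("monoprotic_acid", "monoprotic_base_strong",
               "monoprotic_base_weak", "neutral", "zwitterion")
  mix <- stats::setNames(rep(0, length(classes)), classes)
  mix[names(class_mix)] <- class_mix
  if (any(mix < 0) || abs(sum(mix) - 1) > 1e-8) {
    abort_pbpk("`class_mix` proportions must be non-negative and sum to 1",
               class = "pbpkfit_domain_error")
  }
  # deterministic class counts proportional to the mix
  counts <- diff(c(0, round(cumsum(mix) * n)))
  cls <- rep(classes, counts)

  set.seed(as.integer(seed))
  compounds <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    name <- sprintf("SYN%03d", i)
    true_logp <- stats::runif(1, -1, 5)
    ion <- switch(cls[i],
      monoprotic_acid = ionization_acid(stats::runif(1, 3, 6)),
      monoprotic_base_strong = ionization_base(stats::runif(1, 7.5, 10.5)),
      monoprotic_base_weak = ionization_base(stats::runif(1, 4, 7)),
      neutral = ionization_neutral(),
      zwitterion = ionization_zwitterion(stats::runif(1, 3, 6),
                                         stats::runif(1, 4, 7)))
    fup <- stats::runif(1, 0.01, 1)
    cl_h <- stats::runif(1, 5, 60)
    cl_r <- stats::runif(1, 0, 10)
    true_bp <- stats::runif(1, 0.8, 2)
    true_ka <- 10^stats::runif(1, log10(0.1), log10(3))
    f_oral <- stats::runif(1, 0.5, 1)
    true_kp <- 10^stats::runif(1, log10(0.5), log10(20))
    measured_logp <- min(max(true_logp + stats::rnorm(1, 0, 0.75), -2), 7)

    cpd <- compound_profile(name, logp = measured_logp, ionization = ion,
                            fup = fup, bp_ratio = true_bp,
                            cl_hepatic = cl_h, cl_renal = cl_r,
                            ka = true_ka, f_oral = f_oral)
    rep_ok <- validate_compound(cpd, physiology)
    if (nrow(rep_ok) > 0) {
      abort_pbpk(paste0("sampled compound failed validation: ",
                        paste(rep_ok$rule, collapse = ", ")),
                 class = "pbpkfit_domain_error")
    }
    compounds[[i]] <- cpd
    truth[[i]] <- tibble::tibble(
      name = name, class = cls[i], true_logp = true_logp,
      measured_logp = measured_logp, true_kp = true_kp, true_ka = true_ka,
      true_bp = true_bp, f_oral = f_oral, fup = fup,
      cl_hepatic = cl_h, cl_renal = cl_r)
  }
  list(compounds = compounds, truth = dplyr::bind_rows(truth))
}

#' Default sampling designs
#'
#' Rich sampling schedules: 12 log-spaced points over 0.083-48 h after IV
#' dosing and over 0.25-48 h after oral dosing.
#'
#' @param route `"iv_bolus"` or `"oral"`.
#' @param n_points Number of samples.
#' @param t_end Last sample time, hours.
#' @return Numeric vector of sampling times (hours).
#' @export
default_design_times <- function(route = c("iv_bolus", "oral"),
                                 n_points = 12, t_end = 48) {
  route <- match.arg(route)
  t0 <- if (route == "iv_bolus") 0.083 else 0.25
  logspace(t0, t_end, n_points)
}

#' Generate one noisy concentration-time dataset
#'
#' Forward-simulates the truth compound (true logP/Kp/ka/B:P from the
#' library's hidden record) and perturbs each concentration with
#' multiplicative log-normal error: `C_obs = C * exp(eps)`,
#' `eps ~ N(0, sigma^2)` with `sigma = sqrt(log(1 + cv^2))`, so `cv = 0`
#' reproduces the noiseless curve exactly.
#'
#' @param compound The [compound_profile()] (measured parameters; only
#'   fixed fields are used).
#' @param truth_row One row of the library `truth` tibble.
#' @param physiology A [load_physiology()] object.
#' @param route,dose_ug,times Dose arm design.
#' @param cv Coefficient of variation of the multiplicative residual error.
#' @param seed Integer seed (`NULL` leaves the RNG stream alone).
#' @param mechanism `"kp"`: truth partitioning is the single effective
#'   global Kp; `"rodgers"`: mechanistic partitioning from true logP.
#' @return A tibble `time_h`, `conc_ug_per_L`.
#' @export
generate_dataset <- function(compound, truth_row, physiology,
                             route = "iv_bolus",
                             dose_ug = 1e4,
                             times = default_design_times(route),
                             cv = 0.15, seed = NULL,
                             mechanism = c("kp", "rodgers")) {
  mechanism <- match.arg(mechanism)
  true_cpd <- compound
  true_cpd$logp <- truth_row$true_logp
  true_cpd$bp_ratio <- truth_row$true_bp
  true_cpd$ka <- truth_row$true_ka
  true_cpd$f_oral <- truth_row$f_oral
  ps <- if (mechanism == "kp") {
    build_partition_set(true_cpd, physiology, method = "kp_optimized",
                        kp_scalar = truth_row$true_kp)
  } else {
    build_partition_set(true_cpd, physiology, method = "rodgers_fixed")
  }
  dose <- switch(route,
                 iv_bolus = dose_iv_bolus(dose_ug),
                 oral = dose_oral(dose_ug),
                 abort_pbpk(paste0("unsupported design route: ", route),
                            class = "pbpkfit_config_error"))
  sim <- simulate_pbpk(true_cpd, physiology, ps, dose,
                       t_end = max(times), output_times = times)
  conc <- sim$plasma$conc_ug_per_L
  if (cv > 0) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    sigma <- sqrt(log(1 + cv^2))
    conc <- conc * exp(stats::rnorm(length(conc), 0, sigma))
  }
  tibble::tibble(time_h = times, conc_ug_per_L = conc)
}

#' Generate a full synthetic study
#'
#' A compound library plus IV and oral dose arms per compound with
#' multiplicative log-normal residual error, structured like a literature
#' PK corpus (e.g. 21 compounds x 3 arms = 63 datasets). Arms cycle
#' through IV bolus (10 mg), oral (20 mg) and oral (40 mg). Fully
#' reproducible from the seed.
#'
#' @param n_compounds,datasets_per_compound Study size (>= 1 each).
#' @param cv Residual-error coefficient of variation (default 0.15).
#' @param seed Integer seed.
#' @param mechanism Truth partitioning mechanism, see [generate_dataset()].
#' @param class_mix Passed to [sample_compound_library()].
#' @param physiology A [load_physiology()] object.
#' @return A `study_bundle`: list with `compounds`, `truth`, `datasets`
#'   (nested tibble: `dataset_id`, `compound`, `route`, `dose_ug`,
#'   `data`), `noise`, `mechanism`, `seed`.
#' @examples
#' study <- generate_study(n_compounds = 2, datasets_per_compound = 2,
#'                         cv = 0, seed = 1)
#' study$datasets
#' @export
generate_study <- function(n_compounds = 21, datasets_per_compound = 3,
                           cv = 0.15, seed = 1L,
                           mechanism = c("kp", "rodgers"),
                           class_mix = NULL,
                           physiology = load_physiology()) {
  mechanism <- match.arg(mechanism)
  if (n_compounds < 1 || datasets_per_compound < 1) {
    abort_pbpk("study counts must be >= 1", class = "pbpkfit_domain_error")
  }
  lib <- if (is.null(class_mix)) {
    sample_compound_library(n_compounds, seed = seed, physiology = physiology)
  } else {
    sample_compound_library(n_compounds, class_mix = class_mix, seed = seed,
                            physiology = physiology)
  }
  arm_plan <- function(j) {
    # cycle IV 10 mg, oral 20 mg, oral 40 mg
    switch(((j - 1) %% 3) + 1,
           list(route = "iv_bolus", dose_ug = 1e4),
           list(route = "oral", dose_ug = 2e4),
           list(route = "oral", dose_ug = 4e4))
  }
  rows <- list()
  counter <- 0L
  for (i in seq_len(n_compounds)) {
    cpd <- lib$compounds[[i]]
    tr <- lib$truth[i, ]
    for (j in seq_len(datasets_per_compound)) {
      counter <- counter + 1L
      plan <- arm_plan(j)
      d <- generate_dataset(cpd, tr, physiology, route = plan$route,
                            dose_ug = plan$dose_ug,
                            times = default_design_times(plan$route),
                            cv = cv, seed = as.integer(seed) * 1000L + counter,
                            mechanism = mechanism)
      rows[[counter]] <- tibble::tibble(
        dataset_id = sprintf("%s_arm%d", cpd$name, j),
        compound = cpd$name, route = plan$route, dose_ug = plan$dose_ug,
        data = list(d))
    }
  }
  structure(list(compounds = lib$compounds, truth = lib$truth,
                 datasets = dplyr::bind_rows(rows),
                 noise = list(model = "multiplicative_lognormal", cv = cv),
                 mechanism = mechanism, seed = as.integer(seed)),
            class = "study_bundle")
}

#' @export
print.study_bundle <- function(x, ...) {
  cat(sprintf("<study_bundle> %d compounds, %d datasets, noise cv = %g, truth mechanism = %s, seed = %d\n",
              length(x$compounds), nrow(x$datasets), x$noise$cv,
              x$mechanism, x$seed))
  invisible(x)
}
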