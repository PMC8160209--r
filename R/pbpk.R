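#' Dose events
#'
#' Constructors for the dose-event table consumed by [simulate_pbpk()].
#' Amounts are in micrograms, times in hours. IV boluses are applied as an
#' instantaneous addition to venous blood, infusions as a constant-rate
#' venous input over `duration_h`, and oral doses as a deposit into a gut
#' lumen depot that empties with first-order rate `ka`, of which fraction
#' `f_oral` reaches gut tissue (and from there the portal vein).
#'
#' @param amount_ug Dose amount, micrograms (> 0).
#' @param time_h Dose start time, hours (>= 0).
#' @param duration_h Infusion duration, hours (> 0).
#' @return A one-row tibble with columns `route`, `amount_ug`,
#'   `start_time_h`, `duration_h`; rows from repeated calls can be bound
#'   together.
#' @examples
#' dplyr::bind_rows(dose_iv_bolus(1000), dose_oral(2000, time_h = 12))
#' @export
dose_iv_bolus <- function(amount_ug, time_h = 0) {
  assert_number(amount_ug, "amount_ug", lower = 0, closed_lower = FALSE)
  assert_number(time_h, "time_h", lower = 0)
  tibble::tibble(route = "iv_bolus", amount_ug = amount_ug,
                 start_time_h = time_h, duration_h = 0)
}

#' @rdname dose_iv_bolus
#' @export
dose_iv_infusion <- function(amount_ug, duration_h, time_h = 0) {
  assert_number(amount_ug, "amount_ug", lower = 0, closed_lower = FALSE)
  assert_number(duration_h, "duration_h", lower = 0, closed_lower = FALSE)
  assert_number(time_h, "time_h", lower = 0)
  tibble::tibble(route = "iv_infusion", amount_ug = amount_ug,
                 start_time_h = time_h, duration_h = duration_h)
}

#' @rdname dose_iv_bolus
#' @export
dose_oral <- function(amount_ug, time_h = 0) {
  assert_number(amount_ug, "amount_ug", lower = 0, closed_lower = FALSE)
  assert_number(time_h, "time_h", lower = 0)
  tibble::tibble(route = "oral", amount_ug = amount_ug,
                 start_time_h = time_h, duration_h = 0)
}

# state ordering for the ODE system; the three trailing states are the oral
# depot and the two bookkeeping sinks that make mass conservation exact
pbpk_states <- function() c(ALL_COMPARTMENTS, "gut_lumen", "eliminated",
                            "unabsorbed")

# Rate matrix M of the linear system dA/dt = M A (+ u for infusions).
# A is the amount vector (ug); concentrations leaving a tissue are on the
# blood scale, C_out = A * B:P / (V * Kp). Elimination acts on outflow
# blood concentration (hepatic and renal clearance), keeping Dose/AUC_blood
# equal to total clearance in the low-extraction limit. Column sums are
# zero by construction, so total mass is conserved to machine precision.
pbpk_rate_matrix <- function(compound, physiology, partition_set) {
  states <- pbpk_states()
  n <- length(states)
  M <- matrix(0, n, n, dimnames = list(states, states))
  kp <- kp_vector(partition_set)
  missing_kp <- setdiff(TISSUE_COMPARTMENTS, names(kp))
  if (length(missing_kp) > 0) {
    abort_pbpk(paste0("partition set missing Kp for: ",
                      paste(missing_kp, collapse = ", ")),
               class = "pbpkfit_config_error")
  }
  bp <- compound$bp_ratio
  co <- physiology$cardiac_output
  v <- stats::setNames(physiology$tissues$volume_L, physiology$tissues$tissue)
  q <- stats::setNames(physiology$tissues$flow_L_per_h, physiology$tissues$tissue)
  # per-unit-amount outflow blood concentration for each tissue
  cout <- bp / (v[TISSUE_COMPARTMENTS] * kp[TISSUE_COMPARTMENTS])

  # venous -> lung -> arterial in series
  M["lung", "venous_blood"] <- co / v["venous_blood"]
  M["venous_blood", "venous_blood"] <- -co / v["venous_blood"]
  M["arterial_blood", "lung"] <- co * cout["lung"]
  M["lung", "lung"] <- -co * cout["lung"]
  M["arterial_blood", "arterial_blood"] <- -co / v["arterial_blood"]

  simple <- setdiff(TISSUE_COMPARTMENTS,
                    c("lung", "liver", "kidney", PORTAL_TISSUES))
  for (t in c(simple, PORTAL_TISSUES, "kidney")) {
    M[t, "arterial_blood"] <- q[t] / v["arterial_blood"]
  }
  for (t in simple) {
    M[t, t] <- -q[t] * cout[t]
    M["venous_blood", t] <- q[t] * cout[t]
  }
  # kidney: renal clearance removes drug from outflow blood
  M["kidney", "kidney"] <- -(q["kidney"] + compound$cl_renal) * cout["kidney"]
  M["venous_blood", "kidney"] <- q["kidney"] * cout["kidney"]
  M["eliminated", "kidney"] <- compound$cl_renal * cout["kidney"]
  # portal tissues drain into the liver
  for (t in PORTAL_TISSUES) {
    M[t, t] <- -q[t] * cout[t]
    M["liver", t] <- q[t] * cout[t]
  }
  # liver: hepatic artery plus portal inflow; hepatic clearance on outflow
  q_liver_total <- q["liver"] + sum(q[PORTAL_TISSUES])
  M["liver", "arterial_blood"] <- q["liver"] / v["arterial_blood"]
  M["liver", "liver"] <- -(q_liver_total + compound$cl_hepatic) * cout["liver"]
  M["venous_blood", "liver"] <- q_liver_total * cout["liver"]
  M["eliminated", "liver"] <- compound$cl_hepatic * cout["liver"]
  # oral depot
  if (!is.na(compound$ka)) {
    M["gut_lumen", "gut_lumen"] <- -compound$ka
    M["gut", "gut_lumen"] <- compound$f_oral * compound$ka
    M["unabsorbed", "gut_lumen"] <- (1 - compound$f_oral) * compound$ka
  }
  M
}

# propagate the inhomogeneous linear system A' = M A + u over dt
# (augmented-matrix trick when u is nonzero; plain expm otherwise)
propagate_linear <- function(M, A, u, dt) {
  if (dt == 0) return(A)
  n <- length(A)
  out <- if (all(u == 0)) {
    E <- as.matrix(Matrix::expm(Matrix::Matrix(M * dt)))
    drop(E %*% A)
  } else {
    Maug <- rbind(cbind(M, u), 0)
    E <- as.matrix(Matrix::expm(Matrix::Matrix(Maug * dt)))
    drop(E %*% c(A, 1))[seq_len(n)]
  }
  stats::setNames(out, names(A))
}

# Eigendecomposition of M for the homogeneous fast path:
# exp(M dt) A = V exp(lambda dt) V^-1 A. Returns NULL when M is defective
# (repeated eigenvalues without a full eigenbasis), in which case the
# caller falls back to the Pade matrix exponential.
eigen_propagator <- function(M) {
  eig <- tryCatch(eigen(M), error = function(e) NULL)
  if (is.null(eig)) return(NULL)
  vinv <- tryCatch(solve(eig$vectors), error = function(e) NULL)
  if (is.null(vinv)) return(NULL)
  recon <- eig$vectors %*% (eig$values * vinv)
  scale <- max(abs(M), 1)
  if (max(Mod(recon - M)) > 1e-9 * scale) return(NULL)
  list(v = eig$vectors, values = eig$values, vinv = vinv)
}

propagate_eigen <- function(ep, A, dt) {
  if (dt == 0) return(A)
  stats::setNames(Re(drop(ep$v %*% (exp(ep$values * dt) * (ep$vinv %*% A)))),
                  names(A))
}

# classic RK4 with fixed step for the same system (parity mode)
propagate_rk4 <- function(M, A, u, dt, step_h) {
  if (dt == 0) return(A)
  n_steps <- max(1L, ceiling(dt / step_h))
  h <- dt / n_steps
  f <- function(a) drop(M %*% a) + u
  for (i in seq_len(n_steps)) {
    k1 <- f(A); k2 <- f(A + h / 2 * k1)
    k3 <- f(A + h / 2 * k2); k4 <- f(A + h * k3)
    A <- A + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
  }
  A
}

#' Simulate the whole-body PBPK model
#'
#' Solves the 14-compartment perfusion-limited mass-balance system. Each
#' non-eliminating tissue obeys
#' `V_t dC_t/dt = Q_t (C_in - C_t * B:P / Kp_t)` with inflow on the blood
#' concentration scale; liver (hepatic clearance) and kidney (renal
#' clearance) carry an additional elimination term acting on outflow blood
#' concentration. The lung sits in series between venous and arterial
#' blood; gut and spleen drain portally into the liver so oral first-pass
#' loss emerges mechanistically. Oral doses pass through a first-order gut
#' lumen depot.
#'
#' The dosing mechanisms are all linear, so between dose events the system
#' is solved *exactly* by matrix exponentials (default). A fixed-step RK4
#' mode (`solver = "fixed_step"`, default step 1e-4 h) is available for
#' parity with fixed-step engines; it is much slower and numerically
#' inferior.
#'
#' @param compound A [compound_profile()].
#' @param physiology A [load_physiology()] object.
#' @param partition_set A [build_partition_set()] result covering all
#'   twelve tissue compartments.
#' @param doses Dose-event tibble from [dose_iv_bolus()] and friends.
#' @param t_end End of the simulation window, hours.
#' @param output_times Times (hours) at which amounts and plasma
#'   concentration are reported; defaults to 201 evenly spaced points over
#'   `[0, t_end]`. Must lie within `[0, t_end]`.
#' @param solver `"matrix_exp"` (exact, default) or `"fixed_step"` (RK4).
#' @param step_h Fixed step size in hours for `solver = "fixed_step"`.
#' @return A `pbpk_simulation`: list with `times`, `amounts` (matrix, time
#'   by state, micrograms; states include the gut lumen depot and the
#'   `eliminated`/`unabsorbed` bookkeeping sinks), `plasma` (tibble
#'   `time_h`, `conc_ug_per_L` of venous *plasma*), `dose_total`,
#'   `diagnostics` (list: `n_segments`, `mass_balance_residual`).
#' @examples
#' phys <- load_physiology()
#' cpd <- compound_profile("drug", logp = 2, ionization = ionization_neutral(),
#'                         fup = 0.3, bp_ratio = 1, cl_hepatic = 20)
#' ps <- build_partition_set(cpd, phys, method = "rodgers_fixed")
#' sim <- simulate_pbpk(cpd, phys, ps, dose_iv_bolus(10000), t_end = 24)
#' head(sim$plasma)
#' @export
simulate_pbpk <- function(compound, physiology, partition_set, doses, t_end,
                          output_times = NULL,
                          solver = c("matrix_exp", "fixed_step"),
                          step_h = 1e-4) {
  solver <- match.arg(solver)
  stopifnot(inherits(compound, "compound_profile"),
            inherits(physiology, "subject_physiology"),
            inherits(partition_set, "partition_set"))
  assert_number(t_end, "t_end", lower = 0, closed_lower = FALSE)
  if (!is.data.frame(doses) || nrow(doses) == 0) {
    abort_pbpk("`doses` must contain at least one dose event",
               class = "pbpkfit_config_error")
  }
  if (any(doses$route == "oral") && is.na(compound$ka)) {
    abort_pbpk("oral dosing requires a positive absorption rate `ka`",
               class = "pbpkfit_config_error")
  }
  if (is.null(output_times)) output_times <- seq(0, t_end, length.out = 201)
  output_times <- sort(unique(output_times))
  if (any(output_times < 0) || any(output_times > t_end + 1e-12)) {
    abort_pbpk("`output_times` must lie within [0, t_end]",
               class = "pbpkfit_config_error")
  }

  M <- pbpk_rate_matrix(compound, physiology, partition_set)
  states <- pbpk_states()
  n <- length(states)
  A <- stats::setNames(numeric(n), states)

  # breakpoints: dose starts, infusion ends, output times
  inf <- doses[doses$route == "iv_infusion", , drop = FALSE]
  brk <- sort(unique(c(0, t_end, output_times, doses$start_time_h,
                       if (nrow(inf)) inf$start_time_h + inf$duration_h)))
  brk <- brk[brk <= t_end + 1e-12]

  out <- matrix(NA_real_, length(output_times), n,
                dimnames = list(NULL, states))
  dosed <- numeric(length(output_times))  # cumulative administered dose
  cum_dose <- 0
  record <- function(tm) {
    idx <- which(abs(output_times - tm) < 1e-12)
    for (i in idx) {
      out[i, ] <<- A
      dosed[i] <<- cum_dose
    }
  }

  t_cur <- 0
  # instantaneous doses at t = 0 are applied before the first record
  apply_instant <- function(tm) {
    hit <- doses$start_time_h == tm & doses$route %in% c("iv_bolus", "oral")
    if (any(hit)) {
      for (i in which(hit)) {
        tgt <- if (doses$route[i] == "iv_bolus") "venous_blood" else "gut_lumen"
        A[tgt] <<- A[tgt] + doses$amount_ug[i]
        cum_dose <<- cum_dose + doses$amount_ug[i]
      }
    }
  }

  infusion_rate <- function(tm) {
    # total active infusion rate (ug/h) on [tm, next breakpoint)
    if (nrow(inf) == 0) return(0)
    active <- inf$start_time_h <= tm + 1e-12 &
      tm < inf$start_time_h + inf$duration_h - 1e-12
    sum(inf$amount_ug[active] / inf$duration_h[active])
  }

  ep <- if (solver == "matrix_exp") eigen_propagator(M) else NULL

  apply_instant(t_cur)
  record(t_cur)
  for (k in seq_along(brk)[-1]) {
    t_next <- brk[k]
    rate <- infusion_rate(t_cur)
    u <- stats::setNames(numeric(n), states)
    u["venous_blood"] <- rate
    A <- if (solver == "matrix_exp") {
      if (!is.null(ep) && rate == 0) propagate_eigen(ep, A, t_next - t_cur)
      else propagate_linear(M, A, u, t_next - t_cur)
    } else propagate_rk4(M, A, u, t_next - t_cur, step_h)
    cum_dose <- cum_dose + rate * (t_next - t_cur)
    t_cur <- t_next
    apply_instant(t_cur)
    record(t_cur)
  }

  total_dose <- sum(doses$amount_ug)
  resid <- if (total_dose > 0) {
    max(abs(rowSums(out) - dosed)) / total_dose
  } else 0
  # floating-point cancellation can leave amounts a hair below zero;
  # anything beyond the -1e-9 * dose floor is a genuine solver failure
  floor_amt <- -1e-9 * total_dose
  if (any(out < floor_amt)) {
    abort_pbpk(sprintf(
      "solver produced negative amounts (min %.3g ug, floor %.3g ug); mass-balance residual %.3g",
      min(out), floor_amt, resid), class = "pbpkfit_solver_error")
  }
  out[out < 0] <- 0
  v_ven <- tissue_volume(physiology, "venous_blood")
  plasma <- tibble::new_tibble(
    list(time_h = output_times,
         conc_ug_per_L = out[, "venous_blood"] / v_ven / compound$bp_ratio),
    nrow = length(output_times))

  structure(list(
    times = output_times, amounts = out, plasma = plasma,
    dose_total = total_dose, doses = doses,
    compound_name = compound$name, bp_ratio = compound$bp_ratio,
    diagnostics = list(n_segments = length(brk) - 1L,
                       mass_balance_residual = resid)),
    class = "pbpk_simulation")
}

#' @export
print.pbpk_simulation <- function(x, ...) {
  cat(sprintf("<pbpk_simulation> %s, dose %.4g ug, %d output times over [%g, %g] h\n",
              x$compound_name, x$dose_total, length(x$times),
              min(x$times), max(x$times)))
  cat(sprintf("  mass-balance residual %.2e (relative)\n",
              x$diagnostics$mass_balance_residual))
  invisible(x)
}

#' Venous plasma concentration series from a simulation
#'
#' The model state is drug amount in whole blood and tissue; observed data
#' are plasma concentrations. Venous plasma concentration is venous *blood*
#' concentration divided by the blood:plasma ratio.
#'
#' @param result A [simulate_pbpk()] result.
#' @param bp_ratio Blood:plasma ratio; defaults to the one used in the
#'   simulation.
#' @return A tibble with `time_h` and `conc_ug_per_L`.
#' @export
venous_plasma_series <- function(result, bp_ratio = NULL) {
  stopifnot(inherits(result, "pbpk_simulation"))
  bp_used <- bp_ratio %||% result$bp_ratio
  tibble::tibble(
    time_h = result$times,
    conc_ug_per_L = result$plasma$conc_ug_per_L * result$bp_ratio / bp_used)
}

#' Analytic steady-state distribution volume of the model
#'
#' Closed-form plasma-referenced Vdss of the perfusion-limited model: at
#' distribution equilibrium every tissue holds `V_t * Kp_t` per unit plasma
#' concentration and the blood compartments hold `V_blood * B:P`. Used as
#' an independent oracle for the non-compartmental Vdss.
#'
#' @param physiology A [load_physiology()] object.
#' @param partition_set A [build_partition_set()] result.
#' @param compound A [compound_profile()] (supplies `bp_ratio`).
#' @return Vdss in litres.
#' @export
analytic_vdss <- function(physiology, partition_set, compound) {
  kp <- kp_vector(partition_set)
  v <- stats::setNames(physiology$tissues$volume_L, physiology$tissues$tissue)
  v_blood <- sum(v[BLOOD_COMPARTMENTS])
  compound$bp_ratio * v_blood + sum(v[TISSUE_COMPARTMENTS] * kp[TISSUE_COMPARTMENTS])
}
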