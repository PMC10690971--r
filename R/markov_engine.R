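#' Run configuration for a cohort simulation
#'
#' @param horizon Time horizon in years (cycles); at least 1.
#' @param start_age Cohort age at therapy start (years); may be left
#'   `NULL` when the configuration is handed to [run_cea()], which then
#'   takes the population profile's starting age.
#' @param disc_cost,disc_qaly Annual discount rates for costs and QALYs
#'   (fractions; the base case uses 0.05 for both, sensitivity sweeps run
#'   0 to 0.08).
#' @param perspective `"healthcare"` (direct medical costs only) or
#'   `"private_payer"` (adds indirect costs).
#' @param regimen Evolocumab dosing regimen, `"Q2W_140"` or `"QM_420"`.
#' @param entry_state State holding the full cohort at cycle 0; the
#'   default `"Post-MI"` reflects AMI survivors starting therapy after
#'   the index event.
#' @param drug_hcc Accrue drug acquisition costs half-cycle corrected
#'   over the living states (default) rather than on start-of-cycle
#'   occupancy.
#' @param hospital_multiplier Scales hospitalization (acute-year and
#'   revascularization) direct costs, for hospital-tier scenarios.
#' @param evolocumab_annual_cost Optional override of the packaged annual
#'   evolocumab cost (CNY), for price sweeps.
#' @param statin_annual_cost Optional override of the annual statin cost
#'   (CNY).
#' @return Object of class `run_config`.
#' @export
run_config <- function(horizon = 25, start_age = NULL,
                       disc_cost = 0.05, disc_qaly = 0.05,
                       perspective = c("healthcare", "private_payer"),
                       regimen = c("Q2W_140", "QM_420"),
                       entry_state = "Post-MI", drug_hcc = TRUE,
                       hospital_multiplier = 1,
                       evolocumab_annual_cost = NULL,
                       statin_annual_cost = NULL) {
  if (horizon < 1) stop("horizon must be at least 1 year")
  if (disc_cost < 0 || disc_qaly < 0) stop("discount rates must be >= 0")
  structure(list(horizon = as.integer(horizon), start_age = start_age,
                 disc_cost = disc_cost, disc_qaly = disc_qaly,
                 perspective = match.arg(perspective),
                 regimen = match.arg(regimen), entry_state = entry_state,
                 drug_hcc = drug_hcc,
                 hospital_multiplier = hospital_multiplier,
                 evolocumab_annual_cost = evolocumab_annual_cost,
                 statin_annual_cost = statin_annual_cost),
            class = "run_config")
}

#' Half-cycle correction
#'
#' Transitions happen throughout a cycle, not at its boundary; rewards
#' are therefore accrued on the average of the start- and end-of-cycle
#' occupancy (trapezoidal correction).
#'
#' @param start_occupancy,end_occupancy Occupancy vectors of equal
#'   length.
#' @return Element-wise mean of the two vectors.
#' @export
half_cycle_correct <- function(start_occupancy, end_occupancy) {
  if (length(start_occupancy) != length(end_occupancy))
    stop("occupancy vectors differ in length")
  (start_occupancy + end_occupancy) / 2
}

#' Discount factor at a cycle
#'
#' Rewards of cycle `t` (0-based) are discounted by `1/(1+rate)^t`
#' (annual-start convention).
#'
#' @param rate Annual discount rate (fraction, non-negative).
#' @param cycle_index 0-based cycle.
#' @return Discount factor.
#' @export
discount_factor <- function(rate, cycle_index) {
  if (any(rate < 0)) stop("discount rate must be non-negative")
  1 / (1 + rate)^cycle_index
}

# Per-cycle transition matrices (and event probabilities) for one arm.
# spec = NULL is the comparator (statins alone); otherwise the treated
# arm's effect specification.
cohort_matrices <- function(space, rates, table, config, spec = NULL) {
  mult <- state_history_multiplier(space, rates)
  lapply(seq_len(config$horizon) - 1L, function(t) {
    age <- config$start_age + t
    cp <- cycle_probabilities(space, rates, table, age, config$start_age,
                              spec, t, mult)
    M <- tryCatch(
      build_transition_matrix(space, cp$p_mi, cp$p_stroke, cp$p_cv, cp$p_ncv),
      error = function(e) stop("cycle ", t, ": ", conditionMessage(e),
                               call. = FALSE))
    list(M = M, p_rv = cp$p_rv)
  })
}

#' Run the cohort through the model for one arm
#'
#' Simulates `horizon` one-year cycles: each cycle the transition matrix
#' is rebuilt at the cohort's current age (mortality is age-dependent),
#' the occupancy vector is advanced, and half-cycle-corrected state costs
#' and utilities, revascularization procedure costs, drug costs and (in
#' the evolocumab arm) injection-site-reaction disutilities are accrued
#' and discounted.
#'
#' @param space A [build_state_space()] state space.
#' @param rates Baseline [event_rates()] for the cohort.
#' @param table A [life_table()].
#' @param params A [parameter_set()] supplying costs and utilities.
#' @param config A [run_config()].
#' @param spec `NULL` for the comparator (statins alone) or an
#'   [effect_spec()] for the evolocumab + statins arm.
#' @return Object of class `cohort_trace`: list with `occupancy`
#'   (`(horizon+1) x nstates` matrix), `cycles` (per-cycle data frame of
#'   discounted and undiscounted accruals and expected event counts) and
#'   totals `discounted_cost`, `discounted_qalys`.
#' @export
run_cohort <- function(space, rates, table, params, config, spec = NULL) {
  n <- nrow(space)
  mats <- cohort_matrices(space, rates, table, config, spec)
  u <- state_utilities(space, params)
  cst <- state_costs(space, params, config$perspective,
                     config$hospital_multiplier)
  c_death <- cv_death_costs(space, params, config$perspective)
  c_rv <- rv_cost(params, config$perspective, config$hospital_multiplier)
  statin_cost <- if (!is.null(config$statin_annual_cost))
    config$statin_annual_cost else param_value(params, "drug_cost", "Statins")
  evo_cost <- if (!is.null(config$evolocumab_annual_cost))
    config$evolocumab_annual_cost
  else param_value(params, "drug_cost",
                   if (config$regimen == "Q2W_140") "Evolocumab (140 mg/2W)"
                   else "Evolocumab (420 mg/M)")
  treated <- !is.null(spec)
  p_ae <- if (treated) annual_ae_prob(spec$ae_prob_26mo) else 0
  ae_du <- if (treated) -spec$ae_disutility else 0

  i_cv <- state_index(space, "CV death")
  living <- !space$absorbing
  pi <- matrix(0, config$horizon + 1L, n, dimnames = list(NULL, space$name))
  pi[1, state_index(space, config$entry_state)] <- 1

  cyc <- data.frame(cycle = seq_len(config$horizon) - 1L)
  cyc$age <- config$start_age + cyc$cycle
  cyc$cost <- cyc$qaly <- cyc$cost_undisc <- cyc$qaly_undisc <- 0
  cyc$rv_events <- cyc$ae_events <- cyc$cv_deaths <- 0

  for (t in seq_len(config$horizon)) {
    M <- mats[[t]]$M
    p_rv <- mats[[t]]$p_rv
    start <- pi[t, ]
    end <- as.numeric(start %*% M)
    pi[t + 1L, ] <- end
    h <- half_cycle_correct(start, end)
    alive_h <- sum(h[living])
    rv_ev <- sum(h[living] * p_rv[living])
    cvd_into <- start[living] * M[living, i_cv]  # expected CV-death entries
    cvd_tr <- sum(cvd_into)
    ae_ev <- if (treated) alive_h * p_ae else 0
    drug_occ <- if (config$drug_hcc) alive_h else sum(start[living])
    cost_t <- sum(h * cst) + rv_ev * c_rv + sum(cvd_into * c_death[living]) +
      drug_occ * (statin_cost + if (treated) evo_cost else 0)
    qaly_t <- sum(h * u) - ae_ev * ae_du
    d_c <- discount_factor(config$disc_cost, t - 1L)
    d_q <- discount_factor(config$disc_qaly, t - 1L)
    cyc$cost_undisc[t] <- cost_t
    cyc$qaly_undisc[t] <- qaly_t
    cyc$cost[t] <- cost_t * d_c
    cyc$qaly[t] <- qaly_t * d_q
    cyc$rv_events[t] <- rv_ev
    cyc$ae_events[t] <- ae_ev
    cyc$cv_deaths[t] <- cvd_tr
  }
  structure(list(occupancy = pi, cycles = cyc,
                 discounted_cost = sum(cyc$cost),
                 discounted_qalys = sum(cyc$qaly),
                 undiscounted_cost = sum(cyc$cost_undisc),
                 undiscounted_qalys = sum(cyc$qaly_undisc),
                 config = config, treated = treated),
            class = "cohort_trace")
}

#' @export
print.cohort_trace <- function(x, ...) {
  cat("Cohort trace:", nrow(x$cycles), "cycles,",
      if (x$treated) "evolocumab + statins" else "statins alone", "\n")
  cat(sprintf("  discounted cost  : %.2f CNY\n", x$discounted_cost))
  cat(sprintf("  discounted QALYs : %.4f\n", x$discounted_qalys))
  invisible(x)
}

#' Export a cohort trace as CSV
#'
#' Writes one row per cycle: age, occupancy of every state, and the
#' discounted cost and QALY increments, at full precision.
#'
#' @param trace A [run_cohort()] trace.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trace_csv <- function(trace, path) {
  occ <- trace$occupancy[seq_len(nrow(trace$cycles)), , drop = FALSE]
  df <- cbind(trace$cycles[, c("cycle", "age")], occ,
              trace$cycles[, c("cost", "qaly")])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Individual-level microsimulation of the same transition structure
#'
#' Simulates `n_patients` independent patients through the identical
#' per-cycle transition matrices used by the cohort engine (state counts
#' propagate by multinomial sampling, which is the exact aggregate of
#' patient-level simulation).  Serves as an independent stochastic check
#' of the deterministic cohort trace.
#'
#' @inheritParams run_cohort
#' @param n_patients Number of simulated patients.
#' @param seed Integer seed; the simulation is reproducible given it.
#' @return Matrix of occupancy fractions, `(horizon+1) x nstates`.
#' @export
microsimulate_cohort <- function(space, rates, table, params, config,
                                 spec = NULL, n_patients = 1e5, seed = 1) {
  mats <- cohort_matrices(space, rates, table, config, spec)
  n <- nrow(space)
  counts <- matrix(0L, config$horizon + 1L, n,
                   dimnames = list(NULL, space$name))
  counts[1, state_index(space, config$entry_state)] <- n_patients
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  for (t in seq_len(config$horizon)) {
    M <- mats[[t]]$M
    nxt <- integer(n)
    for (i in seq_len(n)) {
      if (counts[t, i] == 0L) next
      nxt <- nxt + as.integer(stats::rmultinom(1, counts[t, i], M[i, ]))
    }
    counts[t + 1L, ] <- nxt
  }
  counts / n_patients
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}
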