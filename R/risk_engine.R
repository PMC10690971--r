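#' Convert an event rate to a per-cycle probability
#'
#' Constant-hazard conversion of a rate expressed per 100 patient-years
#' into a probability over `cycle_years`: `1 - exp(-(rate/100) * cycle_years)`.
#'
#' @param rate Event rate per 100 patient-years (non-negative).
#' @param cycle_years Cycle length in years (default 1).
#' @return Probability in `[0, 1)`.
#' @examples
#' rate_to_prob(1.7)      # annual probability for 1.7 per 100 pt-yr
#' rate_to_prob(6.4, 0.5) # half-year cycle
#' @export
rate_to_prob <- function(rate, cycle_years = 1) {
  if (any(rate < 0)) stop("rate must be non-negative")
  if (any(cycle_years <= 0)) stop("cycle_years must be positive")
  1 - exp(-(rate / 100) * cycle_years)
}

# inverse of rate_to_prob, used when scaling probabilities as rates
prob_to_rate <- function(p, cycle_years = 1) {
  if (any(p < 0 | p >= 1)) stop("probability must be in [0, 1)")
  -100 * log(1 - p) / cycle_years
}

#' Non-cardiovascular mortality as the all-cause / cardiovascular residual
#'
#' @param all_cause All-cause death probability (or rate).
#' @param cv Cardiovascular death probability (or rate), on the same scale.
#' @return `all_cause - cv` (non-negative).
#' @examples
#' split_mortality(0.031, 0.022)
#' @export
split_mortality <- function(all_cause, cv) {
  if (any(cv > all_cause))
    stop("cardiovascular mortality exceeds all-cause mortality: ",
         "inconsistent life table")
  pmax(all_cause - cv, 0)
}

#' Annualize the injection-site adverse-event probability
#'
#' Trial safety follow-up reports the cumulative probability of a mild
#' injection-site reaction over 26 months; the model needs an annual
#' probability.  Under a constant hazard the conversion is
#' `1 - (1 - p_26mo)^(12/26)`.
#'
#' @param p_26mo Cumulative probability over 26 months, in `[0, 1)`.
#' @return Annual probability.
#' @export
annual_ae_prob <- function(p_26mo) {
  if (any(p_26mo < 0 | p_26mo >= 1)) stop("p_26mo must be in [0, 1)")
  1 - (1 - p_26mo)^(12 / 26)
}

#' Baseline cardiovascular event rates
#'
#' Bundle of annual event rates per 100 patient-years for the modelled
#' cohort, with the hazard multipliers ("adjustment factors") applied to
#' states carrying a history of prior events.
#'
#' @param nonfatal_MI,nonfatal_stroke,CV_death,revascularization Rates per
#'   100 patient-years.
#' @param all_cause_death Optional all-cause mortality rate per 100
#'   patient-years; when supplied it must be at least `CV_death`.
#' @param history_multipliers Named numeric vector of multiplicative
#'   hazard adjustments applied to all cardiovascular rates of states with
#'   the matching history: `prior_MI` (any MI history beyond the index
#'   event), `prior_stroke` (any stroke history), `mi_2plus`
#'   (two-or-more MIs), `stroke_2plus`.  Multipliers for two distinct
#'   histories stack multiplicatively.
#' @return Object of class `event_rates`.
#' @export
event_rates <- function(nonfatal_MI, nonfatal_stroke, CV_death,
                        revascularization, all_cause_death = NULL,
                        history_multipliers = c(prior_MI = 1, prior_stroke = 1,
                                                mi_2plus = 1,
                                                stroke_2plus = 1)) {
  r <- c(nonfatal_MI = nonfatal_MI, nonfatal_stroke = nonfatal_stroke,
         CV_death = CV_death, revascularization = revascularization)
  if (any(r < 0)) stop("event rates must be non-negative")
  if (!is.null(all_cause_death)) {
    if (all_cause_death < CV_death)
      stop("all-cause mortality below cardiovascular mortality")
  }
  hm <- c(prior_MI = 1, prior_stroke = 1, mi_2plus = 1, stroke_2plus = 1)
  hm[names(history_multipliers)] <- history_multipliers
  if (any(hm < 0)) stop("history multipliers must be non-negative")
  structure(list(nonfatal_MI = nonfatal_MI, nonfatal_stroke = nonfatal_stroke,
                 CV_death = CV_death, revascularization = revascularization,
                 all_cause_death = all_cause_death,
                 history_multipliers = hm),
            class = "event_rates")
}

#' Treatment-effect specification
#'
#' One of two engines for translating trial evidence into per-cycle rate
#' multipliers for the intervention arm:
#'
#' * `mode = "endpoint_HR"`: event-specific hazard ratios from trial
#'   clinical endpoints, split into a first-year value (applied in model
#'   cycle 0, when therapy starts) and a beyond-first-year value.
#' * `mode = "ldl_RR"`: rate ratios per 1 mmol/l of LDL-C reduction from
#'   meta-analysis, applied as `RR ^ delta_LDL` where `delta_LDL` is the
#'   absolute LDL-C reduction achieved by the intervention (mmol/l).
#'
#' @param mode `"endpoint_HR"` or `"ldl_RR"`.
#' @param mi_y1,mi_later,stroke_y1,stroke_later,rv_y1,rv_later Per-event
#'   effects (HRs, or RRs per mmol/l), year-1 and beyond-year-1.
#' @param cv_death_effect HR (endpoint mode; a combined MI/stroke
#'   mortality HR is not always published, so the default is the null
#'   value 1 and should be set explicitly when available) or RR per mmol/l
#'   (LDL mode; meta-analysis value 0.86 applies in both periods).
#' @param delta_LDL Absolute LDL-C reduction in mmol/l (`ldl_RR` mode).
#' @param ae_prob_26mo Probability of a mild injection-site reaction
#'   within 26 months of therapy.
#' @param ae_disutility One-off utility decrement per injection-site
#'   reaction (non-positive).
#' @return Object of class `effect_spec`.
#' @examples
#' effect_spec("ldl_RR", mi_y1 = 0.84, mi_later = 0.74,
#'             stroke_y1 = 0.96, stroke_later = 0.81,
#'             rv_y1 = 0.88, rv_later = 0.71,
#'             cv_death_effect = 0.86, delta_LDL = 1.88)
#' @export
effect_spec <- function(mode = c("endpoint_HR", "ldl_RR"),
                        mi_y1, mi_later, stroke_y1, stroke_later,
                        rv_y1, rv_later, cv_death_effect = 1,
                        delta_LDL = NULL, ae_prob_26mo = 0.021,
                        ae_disutility = -0.0003) {
  mode <- match.arg(mode)
  eff <- c(mi_y1, mi_later, stroke_y1, stroke_later, rv_y1, rv_later,
           cv_death_effect)
  if (any(eff <= 0)) stop("effects must be positive")
  if (mode == "ldl_RR") {
    if (is.null(delta_LDL)) stop("ldl_RR mode requires delta_LDL")
    if (delta_LDL < 0) stop("delta_LDL must be non-negative")
  }
  if (ae_prob_26mo < 0 || ae_prob_26mo >= 1)
    stop("ae_prob_26mo must be in [0, 1)")
  if (ae_disutility > 0) stop("ae_disutility must be non-positive")
  structure(list(mode = mode, mi_y1 = unname(mi_y1),
                 mi_later = unname(mi_later), stroke_y1 = unname(stroke_y1),
                 stroke_later = unname(stroke_later), rv_y1 = unname(rv_y1),
                 rv_later = unname(rv_later),
                 cv_death_effect = unname(cv_death_effect),
                 delta_LDL = if (is.null(delta_LDL)) NULL
                             else unname(delta_LDL),
                 ae_prob_26mo = unname(ae_prob_26mo),
                 ae_disutility = unname(ae_disutility)),
            class = "effect_spec")
}

# per-event multiplier implied by the spec at a given cycle
effect_multipliers <- function(spec, cycle_index) {
  y1 <- cycle_index == 0L
  m <- c(mi = if (y1) spec$mi_y1 else spec$mi_later,
         stroke = if (y1) spec$stroke_y1 else spec$stroke_later,
         rv = if (y1) spec$rv_y1 else spec$rv_later,
         cv_death = spec$cv_death_effect)
  if (spec$mode == "ldl_RR") m <- m^spec$delta_LDL
  m
}

#' Apply clinical-endpoint hazard ratios to baseline rates
#'
#' Multiplies each baseline event rate by the event's hazard ratio:
#' the year-1 HR in model cycle 0 (therapy start), the beyond-year-1 HR
#' afterwards.  The cardiovascular death rate is multiplied by
#' `cv_death_effect`.
#'
#' @param baseline An [event_rates()] object.
#' @param spec An [effect_spec()] with `mode = "endpoint_HR"`.
#' @param cycle_index Model cycle (0-based years since therapy start).
#' @return A treated `event_rates` object.
#' @export
apply_endpoint_hr <- function(baseline, spec, cycle_index) {
  if (!inherits(spec, "effect_spec") || spec$mode != "endpoint_HR")
    stop("spec must be an effect_spec with mode 'endpoint_HR'")
  apply_treatment_effect(baseline, spec, cycle_index)
}

#' Apply LDL-C-reduction rate ratios to baseline rates
#'
#' Multiplies each baseline event rate by `RR ^ delta_LDL`, the rate ratio
#' per 1 mmol/l of LDL-C reduction raised to the achieved absolute
#' reduction, using year-1 RRs in cycle 0 and beyond-year-1 RRs after.
#'
#' @inheritParams apply_endpoint_hr
#' @param spec An [effect_spec()] with `mode = "ldl_RR"` and `delta_LDL`
#'   set.
#' @return A treated `event_rates` object.
#' @export
apply_ldl_rr <- function(baseline, spec, cycle_index) {
  if (!inherits(spec, "effect_spec") || spec$mode != "ldl_RR")
    stop("spec must be an effect_spec with mode 'ldl_RR'")
  apply_treatment_effect(baseline, spec, cycle_index)
}

#' Apply a treatment-effect specification to baseline rates
#'
#' Dispatches on the `mode` of the spec; see [apply_endpoint_hr()] and
#' [apply_ldl_rr()].
#'
#' @inheritParams apply_endpoint_hr
#' @param spec An [effect_spec()].
#' @return A treated `event_rates` object.
#' @export
apply_treatment_effect <- function(baseline, spec, cycle_index) {
  if (!inherits(baseline, "event_rates")) stop("baseline must be event_rates")
  if (!inherits(spec, "effect_spec")) stop("spec must be an effect_spec")
  m <- effect_multipliers(spec, cycle_index)
  out <- baseline
  out$nonfatal_MI <- baseline$nonfatal_MI * m[["mi"]]
  out$nonfatal_stroke <- baseline$nonfatal_stroke * m[["stroke"]]
  out$revascularization <- baseline$revascularization * m[["rv"]]
  out$CV_death <- baseline$CV_death * m[["cv_death"]]
  out
}

#' Construct a life table
#'
#' @param age Integer ages (years), consecutive.
#' @param all_cause_prob Annual all-cause death probability at each age.
#' @param cv_fraction Fraction of deaths at each age that are
#'   cardiovascular.
#' @return Object of class `life_table` (a data frame).
#' @export
life_table <- function(age, all_cause_prob, cv_fraction) {
  if (any(all_cause_prob < 0 | all_cause_prob > 1))
    stop("all_cause_prob must be in [0, 1]")
  if (any(cv_fraction < 0 | cv_fraction > 1))
    stop("cv_fraction must be in [0, 1]")
  if (any(diff(age) != 1L)) stop("ages must be consecutive integers")
  i40 <- age >= 40
  if (any(diff(all_cause_prob[i40]) < 0))
    stop("all-cause mortality must be non-decreasing beyond age 40")
  structure(data.frame(age = age, all_cause_prob = all_cause_prob,
                       cv_fraction = cv_fraction),
            class = c("life_table", "data.frame"))
}

#' Age-specific cardiovascular and non-cardiovascular death probabilities
#'
#' Looks an age up in a life table and splits the all-cause annual death
#' probability into its cardiovascular and non-cardiovascular components.
#' Ages outside the table's support are an error: the model never
#' extrapolates mortality silently.
#'
#' @param table A [life_table()].
#' @param age Age in whole years.
#' @return Named numeric vector `c(cv = ..., noncv = ...)`; the two
#'   components sum to the all-cause probability.
#' @export
mortality_at_age <- function(table, age) {
  if (!inherits(table, "life_table")) stop("table must be a life_table")
  i <- match(age, table$age)
  if (is.na(i)) stop("age ", age, " outside life-table support [",
                     min(table$age), ", ", max(table$age), "]")
  q <- table$all_cause_prob[i]
  f <- table$cv_fraction[i]
  c(cv = q * f, noncv = q * (1 - f))
}

# Cohort mortality at a given cycle.  The cohort's own baseline CV death
# rate (and, when available, all-cause rate) anchors the level at the
# starting age; the life table supplies the age trend.  Returns annual
# probabilities c(cv=, noncv=).
cohort_mortality <- function(table, age, start_age, cv_rate,
                             all_cause_rate = NULL) {
  m_now <- mortality_at_age(table, age)
  m_start <- mortality_at_age(table, start_age)
  # degenerate tables (zero mortality at the anchor age) leave the level
  # unscaled rather than dividing by zero
  trend <- function(now, start) if (start > 0) now / start else 1
  cv0 <- rate_to_prob(cv_rate)
  cv <- min(cv0 * trend(m_now[["cv"]], m_start[["cv"]]), 0.999999)
  ncv0 <- if (is.null(all_cause_rate)) m_start[["noncv"]]
          else split_mortality(rate_to_prob(all_cause_rate), cv0)
  ncv <- min(ncv0 * trend(m_now[["noncv"]], m_start[["noncv"]]), 0.999999)
  c(cv = cv, noncv = ncv)
}

# Per-state history multiplier implied by the event_rates adjustment
# factors; death states get NA.
state_history_multiplier <- function(space, rates) {
  hm <- rates$history_multipliers
  vapply(seq_len(nrow(space)), function(i) {
    if (space$absorbing[i]) return(NA_real_)
    m <- 1
    # the index MI that defines the cohort is not an "extra" history;
    # prior_MI counts second-and-further MI histories
    if (!is.na(space$mi[i]) && space$mi[i] >= 2) m <- m * hm[["prior_MI"]]
    if (!is.na(space$stroke[i]) && space$stroke[i] >= 1)
      m <- m * hm[["prior_stroke"]]
    if (!is.na(space$mi[i]) && space$mi[i] >= 2) m <- m * hm[["mi_2plus"]]
    if (!is.na(space$stroke[i]) && space$stroke[i] >= 2)
      m <- m * hm[["stroke_2plus"]]
    m
  }, numeric(1))
}

# Assemble per-state transition inputs for one cycle and one arm.
# Returns list(p_mi, p_stroke, p_cv, p_ncv, p_rv) vectors over states.
cycle_probabilities <- function(space, rates, table, age, start_age,
                                spec = NULL, cycle_index = 0L, mult = NULL) {
  eff <- if (is.null(spec)) rates
         else apply_treatment_effect(rates, spec, cycle_index)
  if (is.null(mult)) mult <- state_history_multiplier(space, rates)
  mult[is.na(mult)] <- 0
  p_mi <- rate_to_prob(eff$nonfatal_MI * mult)
  p_stroke <- rate_to_prob(eff$nonfatal_stroke * mult)
  p_rv <- rate_to_prob(eff$revascularization * mult)
  mort <- cohort_mortality(table, age, start_age, eff$CV_death,
                           rates$all_cause_death)
  # CV death scales with the state's history multiplier at the rate level
  cv_rate_state <- prob_to_rate(rep(mort[["cv"]], nrow(space))) * mult
  p_cv <- rate_to_prob(cv_rate_state)
  p_ncv <- rep(mort[["noncv"]], nrow(space))
  p_ncv[space$absorbing] <- 0
  list(p_mi = p_mi, p_stroke = p_stroke, p_cv = p_cv, p_ncv = p_ncv,
       p_rv = p_rv)
}
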