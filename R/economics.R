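#' Utility of a combined health state
#'
#' A state combining several event histories takes the *lowest* utility of
#' its component states: quality of life after multiple cardiovascular
#' events is driven by the worst sequela.
#'
#' @param components Numeric vector of component utilities (non-empty).
#' @return The minimum utility.
#' @examples
#' composite_utility(c(0.950, 0.750))
#' @export
composite_utility <- function(components) {
  if (length(components) == 0) stop("component utility set is empty")
  min(components)
}

#' Cost of a combined health state
#'
#' A state combining several event histories takes the *highest* cost of
#' its component states.
#'
#' @param components Numeric vector of component costs (non-empty).
#' @return The maximum cost.
#' @examples
#' composite_cost(c(13377.54, 10141.98))
#' @export
composite_cost <- function(components) {
  if (length(components) == 0) stop("component cost set is empty")
  max(components)
}

#' Combine direct and indirect costs under a payer perspective
#'
#' The healthcare perspective counts direct medical costs only; the
#' private-payer perspective adds indirect costs (caregiver wage loss and
#' informal care).
#'
#' @param direct,indirect Costs in CNY (non-negative).
#' @param perspective `"healthcare"` or `"private_payer"`.
#' @return Cost in CNY under the perspective.
#' @export
perspective_cost <- function(direct, indirect,
                             perspective = c("healthcare", "private_payer")) {
  if (any(direct < 0) || any(indirect < 0)) stop("costs must be non-negative")
  perspective <- match.arg(perspective)
  if (perspective == "healthcare") direct else direct + indirect
}

#' Annual drug acquisition cost of evolocumab
#'
#' Computes the annual cost from the unit price of a 140 mg pre-filled
#' injector and the dosing calendar: one unit every 14 days for the
#' 140 mg Q2W regimen, three units every 30 days for the 420 mg QM
#' regimen.  The published annual figures (CNY 7405 and 10365 at the list
#' price of 283.8) are reproduced within 0.05%; the packaged parameter
#' set carries the published figures as the defaults and this calculator
#' serves price sweeps.
#'
#' @param regimen `"Q2W_140"` or `"QM_420"`.
#' @param unit_price Price in CNY per 140 mg unit (positive).
#' @return Annual cost in CNY.
#' @examples
#' annual_drug_cost("Q2W_140", 283.8)
#' annual_drug_cost("QM_420", 283.8)
#' @export
annual_drug_cost <- function(regimen = c("Q2W_140", "QM_420"),
                             unit_price = 283.8) {
  regimen <- match.arg(regimen)
  if (unit_price <= 0) stop("unit_price must be positive")
  cal <- switch(regimen,
                Q2W_140 = c(interval_days = 14, units = 1),
                QM_420 = c(interval_days = 30, units = 3))
  (365.25 / cal[["interval_days"]]) * cal[["units"]] * unit_price
}

#' Convert CNY to USD at the reporting exchange rate
#'
#' @param amount_cny Amount in CNY.
#' @param rate CNY per USD (positive); the 2022 average market rate is
#'   6.726.
#' @param headline Round to the nearest integer, the convention for
#'   headline values.
#' @return Amount in USD.
#' @examples
#' convert_currency(257094)          # WTP threshold
#' convert_currency(85698)           # GDP per capita
#' @export
convert_currency <- function(amount_cny, rate = 6.726, headline = TRUE) {
  if (rate <= 0) stop("exchange rate must be positive")
  usd <- amount_cny / rate
  if (headline) round(usd) else usd
}

# ---- state-level cost/utility vectors -------------------------------------

# per-state annual cost under a perspective, from the parameter set.
# Acute tunnel states carry the year-1 (hospitalization) event rows;
# chronic states carry the beyond-1y maintenance rows; composites take
# the highest component cost, with the explicit combined-state row
# overriding the max rule where the input table prints one.  Death states
# carry no ongoing cost.
state_costs <- function(space, params,
                        perspective = c("healthcare", "private_payer"),
                        hospital_multiplier = 1) {
  perspective <- match.arg(perspective)
  pc <- function(dl, il, hosp = FALSE) {
    d <- param_value(params, "direct_cost", dl, default = 0)
    i <- param_value(params, "indirect_cost", il, default = 0)
    # the hospital-tier multiplier scales hospitalization (acute-year)
    # direct costs only, not post-discharge maintenance costs
    perspective_cost(d * (if (hosp) hospital_multiplier else 1), i,
                     perspective)
  }
  c_mi_y1 <- pc("Nonfatal MI (year 1)", "Nonfatal MI (year 1)", hosp = TRUE)
  c_mi_post <- pc("Nonfatal MI (beyond 1y)", "Nonfatal MI (beyond 1y)")
  c_st_y1 <- pc("Nonfatal stroke (year 1)", "Nonfatal stroke (year 1)",
                hosp = TRUE)
  c_st_post <- pc("Nonfatal stroke (beyond 1y)", "Nonfatal stroke (beyond 1y)")
  c_combined <- pc("Stroke + Post MI", "Stroke + Post MI")

  vapply(seq_len(nrow(space)), function(i) {
    if (space$absorbing[i]) return(0)
    mi <- space$mi[i]; st <- space$stroke[i]; phase <- space$phase[i]
    comp <- c(
      if (phase == "acute_MI") c_mi_y1,
      if (phase == "acute_stroke") c_st_y1,
      if (phase != "acute_MI" && mi >= 1) c_mi_post,
      if (phase != "acute_stroke" && st >= 1) c_st_post
    )
    if (phase == "chronic" && mi >= 1 && st >= 1 && c_combined > 0)
      return(c_combined)  # explicit combined-state row overrides the max rule
    composite_cost(comp)
  }, numeric(1))
}

# per-state utility: year-1 rows for the acute tunnels, beyond-1y rows
# for chronic states, 2+ variants where the history is 2+, min rule for
# composites, zero for death.
state_utilities <- function(space, params) {
  u <- function(l) param_value(params, "utility", l)
  u_mi_y1 <- u("Nonfatal MI (year 1)")
  u_mi2_y1 <- u("MI 2+(year 1)")
  u_mi_post <- u("Nonfatal MI (beyond 1y)")
  u_mi2_post <- u("MI 2+ (beyond 1y)")
  u_st_y1 <- u("Nonfatal stroke (year 1)")
  u_st2_y1 <- u("Stroke 2+ (year 1)")
  u_st_post <- u("Nonfatal stroke (beyond 1y)")
  u_st2_post <- u("Stroke 2+ (beyond 1y)")

  vapply(seq_len(nrow(space)), function(i) {
    if (space$absorbing[i]) return(0)
    mi <- space$mi[i]; st <- space$stroke[i]; phase <- space$phase[i]
    comp <- c(
      if (phase == "acute_MI") (if (mi >= 2) u_mi2_y1 else u_mi_y1),
      if (phase == "acute_stroke") (if (st >= 2) u_st2_y1 else u_st_y1),
      if (phase != "acute_MI" && mi >= 1) (if (mi >= 2) u_mi2_post
                                           else u_mi_post),
      if (phase != "acute_stroke" && st >= 1) (if (st >= 2) u_st2_post
                                               else u_st_post)
    )
    composite_utility(comp)
  }, numeric(1))
}

# one-off cost charged on the transition into CV death, attributed by the
# departing state's history: MI-only states take the MI death cost,
# stroke-only the stroke death cost, mixed histories the mean of the two.
cv_death_costs <- function(space, params,
                           perspective = c("healthcare", "private_payer")) {
  perspective <- match.arg(perspective)
  c_mi <- perspective_cost(
    param_value(params, "direct_cost", "Death due to MI", default = 0),
    param_value(params, "indirect_cost", "Death due to MI", default = 0),
    perspective)
  c_st <- perspective_cost(
    param_value(params, "direct_cost", "Death due to stroke", default = 0),
    param_value(params, "indirect_cost", "Death due to stroke", default = 0),
    perspective)
  vapply(seq_len(nrow(space)), function(i) {
    if (space$absorbing[i]) return(0)
    mi <- space$mi[i]; st <- space$stroke[i]
    if (space$phase[i] == "acute_MI") return(c_mi)
    if (space$phase[i] == "acute_stroke") return(c_st)
    if (mi >= 1 && st >= 1) return((c_mi + c_st) / 2)
    if (mi >= 1) c_mi else c_st
  }, numeric(1))
}

# per-procedure revascularization cost under a perspective
rv_cost <- function(params, perspective = c("healthcare", "private_payer"),
                    hospital_multiplier = 1) {
  perspective <- match.arg(perspective)
  perspective_cost(
    param_value(params, "direct_cost",
                "Coronary revascularization") * hospital_multiplier,
    param_value(params, "indirect_cost", "Coronary revascularization",
                default = 0),
    perspective)
}
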