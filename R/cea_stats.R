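#' Incremental cost-effectiveness ratio
#'
#' @param delta_cost Incremental cost (CNY), intervention minus
#'   comparator.
#' @param delta_qalys Incremental QALYs.
#' @return List with `value` (CNY per QALY, `NA` when not a ratio) and
#'   `status`: `"ratio"`, `"dominant"` (more effective, not more costly),
#'   `"dominated"` (less effective, not less costly) or `"undefined"`
#'   (zero QALY difference).  Negative ICERs are never reported as
#'   ratios; the dominance label is used instead.
#' @examples
#' icer(48732.96, 0.35)
#' icer(-5, 0.2)
#' @export
icer <- function(delta_cost, delta_qalys) {
  if (delta_qalys == 0) return(list(value = NA_real_, status = "undefined"))
  if (delta_qalys > 0 && delta_cost <= 0)
    return(list(value = NA_real_, status = "dominant"))
  if (delta_qalys < 0 && delta_cost >= 0)
    return(list(value = NA_real_, status = "dominated"))
  list(value = delta_cost / delta_qalys, status = "ratio")
}

#' Classify an ICER against the GDP-based willingness-to-pay thresholds
#'
#' Below one GDP per capita per QALY the strategy is highly
#' cost-effective; between one and three times GDP (boundaries included)
#' it is cost-effective; above three times GDP it is not cost-effective.
#'
#' @param icer_value ICER in CNY per QALY.
#' @param gdp_per_capita GDP per capita in CNY (positive).
#' @return One of `"highly_cost_effective"`, `"cost_effective"`,
#'   `"not_cost_effective"`.
#' @examples
#' classify_icer(137755.18, 85698)
#' classify_icer(40905.80, 85698)
#' @export
classify_icer <- function(icer_value, gdp_per_capita) {
  if (gdp_per_capita <= 0) stop("gdp_per_capita must be positive")
  if (is.na(icer_value)) return(NA_character_)
  if (icer_value < gdp_per_capita) "highly_cost_effective"
  else if (icer_value <= 3 * gdp_per_capita) "cost_effective"
  else "not_cost_effective"
}

#' Net monetary benefit
#'
#' `wtp * delta_qalys - delta_cost`; positive exactly when the ICER is
#' below the willingness-to-pay (for a QALY gain).
#'
#' @param delta_cost Incremental cost (CNY).
#' @param delta_qalys Incremental QALYs.
#' @param wtp Willingness-to-pay per QALY (CNY, non-negative).
#' @return NMB in CNY.
#' @export
nmb <- function(delta_cost, delta_qalys, wtp) {
  if (any(wtp < 0)) stop("wtp must be non-negative")
  wtp * delta_qalys - delta_cost
}

# ---- model assembly -------------------------------------------------------

# baseline event rates of a population profile, from the parameter set
population_rates <- function(population, params) {
  b <- population$rates_block
  acm <- param_value(params, b, "All-cause mortality", default = NA)
  event_rates(
    nonfatal_MI = param_value(params, b, "Nonfatal MI"),
    nonfatal_stroke = param_value(params, b, "Nonfatal stroke"),
    CV_death = param_value(params, b, "Cardiovascular-related death"),
    revascularization = param_value(params, b, "Coronary revascularization"),
    all_cause_death = if (is.na(acm)) NULL else acm,
    history_multipliers = c(
      prior_MI = 1,
      prior_stroke = param_value(params, "adjustment_synthetic",
                                 "History of stroke", default = 1),
      mi_2plus = param_value(params, "adjustment_synthetic",
                             "Recurrent MI (2+)", default = 1),
      stroke_2plus = param_value(params, "adjustment_synthetic",
                                 "Recurrent stroke (2+)", default = 1))
  )
}

# treated-arm effect specification of a population profile
build_effect_spec <- function(population, params, regimen) {
  ae_p <- param_value(params, "adverse_event",
                      "Injection site reaction, 26-month probability",
                      default = 0.021)
  ae_d <- param_value(params, "utility", "Injection site reaction, disutility",
                      default = -0.0003)
  if (population$effect_mode == "endpoint_HR") {
    b <- population$hr_block
    effect_spec("endpoint_HR",
                mi_y1 = param_value(params, b, "Nonfatal MI (year 1)"),
                mi_later = param_value(params, b, "Nonfatal MI (beyond 1y)"),
                stroke_y1 = param_value(params, b, "Nonfatal stroke (year 1)"),
                stroke_later = param_value(params, b,
                                           "Nonfatal stroke (beyond 1y)"),
                rv_y1 = param_value(params, b,
                                    "Coronary revascularization (year 1)"),
                rv_later = param_value(params, b,
                                       "Coronary revascularization (beyond 1y)"),
                cv_death_effect = param_value(params, b,
                                              "Cardiovascular-related death",
                                              default = 1),
                ae_prob_26mo = ae_p, ae_disutility = ae_d)
  } else {
    effect_spec("ldl_RR",
                mi_y1 = param_value(params, "effect_rr",
                                    "Nonfatal MI (year 1)"),
                mi_later = param_value(params, "effect_rr",
                                       "Nonfatal MI (beyond 1y)"),
                stroke_y1 = param_value(params, "effect_rr",
                                        "Nonfatal stroke (year 1)"),
                stroke_later = param_value(params, "effect_rr",
                                           "Nonfatal stroke (beyond 1y)"),
                rv_y1 = param_value(params, "effect_rr",
                                    "Coronary revascularization (year 1)"),
                rv_later = param_value(params, "effect_rr",
                                       "Coronary revascularization (beyond 1y)"),
                cv_death_effect = param_value(params, "effect_rr",
                                              "Vascular causes of death"),
                delta_LDL = unname(population$delta_LDL[regimen]),
                ae_prob_26mo = ae_p, ae_disutility = ae_d)
  }
}

#' Run the full cost-effectiveness comparison for one configuration
#'
#' Runs the cohort model for both arms (statins alone; evolocumab added
#' to statins) and summarizes costs, QALYs, the ICER, its WTP
#' classification and the net monetary benefit.
#'
#' @param population A [gen_population()] profile.
#' @param params A [parameter_set()].
#' @param table A [life_table()].
#' @param config A [run_config()]; its `start_age` is taken from the
#'   population when `NULL`.
#' @param space Optional pre-built [build_state_space()].
#' @return Object of class `cea_result`.
#' @examples
#' \donttest{
#' p <- gen_default_parameters()
#' lt <- gen_life_table(1)
#' res <- run_cea(gen_population("PEACE"), p, lt,
#'                run_config(perspective = "healthcare"))
#' res$icer
#' }
#' @export
run_cea <- function(population, params, table, config = NULL, space = NULL) {
  if (is.null(space)) space <- build_state_space()
  if (is.null(config)) config <- run_config()
  if (is.null(config$start_age)) config$start_age <- population$start_age
  rates <- population_rates(population, params)
  spec <- build_effect_spec(population, params, config$regimen)
  ctrl <- run_cohort(space, rates, table, params, config, spec = NULL)
  trt <- run_cohort(space, rates, table, params, config, spec = spec)
  dc <- trt$discounted_cost - ctrl$discounted_cost
  de <- trt$discounted_qalys - ctrl$discounted_qalys
  ic <- icer(dc, de)
  gdp <- param_value(params, "constants", "GDP per capita, CNY",
                     default = 85698)
  wtp <- param_value(params, "constants", "Willingness-to-pay per QALY, CNY",
                     default = 3 * gdp)
  cls <- if (ic$status == "dominant") "dominant"
         else if (ic$status == "dominated") "dominated"
         else classify_icer(ic$value, gdp)
  structure(list(population = population$name, regimen = config$regimen,
                 perspective = config$perspective,
                 cost_control = ctrl$discounted_cost,
                 cost_treated = trt$discounted_cost,
                 qalys_control = ctrl$discounted_qalys,
                 qalys_treated = trt$discounted_qalys,
                 delta_cost = dc, delta_qalys = de,
                 icer = ic$value, status = ic$status,
                 classification = cls,
                 nmb = nmb(dc, de, wtp), wtp = wtp, gdp = gdp,
                 trace_control = ctrl, trace_treated = trt),
            class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat(sprintf("CEA: %s, %s, %s perspective\n", x$population, x$regimen,
              x$perspective))
  cat(sprintf("  cost (CNY)  statins %.2f | +evolocumab %.2f | delta %.2f\n",
              x$cost_control, x$cost_treated, x$delta_cost))
  cat(sprintf("  QALYs       statins %.4f | +evolocumab %.4f | delta %.4f\n",
              x$qalys_control, x$qalys_treated, x$delta_qalys))
  if (x$status == "ratio")
    cat(sprintf("  ICER: %.2f CNY/QALY (%s)\n", x$icer, x$classification))
  else cat("  ICER:", x$status, "\n")
  invisible(x)
}

# flat one-row summary of a cea_result
cea_row <- function(x) {
  data.frame(population = x$population, regimen = x$regimen,
             perspective = x$perspective, cost_control = x$cost_control,
             cost_treated = x$cost_treated, qalys_control = x$qalys_control,
             qalys_treated = x$qalys_treated, delta_cost = x$delta_cost,
             delta_qalys = x$delta_qalys, icer = x$icer, status = x$status,
             classification = x$classification, nmb = x$nmb,
             stringsAsFactors = FALSE)
}

# ---- deterministic sensitivity analysis -----------------------------------

#' One-way deterministic sensitivity analysis (tornado table)
#'
#' Re-runs the base case with each uncertain parameter set to its lower
#' and upper bound in turn, everything else held at the point value, and
#' reports the resulting ICERs sorted by the absolute ICER spread
#' (descending; ties broken by parameter name).  The discount rate is
#' swept over its stated 0-8% range as an additional row.
#'
#' @inheritParams run_cea
#' @param ranges Optional data frame with columns `block`, `label`,
#'   `low`, `high`; defaults to every parameter row carrying a finite
#'   range plus the discount-rate sweep.
#' @return Data frame: `parameter`, `low`, `high`, `icer_low`,
#'   `icer_high`, `spread`.
#' @export
one_way_dsa <- function(population, params, table, config = NULL,
                        ranges = NULL, space = NULL) {
  if (is.null(space)) space <- build_state_space()
  if (is.null(config)) config <- run_config(start_age = population$start_age)
  if (is.null(ranges)) {
    has <- !is.na(params$low) & !is.na(params$high) &
      !(params$block == "constants")
    ranges <- params[has, c("block", "label", "low", "high")]
    ranges <- rbind(ranges, data.frame(block = "config",
                                       label = "Discount rate",
                                       low = 0, high = 0.08))
  }
  run_at <- function(block, label, value) {
    cfg <- config
    pars <- params
    if (block == "config" && label == "Discount rate") {
      cfg$disc_cost <- cfg$disc_qaly <- value
    } else {
      pars <- validate_parameters(set_param(pars, block, label, value))
    }
    run_cea(population, pars, table, cfg, space)$icer
  }
  out <- do.call(rbind, lapply(seq_len(nrow(ranges)), function(i) {
    b <- ranges$block[i]; l <- ranges$label[i]
    data.frame(parameter = paste0(b, ": ", l),
               low = ranges$low[i], high = ranges$high[i],
               icer_low = run_at(b, l, ranges$low[i]),
               icer_high = run_at(b, l, ranges$high[i]),
               stringsAsFactors = FALSE)
  }))
  out$spread <- out$icer_high - out$icer_low
  out <- out[order(-abs(out$spread), out$parameter), ]
  rownames(out) <- NULL
  out
}

# ---- probabilistic sensitivity analysis -----------------------------------

#' Fit a PSA sampling distribution from a point value and 95% interval
#'
#' Lognormal parameters are fitted by matching the median to the point
#' value and the 2.5/97.5% quantiles to the interval; gamma and beta by
#' moment matching, with the standard deviation taken as interval width
#' divided by 3.92.  Negative-valued rows (disutilities) are fitted on
#' their magnitude and negated on sampling.
#'
#' @param dist `"lognormal"`, `"gamma"`, `"beta"` or `"fixed"`.
#' @param value Point value.
#' @param low,high 95% interval bounds (ignored for `"fixed"`).
#' @param label Parameter name used in error messages.
#' @return A function of `n` returning `n` draws.
#' @export
fit_psa_distribution <- function(dist, value, low, high, label = "parameter") {
  if (dist == "fixed") return(function(n) rep(value, n))
  if (is.na(low) || is.na(high))
    stop("parameter '", label, "': interval required for ", dist)
  neg <- value < 0
  if (neg) {  # fit the magnitude, return the negated draws
    tmp <- -value; nl <- -high; nh <- -low
    value <- tmp; low <- nl; high <- nh
  }
  sd <- (high - low) / (2 * stats::qnorm(0.975))
  if (dist == "lognormal") {
    if (value <= 0 || low <= 0)
      stop("parameter '", label, "': lognormal needs positive values")
    meanlog <- log(value)
    sdlog <- (log(high) - log(low)) / (2 * stats::qnorm(0.975))
    f <- function(n) stats::rlnorm(n, meanlog, sdlog)
  } else if (dist == "gamma") {
    if (value <= 0) stop("parameter '", label, "': gamma needs a positive mean")
    shape <- value^2 / sd^2
    rate <- value / sd^2
    f <- function(n) stats::rgamma(n, shape = shape, rate = rate)
  } else if (dist == "beta") {
    if (value <= 0 || value >= 1)
      stop("parameter '", label, "': beta needs a mean inside (0, 1)")
    v <- sd^2
    if (v >= value * (1 - value))
      stop("parameter '", label, "': infeasible beta fit (variance too large)")
    nu <- value * (1 - value) / v - 1
    a <- value * nu; b <- (1 - value) * nu
    f <- function(n) stats::rbeta(n, a, b)
  } else stop("unknown distribution: ", dist)
  if (neg) function(n) -f(n) else f
}

#' Draw parameter replicates for probabilistic sensitivity analysis
#'
#' All parameters are drawn independently from their fitted
#' distributions (`"fixed"` rows always return the point value).  Given
#' the same seed the draw matrix is identical.
#'
#' @param params A [parameter_set()].
#' @param n_draws Number of Monte Carlo replications.
#' @param seed Integer seed.
#' @return Numeric matrix `n_draws x nrow(params)`, columns keyed
#'   `block||label`.
#' @export
sample_parameters <- function(params, n_draws = 10000, seed = 1L) {
  if (n_draws < 1) stop("n_draws must be at least 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  draws <- matrix(NA_real_, n_draws, nrow(params),
                  dimnames = list(NULL, paste(params$block, params$label,
                                              sep = "||")))
  for (j in seq_len(nrow(params))) {
    f <- fit_psa_distribution(params$dist[j], params$value[j], params$low[j],
                              params$high[j], params$label[j])
    draws[, j] <- f(n_draws)
  }
  draws
}

#' Probabilistic sensitivity analysis
#'
#' Monte Carlo simulation over the parameter distributions: each draw
#' re-runs the full two-arm model, yielding the incremental cost /
#' incremental QALY scatter and the cost-effectiveness acceptability
#' curve, `CEAC(lambda)` = fraction of draws with positive net monetary
#' benefit at willingness-to-pay `lambda`.
#'
#' @inheritParams run_cea
#' @param n_draws Number of Monte Carlo replications (10000 in the full
#'   analysis; smaller values keep exploratory runs fast).
#' @param seed Integer seed; identical seeds give identical results.
#' @param wtp_grid Willingness-to-pay grid for the CEAC; defaults to 101
#'   evenly spaced points from 0 to three times the WTP threshold, with
#'   the threshold itself always included.
#' @return List with `scatter` (data frame `draw`, `delta_cost`,
#'   `delta_qalys`), `ceac` (data frame `wtp`, `prob_cost_effective`),
#'   `n_failed` (draws where the model errored; they are recorded and
#'   skipped) and `prob_ce_at_wtp`.
#' @export
run_psa <- function(population, params, table, config = NULL,
                    n_draws = 10000, seed = 1L, wtp_grid = NULL,
                    space = NULL) {
  if (is.null(space)) space <- build_state_space()
  if (is.null(config)) config <- run_config(start_age = population$start_age)
  wtp <- param_value(params, "constants", "Willingness-to-pay per QALY, CNY",
                     default = 257094)
  if (is.null(wtp_grid))
    wtp_grid <- sort(unique(c(seq(0, 3 * wtp, length.out = 101), wtp)))
  draws <- sample_parameters(params, n_draws, seed)
  dc <- de <- rep(NA_real_, n_draws)
  n_failed <- 0L
  pars <- params
  for (k in seq_len(n_draws)) {
    pars$value <- as.numeric(draws[k, ])
    res <- tryCatch(run_cea(population, pars, table, config, space),
                    error = function(e) NULL)
    if (is.null(res)) { n_failed <- n_failed + 1L; next }
    dc[k] <- res$delta_cost
    de[k] <- res$delta_qalys
  }
  ok <- !is.na(dc)
  ceac <- vapply(wtp_grid, function(l) mean(nmb(dc[ok], de[ok], l) > 0),
                 numeric(1))
  list(scatter = data.frame(draw = seq_len(n_draws)[ok],
                            delta_cost = dc[ok], delta_qalys = de[ok]),
       ceac = data.frame(wtp = wtp_grid, prob_cost_effective = ceac),
       n_failed = n_failed,
       prob_ce_at_wtp = ceac[match(wtp, wtp_grid)])
}

# ---- scenario analyses ----------------------------------------------------

#' Scenario sweeps over horizon, starting age, discount, prices and
#' hospital tier
#'
#' Re-runs the base case across the scenario grid: time horizon, age at
#' therapy start, discount rate, annual statin cost at the centralized
#' procurement bounds, evolocumab annual cost and hospital-tier cost
#' multipliers; for both regimens under the configured perspective.
#'
#' @inheritParams run_cea
#' @param horizons,start_ages,discounts,statin_costs,evo_cost_factors
#'   Scenario axis levels; `NULL` skips the axis.  Defaults follow the
#'   published scenario grid.
#' @param hospital_tiers Named vector of hospitalization-cost multipliers
#'   (synthetic defaults spanning county to national referral hospitals).
#' @param regimens Regimens to run.
#' @return Data frame: `axis`, `level`, `regimen`, `perspective`,
#'   `icer`, `status`, `classification`.
#' @export
run_scenarios <- function(population, params, table, config = NULL,
                          horizons = c(5, 10, 15, 20, 25, 30, 35),
                          start_ages = c(65, 70, 75),
                          discounts = c(0.03, 0.05, 0.06),
                          statin_costs = c(118.86, 2855, 5470.28),
                          evo_cost_factors = NULL,
                          hospital_tiers = c(
                            "County hospitals" = 0.55,
                            "County-level municipal hospitals" = 0.70,
                            "Prefecture-level municipal hospitals" = 1.00,
                            "Provincial hospitals" = 1.15,
                            "Hospitals directly under the Health Commission" = 1.45),
                          regimens = c("Q2W_140", "QM_420"),
                          space = NULL) {
  if (is.null(space)) space <- build_state_space()
  if (is.null(config)) config <- run_config(start_age = population$start_age)
  max_age <- max(table$age)
  rows <- list()
  run_one <- function(axis, level, cfg) {
    if (cfg$start_age + cfg$horizon > max_age)
      stop("horizon exceeds life-table support")
    for (reg in regimens) {
      cfg$regimen <- reg
      r <- run_cea(population, params, table, cfg, space)
      rows[[length(rows) + 1L]] <<- data.frame(
        axis = axis, level = as.character(level), regimen = reg,
        perspective = cfg$perspective, icer = r$icer, status = r$status,
        classification = r$classification, stringsAsFactors = FALSE)
    }
  }
  for (h in horizons) { cfg <- config; cfg$horizon <- as.integer(h)
                        run_one("horizon", h, cfg) }
  for (a in start_ages) { cfg <- config; cfg$start_age <- a
                          run_one("start_age", a, cfg) }
  for (d in discounts) { cfg <- config; cfg$disc_cost <- cfg$disc_qaly <- d
                         run_one("discount", d, cfg) }
  for (s in statin_costs) { cfg <- config; cfg$statin_annual_cost <- s
                            run_one("statin_cost", s, cfg) }
  if (!is.null(evo_cost_factors)) {
    for (f in evo_cost_factors) {
      cfg <- config
      for (reg in regimens) {
        base_cost <- param_value(params, "drug_cost",
                                 if (reg == "Q2W_140") "Evolocumab (140 mg/2W)"
                                 else "Evolocumab (420 mg/M)")
        cfg$regimen <- reg
        cfg$evolocumab_annual_cost <- base_cost * f
        r <- run_cea(population, params, table, cfg, space)
        rows[[length(rows) + 1L]] <- data.frame(
          axis = "evolocumab_cost_factor", level = as.character(f),
          regimen = reg, perspective = cfg$perspective, icer = r$icer,
          status = r$status, classification = r$classification,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!is.null(hospital_tiers)) {
    for (tname in names(hospital_tiers)) {
      cfg <- config; cfg$hospital_multiplier <- hospital_tiers[[tname]]
      run_one("hospital_tier", tname, cfg)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare the two treatment-effect engines on a shared population
#'
#' Runs the full CEA under the clinical-endpoint (hazard-ratio) engine
#' and the LDL-C-reduction (rate-ratio) engine with otherwise identical
#' inputs -- the full-trial cohort profile -- and reports the ratio of
#' the two ICERs per perspective and regimen.
#'
#' @param params A [parameter_set()].
#' @param table A [life_table()].
#' @param horizon,disc Time horizon (years) and discount rate.
#' @param perspectives,regimens Grid to report.
#' @param space Optional state space.
#' @return Data frame with `perspective`, `regimen`, `icer_endpoint_hr`,
#'   `icer_ldl_rr`, `ratio` (`NA`, flagged `non-computable` in `note`,
#'   when either run is not a ratio).
#' @export
compare_effect_engines <- function(params, table, horizon = 25, disc = 0.05,
                                   perspectives = c("healthcare",
                                                    "private_payer"),
                                   regimens = c("Q2W_140", "QM_420"),
                                   space = NULL) {
  if (is.null(space)) space <- build_state_space()
  pop_hr <- gen_population("FOURIER")
  pop_rr <- gen_population("FOURIER")
  pop_rr$effect_mode <- "ldl_RR"
  out <- list()
  for (p in perspectives) {
    for (reg in regimens) {
      cfg <- run_config(horizon = horizon, start_age = pop_hr$start_age,
                        disc_cost = disc, disc_qaly = disc,
                        perspective = p, regimen = reg)
      r_hr <- run_cea(pop_hr, params, table, cfg, space)
      r_rr <- run_cea(pop_rr, params, table, cfg, space)
      computable <- r_hr$status == "ratio" && r_rr$status == "ratio"
      out[[length(out) + 1L]] <- data.frame(
        perspective = p, regimen = reg,
        icer_endpoint_hr = r_hr$icer, icer_ldl_rr = r_rr$icer,
        ratio = if (computable) r_hr$icer / r_rr$icer else NA_real_,
        note = if (computable) "" else "non-computable",
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, out)
}

# ---- plots ----------------------------------------------------------------

#' Tornado plot of a one-way sensitivity analysis
#'
#' @param tornado Output of [one_way_dsa()].
#' @param base_icer Base-case ICER (vertical reference line).
#' @param top Number of parameters to display.
#' @return Invisibly, the plotted subset.
#' @export
plot_tornado <- function(tornado, base_icer = NULL, top = 12) {
  t <- utils::head(tornado, top)
  t <- t[rev(seq_len(nrow(t))), ]
  lo <- pmin(t$icer_low, t$icer_high)
  hi <- pmax(t$icer_low, t$icer_high)
  graphics::par(mar = c(4, 16, 1, 1))
  graphics::plot(NULL, xlim = range(c(lo, hi, base_icer), na.rm = TRUE),
                 ylim = c(0.5, nrow(t) + 0.5), yaxt = "n",
                 xlab = "ICER (CNY per QALY)", ylab = "")
  graphics::segments(lo, seq_len(nrow(t)), hi, seq_len(nrow(t)), lwd = 8,
                     col = "steelblue")
  graphics::axis(2, at = seq_len(nrow(t)), labels = t$parameter, las = 1,
                 cex.axis = 0.6)
  if (!is.null(base_icer)) graphics::abline(v = base_icer, lty = 2)
  invisible(t)
}

#' Cost-effectiveness acceptability curve plot
#'
#' @param psa Output of [run_psa()].
#' @param wtp Willingness-to-pay threshold to mark.
#' @export
plot_ceac <- function(psa, wtp = NULL) {
  graphics::plot(psa$ceac$wtp, psa$ceac$prob_cost_effective, type = "l",
                 ylim = c(0, 1), xlab = "Willingness-to-pay (CNY per QALY)",
                 ylab = "Probability cost-effective")
  if (!is.null(wtp)) graphics::abline(v = wtp, lty = 2)
  invisible(psa$ceac)
}

#' Cost-effectiveness plane scatter plot
#'
#' @param psa Output of [run_psa()].
#' @param wtp Willingness-to-pay threshold (slope of the reference line).
#' @export
plot_ce_plane <- function(psa, wtp = NULL) {
  graphics::plot(psa$scatter$delta_qalys, psa$scatter$delta_cost, pch = 16,
                 cex = 0.3, col = grDevices::adjustcolor("steelblue", 0.4),
                 xlab = "Incremental QALYs", ylab = "Incremental cost (CNY)")
  graphics::abline(h = 0, v = 0, col = "grey")
  if (!is.null(wtp)) graphics::abline(a = 0, b = wtp, lty = 2)
  invisible(psa$scatter)
}
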