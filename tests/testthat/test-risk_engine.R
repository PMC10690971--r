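test_that("rate-to-probability conversion matches the closed form", {
  expect_identical(rate_to_prob(0, 1), 0)
  expect_equal(rate_to_prob(1.7, 1), 1 - exp(-0.017), tolerance = 1e-15)
  expect_equal(rate_to_prob(1.7, 1), 0.0168563, tolerance = 1e-6)
  p <- rate_to_prob(1e6, 1)
  expect_lte(p, 1)  # saturates at double precision
  expect_gt(p, 1 - 1e-12)
  expect_error(rate_to_prob(-1), "non-negative")
  # monotone in the rate; small-rate limit p ~ r/100 within 1% relative
  r <- seq(0, 50, by = 0.5)
  expect_true(all(diff(rate_to_prob(r)) > 0))
  small <- c(0.01, 0.1, 0.5, 0.9)
  expect_true(all(abs(rate_to_prob(small) - small / 100) /
                    (small / 100) < 0.01))
})

test_that("mortality splits into CV and non-CV components consistently", {
  expect_equal(split_mortality(0.031, 0.022), 0.009)
  expect_identical(split_mortality(0.04, 0.04), 0)
  expect_error(split_mortality(0.05, 0.06), "inconsistent")
  # conservation: cv + noncv == all_cause
  set.seed(3)
  ac <- runif(50, 0, 0.5)
  cv <- ac * runif(50)
  expect_equal(cv + split_mortality(ac, cv), ac, tolerance = 1e-15)
})

test_that("endpoint hazard ratios multiply rates by period", {
  base <- event_rates(nonfatal_MI = 2.5, nonfatal_stroke = 0.9,
                      CV_death = 0.8, revascularization = 3.9)
  spec <- effect_spec("endpoint_HR", mi_y1 = 0.79, mi_later = 0.64,
                      stroke_y1 = 0.52, stroke_later = 0.52,
                      rv_y1 = 0.84, rv_later = 0.72, cv_death_effect = 1)
  y1 <- apply_endpoint_hr(base, spec, 0L)
  expect_equal(y1$nonfatal_MI, 2.5 * 0.79)
  expect_equal(y1$nonfatal_MI, 1.975)
  expect_equal(y1$nonfatal_stroke, 0.9 * 0.52)
  later <- apply_endpoint_hr(base, spec, 5L)
  expect_equal(later$nonfatal_MI, 2.5 * 0.64)
  expect_equal(later$nonfatal_stroke, 0.9 * 0.52)
  # null effect leaves rates unchanged
  null <- effect_spec("endpoint_HR", 1, 1, 1, 1, 1, 1, 1)
  expect_equal(apply_endpoint_hr(base, null, 0L)[1:4], base[1:4])
  # engine mismatch is an error
  ldl <- effect_spec("ldl_RR", 0.84, 0.74, 0.96, 0.81, 0.88, 0.71, 0.86,
                     delta_LDL = 1)
  expect_error(apply_endpoint_hr(base, ldl, 0L), "endpoint_HR")
  expect_error(apply_ldl_rr(base, spec, 0L), "ldl_RR")
})

test_that("LDL engine applies RR^deltaLDL and is multiplicative in delta", {
  base <- event_rates(nonfatal_MI = 1, nonfatal_stroke = 1, CV_death = 1,
                      revascularization = 1)
  mk <- function(d) effect_spec("ldl_RR", 0.74, 0.74, 0.74, 0.74, 0.74,
                                0.74, 0.74, delta_LDL = d)
  expect_equal(apply_ldl_rr(base, mk(1), 1L)$nonfatal_MI, 0.74)
  expect_equal(apply_ldl_rr(base, mk(2), 1L)$nonfatal_MI, 0.5476,
               tolerance = 1e-12)
  unit <- effect_spec("ldl_RR", 1, 1, 1, 1, 1, 1, 1, delta_LDL = 3.7)
  expect_equal(apply_ldl_rr(base, unit, 4L)$nonfatal_stroke, 1)
  expect_error(effect_spec("ldl_RR", 0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 0.8),
               "delta_LDL")
})

test_that("the two engines coincide at delta LDL = 1 with HRs set to RRs", {
  base <- event_rates(nonfatal_MI = 1.7, nonfatal_stroke = 0.9,
                      CV_death = 2.2, revascularization = 6.4)
  rr <- c(0.84, 0.74, 0.96, 0.81, 0.88, 0.71, 0.86)
  hr_spec <- effect_spec("endpoint_HR", rr[1], rr[2], rr[3], rr[4], rr[5],
                         rr[6], rr[7])
  rr_spec <- effect_spec("ldl_RR", rr[1], rr[2], rr[3], rr[4], rr[5],
                         rr[6], rr[7], delta_LDL = 1)
  for (t in c(0L, 1L, 7L)) {
    a <- apply_endpoint_hr(base, hr_spec, t)
    b <- apply_ldl_rr(base, rr_spec, t)
    expect_identical(a[c("nonfatal_MI", "nonfatal_stroke", "CV_death",
                         "revascularization")],
                     b[c("nonfatal_MI", "nonfatal_stroke", "CV_death",
                         "revascularization")])
  }
})

test_that("treated rates never exceed baseline for protective effects", {
  set.seed(11)
  for (k in 1:20) {
    base <- event_rates(nonfatal_MI = runif(1, 0, 5),
                        nonfatal_stroke = runif(1, 0, 5),
                        CV_death = runif(1, 0, 5),
                        revascularization = runif(1, 0, 8))
    e <- runif(7, 0.3, 1)
    spec <- effect_spec("endpoint_HR", e[1], e[2], e[3], e[4], e[5], e[6],
                        e[7])
    for (t in c(0L, 3L)) {
      trt <- apply_endpoint_hr(base, spec, t)
      expect_lte(trt$nonfatal_MI, base$nonfatal_MI)
      expect_lte(trt$CV_death, base$CV_death)
    }
  }
})

test_that("adverse-event probability annualizes by constant hazard", {
  expect_identical(annual_ae_prob(0), 0)
  expect_equal(annual_ae_prob(0.021), 1 - 0.979^(12 / 26), tolerance = 1e-15)
  expect_equal(annual_ae_prob(0.021), 0.00975, tolerance = 1e-3)
  # round trip: compounding the annual probability over 26 months
  # recovers the input
  p <- 0.17
  a <- annual_ae_prob(p)
  expect_equal(1 - (1 - a)^(26 / 12), p, tolerance = 1e-12)
  expect_error(annual_ae_prob(1), "\\[0, 1\\)")
})

test_that("life-table lookup conserves and refuses extrapolation", {
  lt <- default_lt()
  m60 <- mortality_at_age(lt, 60)
  expect_equal(sum(m60), lt$all_cause_prob[lt$age == 60], tolerance = 1e-15)
  expect_error(mortality_at_age(lt, min(lt$age) - 1), "outside")
  expect_error(mortality_at_age(lt, max(lt$age) + 1), "outside")
  m70 <- mortality_at_age(lt, 70)
  expect_gte(sum(m70), sum(m60))
})

test_that("event-rate validation enforces signs and mortality ordering", {
  expect_error(event_rates(-1, 1, 1, 1), "non-negative")
  expect_error(event_rates(1, 1, CV_death = 3, revascularization = 1,
                           all_cause_death = 2), "all-cause")
  er <- event_rates(1, 1, 1, 1, history_multipliers = c(prior_stroke = 2))
  expect_equal(unname(er$history_multipliers["prior_stroke"]), 2)
  expect_equal(unname(er$history_multipliers["mi_2plus"]), 1)
})
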