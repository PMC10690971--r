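test_that("ICER handles ratios, dominance and degenerate denominators", {
  expect_equal(icer(100, 1)$value, 100)
  expect_identical(icer(100, 1)$status, "ratio")
  expect_identical(icer(-5, 0.2)$status, "dominant")
  expect_identical(icer(5, -0.2)$status, "dominated")
  expect_identical(icer(50, 0)$status, "undefined")
  expect_true(is.na(icer(50, 0)$value))
  # cheaper and worse is still a ratio (southwest quadrant)
  expect_identical(icer(-50, -1)$status, "ratio")
})

test_that("WTP classification uses the 1x / 3x GDP boundaries", {
  gdp <- 85698
  expect_identical(classify_icer(137755.18, gdp), "cost_effective")
  expect_identical(classify_icer(40905.80, gdp), "highly_cost_effective")
  expect_identical(classify_icer(3 * gdp + 1, gdp), "not_cost_effective")
  # boundaries are inclusive on the cost-effective side
  expect_identical(classify_icer(gdp, gdp), "cost_effective")
  expect_identical(classify_icer(3 * gdp, gdp), "cost_effective")
  expect_identical(classify_icer(gdp - 0.01, gdp), "highly_cost_effective")
  expect_error(classify_icer(1, 0), "positive")
})

test_that("net monetary benefit is consistent with the ICER", {
  expect_identical(nmb(0, 0, 257094), 0)
  expect_equal(nmb(48732.96, 0.35, 257094), 257094 * 0.35 - 48732.96,
               tolerance = 1e-12)
  set.seed(8)
  for (k in 1:50) {
    dc <- runif(1, -1e5, 5e5)
    de <- runif(1, 1e-3, 1)
    wtp <- runif(1, 0, 5e5)
    expect_identical(nmb(dc, de, wtp) > 0, dc / de < wtp)
  }
  expect_error(nmb(1, 1, -5), "non-negative")
})

test_that("distribution fitting matches the stated intervals", {
  set.seed(42)
  # lognormal: median at the point value, ~95% of mass in the interval
  f <- fit_psa_distribution("lognormal", 0.74, 0.70, 0.78)
  x <- f(10000)
  expect_gt(median(x), 0.70)
  expect_lt(median(x), 0.78)
  cover <- mean(x >= 0.70 & x <= 0.78)
  expect_gt(cover, 0.94)
  expect_lt(cover, 0.96)
  # gamma: mean at the point value, sd = width / 3.92
  g <- fit_psa_distribution("gamma", 2855, 2141.25, 3568.75)
  y <- g(200000)
  expect_equal(mean(y), 2855, tolerance = 0.01)
  expect_equal(sd(y), (3568.75 - 2141.25) / (2 * qnorm(0.975)),
               tolerance = 0.02)
  # beta: stays inside (0, 1)
  b <- fit_psa_distribution("beta", 0.51, 0.47, 0.54)
  z <- b(10000)
  expect_true(all(z > 0 & z < 1))
  expect_equal(mean(z), 0.51, tolerance = 0.01)
  # negative (disutility) rows sample non-positive values
  d <- fit_psa_distribution("beta", -0.0003, -0.002, 0)
  expect_true(all(d(1000) <= 0))
  # fixed always returns the point value
  expect_identical(fit_psa_distribution("fixed", 7, NA, NA)(3), rep(7, 3))
  # infeasible beta named in the error
  expect_error(fit_psa_distribution("beta", 0.5, -3, 4, label = "u_bad"),
               "u_bad")
})

test_that("parameter draws are reproducible and respect fixed rows", {
  params <- default_params()
  d1 <- sample_parameters(params, 50, seed = 7)
  d2 <- sample_parameters(params, 50, seed = 7)
  expect_identical(d1, d2)
  d3 <- sample_parameters(params, 50, seed = 8)
  expect_false(identical(d1, d3))
  fixed <- params$dist == "fixed"
  for (j in which(fixed))
    expect_true(all(d1[, j] == params$value[j]))
  expect_error(sample_parameters(params, 0), "at least 1")
})

test_that("tornado analysis orders by spread with deterministic ties", {
  pop <- gen_population("PEACE")
  params <- default_params()
  ranges <- data.frame(
    block = c("drug_cost", "utility", "direct_cost"),
    label = c("Statins", "Nonfatal MI (beyond 1y)",
              "Nonfatal MI (year 1)"),
    low = c(2141.25, 0.942, 19889.18),
    high = c(3568.75, 0.958, 33148.63))
  # a degenerate range contributes zero spread and sorts last
  ranges <- rbind(ranges, data.frame(block = "drug_cost", label = "Statins",
                                     low = 2855, high = 2855))
  tor <- one_way_dsa(pop, params, default_lt(), run_config(start_age = 61),
                     ranges, default_space())
  expect_identical(nrow(tor), 4L)
  expect_true(all(diff(abs(tor$spread)) <= 1e-9))
  expect_equal(tor$spread[4], 0, tolerance = 1e-9)
  # the ±25% cost rule reproduces the statin bounds
  expect_identical(unname(unlist(ranges[1, c("low", "high")])),
                   c(2855 * 0.75, 2855 * 1.25))
  # out-of-domain bounds are rejected with the parameter named
  bad <- data.frame(block = "utility", label = "Nonfatal MI (beyond 1y)",
                    low = 0.9, high = 1.2)
  expect_error(one_way_dsa(pop, params, default_lt(),
                           run_config(start_age = 61), bad,
                           default_space()),
               "Nonfatal MI \\(beyond 1y\\)")
})

test_that("PSA is seed-reproducible with coherent CEAC limits", {
  pop <- gen_population("PEACE")
  params <- default_params()
  cfg <- run_config(horizon = 10, start_age = 61)
  psa1 <- run_psa(pop, params, default_lt(), cfg, n_draws = 40, seed = 7,
                  space = default_space())
  psa2 <- run_psa(pop, params, default_lt(), cfg, n_draws = 40, seed = 7,
                  space = default_space())
  expect_identical(psa1$ceac, psa2$ceac)
  expect_identical(psa1$scatter, psa2$scatter)
  expect_identical(psa1$n_failed, 0L)
  # CEAC(0) is the fraction of draws that save money
  expect_equal(psa1$ceac$prob_cost_effective[psa1$ceac$wtp == 0],
               mean(psa1$scatter$delta_cost < 0))
  # for QALY-gaining draws the CEAC is non-decreasing in lambda
  if (all(psa1$scatter$delta_qalys > 0))
    expect_true(all(diff(psa1$ceac$prob_cost_effective) >= 0))
  # CEAC at huge lambda approaches the fraction of QALY-gaining draws
  hi <- nmb(psa1$scatter$delta_cost, psa1$scatter$delta_qalys, 1e12) > 0
  expect_equal(mean(psa1$scatter$delta_qalys > 0), mean(hi))
})

test_that("an all-fixed parameter set collapses the PSA to the base case", {
  pop <- gen_population("PEACE")
  params <- default_params()
  params$dist <- "fixed"
  cfg <- run_config(horizon = 10, start_age = 61)
  psa <- run_psa(pop, params, default_lt(), cfg, n_draws = 10, seed = 3,
                 space = default_space())
  base <- run_cea(pop, params, default_lt(), cfg, default_space())
  expect_true(all(abs(psa$scatter$delta_cost - base$delta_cost) < 1e-9))
  expect_true(all(abs(psa$scatter$delta_qalys - base$delta_qalys) < 1e-12))
  # the CEAC is then a step function located at the base-case ICER
  below <- psa$ceac$wtp < base$icer
  expect_true(all(psa$ceac$prob_cost_effective[below] == 0))
  expect_true(all(psa$ceac$prob_cost_effective[!below] == 1))
})

test_that("engine comparison reports per-cell ICER ratios", {
  cmpr <- compare_effect_engines(default_params(), default_lt(),
                                 horizon = 15, space = default_space())
  expect_identical(nrow(cmpr), 4L)
  expect_true(all(cmpr$note == ""))
  expect_true(all(cmpr$ratio > 1))
  expect_equal(cmpr$ratio, cmpr$icer_endpoint_hr / cmpr$icer_ldl_rr,
               tolerance = 1e-12)
})
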