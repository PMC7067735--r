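test_that("WTP currency conversion is exact and homogeneous", {
  expect_equal(convert_wtp(5, 1, 1), 5)
  e <- econ_params()
  expect_equal(convert_wtp(71.6, e$deflator, e$fx), 8.29, tolerance = 1e-12)
  expect_equal(convert_wtp(10, 1.2, 4), convert_wtp(10, 1.2, 2) / 2)
  expect_equal(convert_wtp(20, 1.2, 2), 2 * convert_wtp(10, 1.2, 2))
  expect_error(convert_wtp(-1, 1, 1), "positive")
})

test_that("WPUE changes reproduce the published worked arithmetic", {
  expect_equal(wpue_change(0.8, 13), 0.10)
  expect_equal(wpue_change(0.3, -18), -0.05)
  expect_equal(wpue_change(5, 0), 0)
  # full precision mode keeps the unrounded product
  expect_equal(wpue_change(0.3, -18, rounding = FALSE), -0.054)
  expect_error(wpue_change(0, 10), "positive")
})

test_that("valuation of a WPUE change matches the published EUR figures", {
  expect_equal(valuation(0.10, 8.29), 0.8)
  expect_equal(valuation(-0.05, 18.0), -0.9)
  expect_equal(valuation(0, 5), 0)
  expect_equal(valuation(0.10, 8.29, rounding = FALSE), 0.829)
  expect_error(valuation(0.1, 0), "positive")
})

test_that("relative increases over the WPUE baselines match the printed ratios", {
  expect_equal(relative_increase(1, 0.3), 100 / 0.3)
  expect_equal(round(relative_increase(1, 0.3)), 333)
  expect_equal(relative_increase(1, 0.8), 125)
  expect_equal(relative_increase(0, 2), 0)
  expect_error(relative_increase(1, 0), "positive")
})

test_that("effort ratio and delta-method CI reproduce the survey estimate", {
  er <- effort_ratio(505000, 83000, 124000, 64000)
  expect_equal(round(er$ratio, 1), 6.1)
  # delta-method half-width; the survey prints +/- 5.0
  expect_equal(er$ci95, 4.9237, tolerance = 1e-4)
  expect_lt(abs(er$ci95 - 5.0), 0.15)
  expect_equal(effort_ratio(1000, 1000)$ratio, 1)
  expect_error(effort_ratio(10, 0), "positive")
})

test_that("delta-method CI agrees with Monte-Carlo ratio sampling when CVs are small", {
  # at one-tenth of the survey CVs the first-order formula is near exact
  er <- effort_ratio(505000, 83000, 12400, 6400)
  set.seed(31)
  n <- 2e5
  e1 <- rnorm(n, 505000, 12400 / 1.96)
  e2 <- rnorm(n, 83000, 6400 / 1.96)
  mc_half <- 1.96 * sd(e1 / e2)
  expect_equal(er$ci95, mc_half, tolerance = 0.02)
})

test_that("net benefit combines species by effort weight with the right sign logic", {
  nb <- net_benefit(0.829, -0.9, 6.1)
  expect_equal(nb$net_index, 6.1 * 0.829 - 0.9, tolerance = 1e-12)
  expect_equal(round(nb$net_index, 2), 4.16)
  expect_equal(nb$net_sign, 1)
  expect_equal(net_benefit(0.5, -0.5, 1)$net_index, 0)
  expect_equal(net_benefit(0.8, -0.9, 0.9 / 0.8 - 1e-9)$net_sign, -1)
  expect_equal(net_benefit(0.8, -0.9, 0.9 / 0.8 + 1e-9)$net_sign, 1)
  expect_error(net_benefit(1, 1, 0), "positive")
})

test_that("net index is strictly increasing in the effort ratio for a perch gain", {
  rs <- seq(0.5, 10, by = 0.5)
  idx <- sapply(rs, function(r) net_benefit(0.8, -0.9, r)$net_index)
  expect_true(all(diff(idx) > 0))
})

test_that("the full chain reproduces the published scenario valuation exactly", {
  res <- value_chain(c(perch = 13, pikeperch = -18))
  expect_equal(unname(res$delta_wpue), c(0.10, -0.05))
  expect_equal(unname(res$value_change), c(0.8, -0.9))
  expect_equal(round(res$effort_ratio, 1), 6.1)
  expect_equal(res$net_sign, 1)
  # full-precision mode reports the unrounded chain
  full <- value_chain(c(perch = 13, pikeperch = -18), rounding = FALSE)
  expect_equal(unname(full$value_change[1]), 0.8 * 0.13 * 8.29, tolerance = 1e-12)
  expect_error(value_chain(c(perch = 13)), "pikeperch")
})
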