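test_that("generators are bit-identical under a fixed seed", {
  cfg <- demo_config(seed = 7)
  ls1 <- generate_landscape(cfg)
  ls2 <- generate_landscape(cfg)
  expect_identical(ls1$water_mask$values, ls2$water_mask$values)
  expect_identical(ls1$depth$values, ls2$depth$values)
  expect_identical(ls1$secchi_base$values, ls2$secchi_base$values)
  h1 <- generate_habitat_map(ls1, "perch", 11, "gam")
  h2 <- generate_habitat_map(ls2, "perch", 11, "gam")
  expect_identical(h1$values, h2$values)
  m1 <- generate_monitoring(ls1$depth, 10, 0.5, seed = 3)
  m2 <- generate_monitoring(ls1$depth, 10, 0.5, seed = 3)
  expect_identical(m1, m2)
})

test_that("landscape satisfies its structural invariants", {
  ls <- generate_landscape(demo_config(seed = 2))
  water <- ls$water_mask$values == 1
  expect_true(all(ls$depth$values[water] > 0))
  expect_true(all(ls$secchi_base$values[water] > 0))
  expect_true(all(is.na(ls$depth$values[!water])))
  expect_true(all(is.na(ls$secchi_base$values[!water])))
  wf <- mean(water)
  expect_gte(wf, 0.5); expect_lte(wf, 0.95)
  # land strip along the west edge is present on every row
  expect_true(all(ls$water_mask$values[, 1] == 0))
})

test_that("depth increases on average with distance from land", {
  ls <- generate_landscape(demo_config(seed = 4))
  water <- ls$water_mask$values == 1
  land_idx <- which(!water, arr.ind = TRUE)
  wat_idx <- which(water, arr.ind = TRUE)
  d <- sqrt(outer(wat_idx[, 1], land_idx[, 1], "-")^2 +
              outer(wat_idx[, 2], land_idx[, 2], "-")^2)
  dist_to_land <- apply(d, 1, min)
  expect_gt(cor(dist_to_land, ls$depth$values[water]), 0)
})

test_that("habitat prevalence tracks the scenario with the species' response sign", {
  cfg <- demo_config(seed = 5)
  ls <- generate_landscape(cfg)
  levels <- scenario_levels()
  prev <- function(species) sapply(levels, function(sc) {
    maps <- lapply(cfg$techniques, function(tech)
      generate_habitat_map(ls, species, sc, tech, cfg))
    mean(sapply(maps, function(m) mean(m$values, na.rm = TRUE)))
  })
  pp <- prev("perch"); pk <- prev("pikeperch")
  # strict ordering at the extremes, strong rank agreement across all levels
  expect_gt(pp[levels == 48], pp[levels == 0])
  expect_lt(pp[levels == -10], pp[levels == 0])
  expect_lt(pk[levels == 48], pk[levels == 0])
  expect_gt(pk[levels == -10], pk[levels == 0])
  expect_gt(cor(levels, pp, method = "spearman"), 0.9)
  expect_lt(cor(levels, pk, method = "spearman"), -0.9)
  # baseline prevalence near the configured base rate
  expect_lt(abs(pp[levels == 0] - cfg$base_prevalence[["perch"]]), 0.1)
})

test_that("a zero secchi response leaves prevalence flat across scenarios", {
  cfg <- habitat_gen_config(base_prevalence = c(neutral = 0.3),
                            secchi_response = c(neutral = 0),
                            seed = 6)
  ls <- generate_landscape(cfg)
  prev <- sapply(scenario_levels(), function(sc)
    mean(sapply(cfg$techniques, function(tech)
      mean(generate_habitat_map(ls, "neutral", sc, tech, cfg)$values,
           na.rm = TRUE))))
  expect_lt(diff(range(prev)), 0.05)
})

test_that("habitat maps are binary over water, nodata on land, autocorrelated", {
  cfg <- demo_config(seed = 8)
  ls <- generate_landscape(cfg)
  h <- generate_habitat_map(ls, "perch", 0, "maxent", cfg)
  water <- ls$water_mask$values == 1
  expect_true(all(h$values[water] %in% c(0, 1)))
  expect_true(all(is.na(h$values[!water])))
  # join-count style check: same-value neighbour pairs exceed the random
  # expectation p^2 + (1-p)^2
  v <- h$values
  pairs_same <- mean((v[, -1] == v[, -ncol(v)]), na.rm = TRUE)
  p <- mean(v, na.rm = TRUE)
  expect_gt(pairs_same, p^2 + (1 - p)^2 + 0.05)
})

test_that("technique variants are correlated but not identical", {
  cfg <- demo_config(seed = 10)
  ls <- generate_landscape(cfg)
  maps <- lapply(cfg$techniques, function(tech)
    generate_habitat_map(ls, "pikeperch", 0, tech, cfg))
  v <- sapply(maps, function(m) m$values[ls$water_mask$values == 1])
  for (a in 1:2) for (b in (a + 1):3) {
    r <- cor(v[, a], v[, b])
    expect_gt(r, 0.3)
    expect_lt(r, 0.999)
  }
})

test_that("unknown labels are configuration errors", {
  cfg <- demo_config()
  ls <- generate_landscape(cfg)
  expect_error(generate_habitat_map(ls, "cod", 0, "gam", cfg), "unknown species")
  expect_error(generate_habitat_map(ls, "perch", 0, "glm", cfg), "unknown technique")
  expect_error(generate_habitat_map(ls, "perch", 33, "gam", cfg), "unknown scenario")
  expect_error(habitat_gen_config(grid_size = 8), ">= 16")
  expect_error(habitat_gen_config(secchi_response = c(perch = -1, pikeperch = -5)),
               "perch")
  expect_error(habitat_gen_config(base_prevalence = c(perch = 1.2, pikeperch = 0.2)),
               "\\(0, 1\\)")
})

test_that("noiseless monitoring reproduces the map and closes the identity chain", {
  m <- matrix(seq(1, 8, length.out = 64), 8, 8)
  m[1, ] <- NA  # a land row
  cpue <- raster_grid(m, 250)
  obs <- generate_monitoring(cpue, 20, noise_sd = 0, seed = 1)
  expect_equal(obs$observed_cpue, cpue$values[cbind(obs$row, obs$col)])
  fit <- fit_obs_vs_pred(extract_predictions(cpue, obs))
  expect_equal(fit$slope, 1, tolerance = 1e-12)
  expect_equal(fit$intercept, 0, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
})

test_that("monitoring site-count preconditions hold", {
  cpue <- raster_grid(matrix(1, 4, 4), 250)
  expect_error(generate_monitoring(cpue, 2, 0, 1), "at least 3")
  expect_error(generate_monitoring(cpue, 17, 0, 1), "exceeds")
})
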