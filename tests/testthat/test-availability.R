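test_that("circular kernel matches distance arithmetic and symmetry", {
  # radius equal to one cell: centre plus the four orthogonal neighbours
  k <- circular_kernel(250, 250)
  expect_identical(k, matrix(c(0L, 1L, 0L, 1L, 1L, 1L, 0L, 1L, 0L), 3, 3))

  # lattice-point count oracle for the perch window (10 km at 250 m cells)
  r_cells <- 40
  count <- 0L
  for (i in -r_cells:r_cells)
    for (j in -r_cells:r_cells)
      if (sqrt(i^2 + j^2) <= r_cells) count <- count + 1L
  expect_identical(sum(circular_kernel(10000, 250)), count)

  k2 <- circular_kernel(1300, 250)
  expect_identical(k2, t(k2))
  expect_identical(k2, k2[rev(seq_len(nrow(k2))), ])
  expect_identical(k2, k2[, rev(seq_len(ncol(k2)))])
  expect_identical(k2[(nrow(k2) + 1) %/% 2, (ncol(k2) + 1) %/% 2], 1L)
})

test_that("sub-cell radius is rejected rather than degrading to one cell", {
  expect_error(circular_kernel(100, 250), "single cell")
  expect_error(habitat_availability(raster_grid(matrix(0, 4, 4), 250),
                                    raster_grid(matrix(1, 4, 4), 250), 100),
               "single cell")
})

test_that("availability saturates at 1 and vanishes at 0", {
  w <- raster_grid(matrix(1, 16, 16), 250)
  all_hab <- raster_grid(matrix(1, 16, 16), 250)
  no_hab <- raster_grid(matrix(0, 16, 16), 250)
  expect_true(all(habitat_availability(all_hab, w, 1000)$values == 1))
  expect_true(all(habitat_availability(no_hab, w, 1000)$values == 0))
})

test_that("fft and direct counting agree with the double-loop oracle exactly", {
  for (seed in 1:6) {
    fx <- random_habitat_fixture(n = 32, seed = seed)
    radius <- sample(c(500, 750, 1200, 2000), 1)
    oracle <- brute_force_availability(fx$habitat, fx$water, radius)
    fast <- habitat_availability(fx$habitat, fx$water, radius, method = "fft")
    direct <- habitat_availability(fx$habitat, fx$water, radius, method = "direct")
    expect_identical(fast$values, oracle$values)
    expect_identical(direct$values, oracle$values)
  }
})

test_that("availability is nodata exactly on land and in [0,1] on water", {
  fx <- random_habitat_fixture(n = 48, seed = 9)
  a <- habitat_availability(fx$habitat, fx$water, 1500)
  on_land <- fx$water$values == 0
  expect_true(all(is.na(a$values[on_land])))
  vals <- a$values[!on_land]
  expect_false(anyNA(vals))
  expect_true(all(vals >= 0 & vals <= 1))
})

test_that("adding a habitat cell never decreases availability anywhere", {
  fx <- random_habitat_fixture(n = 32, seed = 3, p_hab = 0.2)
  base <- habitat_availability(fx$habitat, fx$water, 1500)
  empty_water <- which(fx$habitat$values == 0)
  set.seed(11)
  for (cell in sample(empty_water, 5)) {
    hab2 <- fx$habitat
    hab2$values[cell] <- 1
    a2 <- habitat_availability(hab2, fx$water, 1500)
    expect_true(all(a2$values >= base$values, na.rm = TRUE))
  }
})

test_that("habitat on land is refused and shape mismatch is an error", {
  w <- raster_grid(matrix(c(0, rep(1, 15)), 4, 4), 250)
  h <- raster_grid(matrix(1, 4, 4), 250)
  expect_error(habitat_availability(h, w, 500), "habitat cells fall on land")
  expect_error(habitat_availability(raster_grid(matrix(0, 3, 3), 250), w, 500),
               "differ in shape")
})

test_that("migration radius changes smoothing scale, not map-wide habitat fraction", {
  fx <- random_habitat_fixture(n = 64, seed = 5, p_hab = 0.35)
  a10 <- habitat_availability(fx$habitat, fx$water, 2500)
  a15 <- habitat_availability(fx$habitat, fx$water, 3750)
  hab_frac <- sum(fx$habitat$values == 1, na.rm = TRUE) /
    sum(fx$water$values == 1)
  # both smoothed means sit near the true habitat fraction (edge effects only)
  expect_lt(abs(mean(a10$values, na.rm = TRUE) - hab_frac), 0.03)
  expect_lt(abs(mean(a15$values, na.rm = TRUE) - hab_frac), 0.03)
  # larger radius smooths more: less cell-to-cell spread
  expect_lt(sd(a15$values, na.rm = TRUE), sd(a10$values, na.rm = TRUE))
})
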