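# Shared fixtures and independent oracles.

# Brute-force focal availability: an explicit double loop over cells and
# kernel offsets, counting habitat and water cells within `radius` metres of
# each water-cell centre. Independent of the package's counting path.
brute_force_availability <- function(habitat, water_mask, radius) {
  cs <- habitat$cell_size
  hab <- habitat$values
  water <- !is.na(water_mask$values) & water_mask$values != 0
  r <- floor(radius / cs)
  offs <- expand.grid(di = -r:r, dj = -r:r)
  offs <- offs[sqrt(offs$di^2 + offs$dj^2) * cs <= radius, ]
  nr <- nrow(hab); nc <- ncol(hab)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      if (!water[i, j]) next
      ii <- i + offs$di; jj <- j + offs$dj
      ok <- ii >= 1 & ii <= nr & jj >= 1 & jj <= nc
      idx <- cbind(ii[ok], jj[ok])
      in_water <- water[idx]
      n_w <- sum(in_water)
      n_h <- sum(hab[idx][in_water] == 1, na.rm = TRUE)
      out[i, j] <- n_h / n_w
    }
  }
  raster_grid(out, cs)
}

# Random binary habitat map on a random land mask (land = left strip plus
# scattered blocks), as a (habitat, water) raster pair.
random_habitat_fixture <- function(n = 64, cell_size = 250, p_hab = 0.3,
                                   seed = 1) {
  set.seed(seed)
  water <- matrix(1, n, n)
  strip <- sample.int(max(2, n %/% 6), 1)
  water[, seq_len(strip)] <- 0
  for (b in seq_len(sample.int(4, 1))) {
    i <- sample.int(n - 4, 1); j <- sample.int(n - 4, 1)
    water[i:(i + 3), j:(j + 3)] <- 0
  }
  hab <- matrix(0, n, n)
  hab[water == 1] <- rbinom(sum(water == 1), 1, p_hab)
  hab[water == 0] <- NA_real_
  list(habitat = raster_grid(hab, cell_size),
       water = raster_grid(water, cell_size))
}

demo_config <- function(seed = 1) habitat_gen_config(seed = seed)
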