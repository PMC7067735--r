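#' Eutrophication scenario levels
#'
#' The scenario set used throughout: relative changes in summer Secchi depth
#' of -10% (deterioration), 0% (initial conditions at the onset of the Baltic
#' Sea Action Plan) and five water-clarity improvements (+11, +20, +30, +40,
#' +48%). +11% is the BSAP target level and +48% the reference level for the
#' Baltic Proper.
#'
#' @return Numeric vector of the seven levels (percent Secchi-depth change),
#'   with attributes `target` (11) and `reference` (48).
#' @export
scenario_levels <- function() {
  structure(c(-10, 0, 11, 20, 30, 40, 48), target = 11, reference = 48)
}

#' Synthetic habitat generator configuration
#'
#' Parameters of the synthetic landscape and habitat-map generator. The
#' generator emulates the statistical structure the pipeline assumes:
#' spatially autocorrelated binary recruitment-habitat maps whose prevalence
#' shifts with water clarity — positively for perch (a clear-water species)
#' and negatively for pikeperch (which favours turbid water) — plus three
#' correlated "technique" variants per map standing in for an ensemble of
#' distribution-modelling methods.
#'
#' @param grid_size Cells per side (>= 16).
#' @param cell_size Cell edge length, metres.
#' @param autocorrelation_range Gaussian smoothing range of the latent
#'   habitat field, metres; larger values give larger habitat patches.
#' @param base_prevalence Named vector, expected habitat fraction of water at
#'   the 0% scenario per species; each in (0, 1).
#' @param secchi_response Named vector, shift in habitat log-odds per unit
#'   relative Secchi change (+1 = +100%); must be positive for perch and
#'   negative for pikeperch.
#' @param technique_noise Standard deviation of the independent perturbation
#'   field added per technique before re-thresholding (0 = identical
#'   techniques).
#' @param techniques Labels of the ensemble members.
#' @param seed Integer master seed; every generated object derives its own
#'   stream from it by hashing labels, so adding a scenario or technique does
#'   not change the others.
#' @return An object of class `habitat_gen_config`.
#' @export
habitat_gen_config <- function(grid_size = 64,
                               cell_size = 250,
                               autocorrelation_range = 1500,
                               base_prevalence = c(perch = 0.30, pikeperch = 0.15),
                               secchi_response = c(perch = 4, pikeperch = -5),
                               technique_noise = 0.5,
                               techniques = c("gam", "maxent", "rf"),
                               seed = 1L) {
  if (!is.numeric(grid_size) || length(grid_size) != 1L || grid_size < 16)
    stop("`grid_size` must be a single number >= 16", call. = FALSE)
  if (!is.numeric(cell_size) || length(cell_size) != 1L || cell_size <= 0)
    stop("`cell_size` must be positive", call. = FALSE)
  if (autocorrelation_range <= 0)
    stop("`autocorrelation_range` must be positive", call. = FALSE)
  if (is.null(names(base_prevalence)) || is.null(names(secchi_response)) ||
      !setequal(names(base_prevalence), names(secchi_response)))
    stop("`base_prevalence` and `secchi_response` must be named by the same species",
         call. = FALSE)
  if (any(base_prevalence <= 0 | base_prevalence >= 1))
    stop("`base_prevalence` values must lie strictly in (0, 1)", call. = FALSE)
  if (!is.na(secchi_response["perch"]) && secchi_response[["perch"]] <= 0)
    stop("perch `secchi_response` must be positive (clear-water species)",
         call. = FALSE)
  if (!is.na(secchi_response["pikeperch"]) && secchi_response[["pikeperch"]] >= 0)
    stop("pikeperch `secchi_response` must be negative (turbid-water species)",
         call. = FALSE)
  if (technique_noise < 0)
    stop("`technique_noise` must be non-negative", call. = FALSE)
  structure(list(grid_size = as.integer(grid_size), cell_size = cell_size,
                 autocorrelation_range = autocorrelation_range,
                 base_prevalence = base_prevalence,
                 secchi_response = secchi_response,
                 technique_noise = technique_noise,
                 techniques = techniques,
                 seed = as.integer(seed)),
            class = "habitat_gen_config")
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed from a master seed and a label path: polynomial
# rolling hash of the labels modulo 2^31 - 1, folded with the master seed.
# Keeps independent streams per (species, scenario, technique).
split_seed <- function(seed, ...) {
  labels <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  M <- 2147483647
  h <- as.numeric(seed) %% M
  for (code in utf8ToInt(labels)) h <- (h * 131 + code) %% M
  as.integer(h)
}

# Standardized Gaussian random field on a torus: white noise smoothed with a
# periodic Gaussian kernel (sd = range/cell_size cells) via FFT, then scaled
# to zero mean and unit variance. Draws its own stream from `seed`.
gaussian_field <- function(nr, nc, range_cells, seed) {
  with_seed(seed, {
    w <- matrix(stats::rnorm(nr * nc), nr, nc)
    di <- pmin(0:(nr - 1), nr - 0:(nr - 1))
    dj <- pmin(0:(nc - 1), nc - 0:(nc - 1))
    k <- exp(-outer(di^2, dj^2, "+") / (2 * range_cells^2))
    f <- Re(stats::fft(stats::fft(w) * stats::fft(k), inverse = TRUE)) / (nr * nc)
    (f - mean(f)) / stats::sd(f)
  })
}

#' Generate a synthetic coastal landscape
#'
#' Builds a schematic archipelago-margin landscape: a connected land strip of
#' varying width along the western grid edge, water elsewhere, a depth field
#' that deepens on average with distance from land (roughly 0.5-25 m, so a
#' 10 m coastal depth limit is binding), and a smooth baseline Secchi-depth
#' field around 4 m. All fields are deterministic for a fixed seed.
#'
#' @param config A [habitat_gen_config()].
#' @return An object of class `landscape` with [raster_grid()] elements
#'   `water_mask` (1 = water, 0 = land), `depth` (m, `NA` on land) and
#'   `secchi_base` (m, `NA` on land), plus the `config` used.
#' @export
generate_landscape <- function(config) {
  if (!inherits(config, "habitat_gen_config"))
    stop("`config` must be a habitat_gen_config", call. = FALSE)
  n <- config$grid_size
  cs <- config$cell_size
  rng_cells <- config$autocorrelation_range / cs

  # coastline: smoothly varying land-strip width along the west edge
  coast <- with_seed(split_seed(config$seed, "coast"), {
    raw <- stats::rnorm(n)
    sm <- stats::filter(rep(raw, 3), rep(1 / 9, 9), circular = TRUE)[(n + 1):(2 * n)]
    w0 <- round(0.12 * n)
    pmin(pmax(round(w0 + 0.06 * n * as.numeric(sm)), 1L), round(0.3 * n))
  })
  water <- matrix(1, n, n)
  for (i in seq_len(n)) water[i, seq_len(coast[i])] <- 0
  wf <- mean(water)
  if (wf < 0.5 || wf > 0.95)
    stop(sprintf("generated water fraction %.2f outside [0.5, 0.95]", wf),
         call. = FALSE)

  # distance of each cell to the nearest land cell, metres (exact, chunked)
  land_idx <- which(water == 0, arr.ind = TRUE)
  all_idx <- which(water >= 0, arr.ind = TRUE)
  dist_m <- matrix(0, n, n)
  chunk <- 2048L
  for (s in seq(1L, nrow(all_idx), by = chunk)) {
    e <- min(s + chunk - 1L, nrow(all_idx))
    blk <- all_idx[s:e, , drop = FALSE]
    d2 <- outer(blk[, 1], land_idx[, 1], "-")^2 +
      outer(blk[, 2], land_idx[, 2], "-")^2
    dist_m[blk] <- sqrt(apply(d2, 1L, min)) * cs
  }
  max_d <- max(dist_m)

  depth_noise <- gaussian_field(n, n, rng_cells,
                                split_seed(config$seed, "depth"))
  depth <- pmax(1 + 22 * dist_m / max_d + 2 * depth_noise, 0.3)
  depth[water == 0] <- NA_real_

  secchi_noise <- gaussian_field(n, n, rng_cells,
                                 split_seed(config$seed, "secchi"))
  secchi <- pmax(4 + 1.5 * secchi_noise, 0.5)
  secchi[water == 0] <- NA_real_

  structure(list(water_mask = raster_grid(water, cs),
                 depth = raster_grid(depth, cs),
                 secchi_base = raster_grid(secchi, cs),
                 config = config),
            class = "landscape")
}

#' @export
print.landscape <- function(x, ...) {
  cat(sprintf("<landscape> %d x %d cells, %.0f%% water, depth %.1f-%.1f m\n",
              nrow(x$water_mask$values), ncol(x$water_mask$values),
              100 * mean(x$water_mask$values),
              min(x$depth$values, na.rm = TRUE),
              max(x$depth$values, na.rm = TRUE)))
  invisible(x)
}

#' Generate a binary recruitment-habitat map
#'
#' Draws one member of the synthetic habitat-map set for a (species,
#' scenario, technique) combination. A latent Gaussian random field shared by
#' all techniques of a species is perturbed by an independent technique field
#' (sd = `technique_noise`), rescaled to unit variance, and thresholded so
#' that the expected habitat prevalence over water equals
#' `plogis(qlogis(base_prevalence) + secchi_response * secchi_change/100)` —
#' the scenario shifts prevalence through the log-odds, not the spatial
#' pattern. Habitat is restricted to water; land is nodata.
#'
#' @param landscape A [generate_landscape()] result.
#' @param species Species label, one of `names(config$base_prevalence)`.
#' @param scenario Secchi-depth change in percent, one of [scenario_levels()]
#'   (or the configured set).
#' @param technique Ensemble-member label, one of `config$techniques`.
#' @param config A [habitat_gen_config()]; defaults to the landscape's own.
#' @return Binary [raster_grid()] (1 habitat, 0 water non-habitat, `NA`
#'   land) with elements `species`, `scenario`, `technique` attached.
#' @export
generate_habitat_map <- function(landscape, species, scenario, technique,
                                 config = landscape$config) {
  if (!inherits(landscape, "landscape"))
    stop("`landscape` must come from generate_landscape()", call. = FALSE)
  if (!species %in% names(config$base_prevalence))
    stop("unknown species '", species, "'; configured: ",
         paste(names(config$base_prevalence), collapse = ", "), call. = FALSE)
  if (!technique %in% config$techniques)
    stop("unknown technique '", technique, "'; configured: ",
         paste(config$techniques, collapse = ", "), call. = FALSE)
  if (!scenario %in% scenario_levels())
    stop("unknown scenario level ", scenario, "; configured: ",
         paste(scenario_levels(), collapse = ", "), call. = FALSE)

  n <- config$grid_size
  rng_cells <- config$autocorrelation_range / config$cell_size
  p <- stats::plogis(stats::qlogis(config$base_prevalence[[species]]) +
                       config$secchi_response[[species]] * scenario / 100)

  z <- gaussian_field(n, n, rng_cells,
                      split_seed(config$seed, "latent", species))
  tn <- config$technique_noise
  if (tn > 0) {
    eps <- gaussian_field(n, n, rng_cells,
                          split_seed(config$seed, "tech", species, scenario,
                                     technique))
    z <- (z + tn * eps) / sqrt(1 + tn^2)
  }
  hab <- ifelse(z < stats::qnorm(p), 1, 0)
  hab[landscape$water_mask$values == 0] <- NA_real_
  out <- raster_grid(hab, config$cell_size)
  out$species <- species
  out$scenario <- scenario
  out$technique <- technique
  out
}

#' Generate synthetic monitoring observations
#'
#' Samples monitoring sites uniformly at random among valid (non-nodata)
#' cells of a predicted CPUE map and attaches observed CPUE values: the map
#' value plus Gaussian noise, truncated at zero. This emulates standardized
#' gillnet monitoring catches used to validate predicted CPUE.
#'
#' @param cpue_map A [raster_grid()] of predicted CPUE.
#' @param n_sites Number of sites (>= 3, at most the number of valid cells).
#' @param noise_sd Observation noise standard deviation, CPUE units.
#' @param seed Integer seed; output is deterministic given it.
#' @return A data.frame with columns `site_id`, `row`, `col`,
#'   `observed_cpue`.
#' @export
generate_monitoring <- function(cpue_map, n_sites, noise_sd, seed) {
  if (!is_raster_grid(cpue_map))
    stop("`cpue_map` must be a raster_grid", call. = FALSE)
  if (n_sites < 3) stop("`n_sites` must be at least 3", call. = FALSE)
  if (noise_sd < 0) stop("`noise_sd` must be non-negative", call. = FALSE)
  valid <- which(!is.na(cpue_map$values))
  if (n_sites > length(valid))
    stop(sprintf("n_sites (%d) exceeds the %d valid water cells", n_sites,
                 length(valid)), call. = FALSE)
  with_seed(seed, {
    cells <- sample(valid, n_sites)
    rc <- arrayInd(cells, dim(cpue_map$values))
    obs <- pmax(0, cpue_map$values[cells] + stats::rnorm(n_sites, 0, noise_sd))
    data.frame(site_id = sprintf("site_%03d", seq_len(n_sites)),
               row = rc[, 1], col = rc[, 2], observed_cpue = obs)
  })
}
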