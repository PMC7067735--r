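#' Habitat productivity functions and species parameters
#'
#' A habitat productivity function (HPF) is the empirical log-linear relation
#' between habitat availability `x` (proportion of water within the migration
#' distance that is recruitment habitat) and the expected adult
#' catch-per-unit-effort in standardized gillnets:
#' `CPUE = a * ln(x + c) + b`, clamped below at zero. The published fits are
#' `CPUE = 2.03 ln(x) + 9.39` for perch (> 20 cm) and
#' `CPUE = 0.05 ln(x + 0.02) + 0.21` for pikeperch (> 30 cm).
#'
#' @param slope Slope `a` in CPUE per ln-unit.
#' @param intercept Intercept `b` in CPUE units.
#' @param offset Dimensionless offset `c` added to `x` inside the logarithm
#'   (0 for perch, 0.02 for pikeperch); must be non-negative.
#' @param slope_se,intercept_se Standard errors of the coefficients.
#' @param n,p,r2 Fit statistics of the original regression, kept as metadata.
#' @return An object of class `productivity_function`.
#' @export
productivity_function <- function(slope, intercept, offset = 0,
                                  slope_se = NA_real_, intercept_se = NA_real_,
                                  n = NA_integer_, p = NA_real_, r2 = NA_real_) {
  if (offset < 0) stop("`offset` must be non-negative", call. = FALSE)
  structure(list(slope = slope, intercept = intercept, offset = offset,
                 slope_se = slope_se, intercept_se = intercept_se,
                 n = n, p = p, r2 = r2),
            class = "productivity_function")
}

#' @export
print.productivity_function <- function(x, ...) {
  cat(sprintf("<productivity_function> CPUE = %g * ln(x%s) + %g\n",
              x$slope, if (x$offset > 0) sprintf(" + %g", x$offset) else "",
              x$intercept))
  invisible(x)
}

#' Per-species parameter sets
#'
#' Bundles the constants the pipeline needs per species: migration distance,
#' length cutoff of the "large fish" class, mean individual weight, the depth
#' limit within which the species is assessed (perch is coastal and only
#' evaluated at 0-10 m; pikeperch has no limit), the habitat productivity
#' function, the linear CPUE-to-biomass factor `k` (kg/ha per CPUE unit), and
#' the proportion `p` that the > cutoff length class makes up of all > 10 cm
#' biomass (used to expand biomass to the > 10 cm class).
#'
#' `species_defaults()` returns the published parameterization for
#' `"perch"` or `"pikeperch"`; the biomass factors default to the ratio of
#' the published study-area mean biomass to mean CPUE (9.4/5.4 for perch,
#' 0.65/0.16 for pikeperch), and the length proportions to the published
#' biomass pairs (9.4 -> 16 and 0.65 -> 1.5 kg/ha).
#'
#' @param species Species label.
#' @param migration_distance Migration distance in metres.
#' @param length_cutoff Lower length bound of the assessed class, cm.
#' @param mean_weight Mean individual weight, kg.
#' @param depth_limit Depth limit in metres (`Inf` for none).
#' @param hpf A [productivity_function()].
#' @param biomass_factor Linear factor `k`, (kg/ha) per CPUE unit.
#' @param length_proportion Fraction of > 10 cm biomass in the > cutoff
#'   class, in (0, 1]; `NA` if unused.
#' @return An object of class `species_params`.
#' @examples
#' sp <- species_defaults("perch")
#' sp$hpf
#' @export
species_params <- function(species, migration_distance, length_cutoff,
                           mean_weight, depth_limit, hpf, biomass_factor,
                           length_proportion = NA_real_) {
  stopifnot(migration_distance > 0, length_cutoff > 0, mean_weight > 0,
            depth_limit > 0)
  if (biomass_factor <= 0)
    stop("`biomass_factor` must be positive", call. = FALSE)
  if (!is.na(length_proportion) &&
      (length_proportion <= 0 || length_proportion > 1))
    stop("`length_proportion` must be in (0, 1]", call. = FALSE)
  if (!inherits(hpf, "productivity_function"))
    stop("`hpf` must be a productivity_function", call. = FALSE)
  structure(list(species = species, migration_distance = migration_distance,
                 length_cutoff = length_cutoff, mean_weight = mean_weight,
                 depth_limit = depth_limit, hpf = hpf,
                 biomass_factor = biomass_factor,
                 length_proportion = length_proportion),
            class = "species_params")
}

#' @rdname species_params
#' @export
species_defaults <- function(species = c("perch", "pikeperch")) {
  species <- match.arg(species)
  if (species == "perch") {
    species_params(
      "perch",
      migration_distance = 10000, length_cutoff = 20, mean_weight = 0.23,
      depth_limit = 10,
      hpf = productivity_function(2.03, 9.39, offset = 0,
                                  slope_se = 0.69, intercept_se = 1.27,
                                  n = 12L, p = 0.015, r2 = 0.46),
      biomass_factor = 9.4 / 5.4,
      length_proportion = 9.4 / 16)
  } else {
    species_params(
      "pikeperch",
      migration_distance = 15000, length_cutoff = 30, mean_weight = 0.51,
      depth_limit = Inf,
      hpf = productivity_function(0.05, 0.21, offset = 0.02,
                                  slope_se = 0.02, intercept_se = 0.04,
                                  n = 12L, p = 0.013, r2 = 0.48),
      biomass_factor = 0.65 / 0.16,
      length_proportion = 0.65 / 1.5)
  }
}

#' Evaluate a habitat productivity function
#'
#' Computes `CPUE = max(0, a * ln(x + c) + b)` elementwise. The clamp keeps
#' CPUE physically meaningful where the log-linear fit would go negative: for
#' perch (`c = 0`) the raw value is negative exactly when
#' `x < exp(-b/a) = exp(-9.39/2.03)`, about 0.0098, and `x = 0` maps to 0.
#' The function is continuous and monotone non-decreasing in `x` on `[0, 1]`.
#'
#' @param x Habitat availability, in `[0, 1]`; scalar, vector, matrix or
#'   [raster_grid()] (`NA` passes through as `NA`).
#' @param f A [productivity_function()].
#' @return CPUE in fish per net per night, same shape as `x`.
#' @examples
#' hpf_cpue(1, species_defaults("perch")$hpf)      # 9.39
#' hpf_cpue(0.98, species_defaults("pikeperch")$hpf) # 0.21
#' @export
hpf_cpue <- function(x, f) {
  if (!inherits(f, "productivity_function"))
    stop("`f` must be a productivity_function", call. = FALSE)
  if (is_raster_grid(x)) {
    out <- x
    out$values <- hpf_cpue(x$values, f)
    return(out)
  }
  if (any(x < 0 | x > 1, na.rm = TRUE))
    stop("habitat availability `x` must lie in [0, 1]", call. = FALSE)
  raw <- f$slope * log(x + f$offset) + f$intercept
  pmax(raw, 0)  # matrix first: pmax keeps the dims of its first argument
}

#' Convert CPUE to biomass density
#'
#' Applies the per-species linear conversion `biomass = k * CPUE` from
#' gillnet CPUE (fish per net per night) to biomass density (kg per hectare).
#' The factor `k` is a calibratable species parameter (see
#' [species_defaults()]); the conversion is linear and homogeneous, so zero
#' CPUE maps to zero biomass and biomass maps are scalar multiples of CPUE
#' maps.
#'
#' @param cpue Non-negative CPUE; scalar, vector, matrix or [raster_grid()].
#' @param sp A [species_params()] (its `biomass_factor` is used).
#' @return Biomass density in kg/ha, same shape as `cpue`.
#' @export
cpue_to_biomass <- function(cpue, sp) {
  if (!inherits(sp, "species_params"))
    stop("`sp` must be a species_params object", call. = FALSE)
  if (is_raster_grid(cpue)) {
    out <- cpue
    out$values <- cpue_to_biomass(cpue$values, sp)
    return(out)
  }
  if (any(cpue < 0, na.rm = TRUE))
    stop("`cpue` must be non-negative", call. = FALSE)
  sp$biomass_factor * cpue
}

#' Expand biomass of the large length class to all fish > 10 cm
#'
#' Monitoring length-frequency distributions give the proportion `p` of
#' > 10 cm biomass that sits in the assessed large class (> 20 cm perch,
#' > 30 cm pikeperch). Dividing by `p` expands the large-class biomass to the
#' > 10 cm class, which is the scale on which independent biomass estimates
#' are usually reported.
#'
#' @param biomass_gt_cutoff Biomass of the large class, kg/ha.
#' @param p Length proportion in (0, 1].
#' @return Biomass of fish > 10 cm, kg/ha.
#' @examples
#' length_class_expand(9.4, 9.4 / 16)  # 16 kg/ha
#' @export
length_class_expand <- function(biomass_gt_cutoff, p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p > 1)
    stop("`p` must be a single value in (0, 1]", call. = FALSE)
  biomass_gt_cutoff / p
}

#' Mask cells beyond a species' depth limit
#'
#' Perch is primarily coastal (0-10 m), so all perch maps and summaries are
#' restricted to cells no deeper than the species' `depth_limit`; cells
#' deeper than the limit become nodata. Species without a limit
#' (`depth_limit = Inf`, e.g. pikeperch) pass through unchanged.
#'
#' @param grid A [raster_grid()] (CPUE or biomass map).
#' @param depth [raster_grid()] of water depth in metres (positive down).
#' @param sp A [species_params()].
#' @return The masked [raster_grid()].
#' @export
apply_depth_mask <- function(grid, depth, sp) {
  if (!inherits(sp, "species_params"))
    stop("`sp` must be a species_params object", call. = FALSE)
  if (is.infinite(sp$depth_limit)) return(grid)
  check_congruent(grid, depth, c("grid", "depth"))
  out <- grid
  too_deep <- !is.na(depth$values) & depth$values > sp$depth_limit
  out$values[too_deep] <- NA_real_
  out
}
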