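#' Ensemble of modelling techniques
#'
#' Combines the congruent biomass (or CPUE) maps of the modelling-technique
#' ensemble into a cellwise mean map and a cellwise uncertainty map. The
#' uncertainty is 1 standard error across techniques: sample standard
#' deviation (n - 1 denominator) divided by `sqrt(n)`; set `se = FALSE` for
#' the plain sample SD. A cell is nodata in both outputs if any member is
#' nodata there.
#'
#' @param maps List of >= 2 congruent [raster_grid()]s (normally the 3
#'   techniques of one species x scenario).
#' @param se If `TRUE` (default) return SD/sqrt(n); otherwise the sample SD.
#' @return List with [raster_grid()] elements `mean` and `se`.
#' @examples
#' g <- function(v) raster_grid(matrix(v, 2, 2), 250)
#' e <- technique_ensemble(list(g(1), g(2), g(3)))
#' e$mean$values[1, 1]  # 2
#' e$se$values[1, 1]    # 1/sqrt(3)
#' @export
technique_ensemble <- function(maps, se = TRUE) {
  if (!is.list(maps) || length(maps) < 2L)
    stop("`maps` must be a list of at least 2 raster_grid objects", call. = FALSE)
  for (i in seq_along(maps)[-1])
    check_congruent(maps[[1]], maps[[i]], c("maps[[1]]", sprintf("maps[[%d]]", i)))
  arr <- vapply(maps, function(g) g$values, maps[[1]]$values)
  any_na <- apply(is.na(arr), c(1, 2), any)
  mu <- apply(arr, c(1, 2), mean)
  sdv <- apply(arr, c(1, 2), stats::sd)
  if (se) sdv <- sdv / sqrt(length(maps))
  mu[any_na] <- NA_real_
  sdv[any_na] <- NA_real_
  list(mean = raster_grid(mu, maps[[1]]$cell_size),
       se = raster_grid(sdv, maps[[1]]$cell_size))
}

#' Study-area biomass summary
#'
#' Averages a biomass map over its valid cells (water, and within the
#' species' depth limit once [apply_depth_mask()] has been applied) and
#' scales up to the total standing biomass of the study area: the mean
#' density times the valid water area, with each cell contributing
#' `cell_size^2 / 10000` hectares.
#'
#' @param grid A [raster_grid()] of biomass density, kg/ha (already masked to
#'   the valid domain).
#' @param species,scenario Labels carried into the output row.
#' @return One-row data.frame: `species`, `scenario`, `mean_kg_ha`,
#'   `total_kg`, `n_cells`, `area_ha`.
#' @export
area_summary <- function(grid, species = NA_character_, scenario = NA_real_) {
  if (!is_raster_grid(grid)) stop("`grid` must be a raster_grid", call. = FALSE)
  valid <- !is.na(grid$values)
  n <- sum(valid)
  if (n == 0L) stop("no valid cells to summarize", call. = FALSE)
  cell_ha <- grid$cell_size^2 / 1e4
  mu <- mean(grid$values[valid])
  data.frame(species = species, scenario = scenario,
             mean_kg_ha = mu, total_kg = mu * n * cell_ha,
             n_cells = n, area_ha = n * cell_ha)
}

#' Relative change of a scenario against the initial condition
#'
#' `100 * (scenario - baseline) / baseline`, the quantity plotted as percent
#' change in biomass per scenario. Both arguments are mean densities (or any
#' positive summaries on a common scale).
#'
#' @param scenario_mean Scenario mean biomass density.
#' @param baseline_mean Baseline (0% scenario) mean biomass density; must be
#'   non-zero.
#' @return Percent change (positive = increase).
#' @export
relative_change <- function(scenario_mean, baseline_mean) {
  if (any(baseline_mean == 0))
    stop("baseline mean is zero; relative change undefined", call. = FALSE)
  100 * (scenario_mean - baseline_mean) / baseline_mean
}

#' Scenario summary table across an ensemble
#'
#' For one species, reduces the per-technique biomass maps of every scenario
#' to a summary row: the across-technique mean and 1 SE of the area-mean
#' density, the total standing biomass, and the relative change of the
#' ensemble-mean density against the 0% baseline (mean first, then ratio).
#'
#' @param maps_by_scenario Named list: one element per scenario level, each a
#'   list of congruent per-technique biomass [raster_grid()]s (masked to the
#'   species' valid domain).
#' @param species Species label for the output.
#' @return data.frame with one row per scenario: `species`, `scenario`,
#'   `mean_kg_ha`, `se_kg_ha`, `total_kg`, `rel_change_pct`.
#' @export
scenario_summary <- function(maps_by_scenario, species = NA_character_) {
  levels <- as.numeric(names(maps_by_scenario))
  if (!0 %in% levels)
    stop("scenario set must contain the 0% baseline", call. = FALSE)
  rows <- lapply(seq_along(maps_by_scenario), function(i) {
    maps <- maps_by_scenario[[i]]
    per_tech <- vapply(maps, function(g) area_summary(g)$mean_kg_ha, numeric(1))
    ens <- technique_ensemble(maps)
    s <- area_summary(ens$mean, species = species, scenario = levels[i])
    data.frame(species = species, scenario = levels[i],
               mean_kg_ha = s$mean_kg_ha,
               se_kg_ha = stats::sd(per_tech) / sqrt(length(per_tech)),
               total_kg = s$total_kg)
  })
  out <- do.call(rbind, rows)
  base <- out$mean_kg_ha[out$scenario == 0]
  out$rel_change_pct <- relative_change(out$mean_kg_ha, base)
  out[order(out$scenario), , drop = FALSE]
}
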