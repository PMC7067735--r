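#' Read and write pipeline tables
#'
#' Thin CSV wrappers used for every table the pipeline emits (monitoring
#' observations, scenario summaries): plain `utils::read.csv` /
#' `utils::write.csv` without row names, so the files round-trip with their
#' header schema intact.
#'
#' @param x data.frame to write.
#' @param path CSV file path.
#' @return `read_table` returns a data.frame; `write_table` returns `path`
#'   invisibly.
#' @export
read_table <- function(path) utils::read.csv(path, stringsAsFactors = FALSE)

#' @rdname read_table
#' @export
write_table <- function(x, path) {
  utils::write.csv(x, path, row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Builds and validates the configuration of an end-to-end run, either from a
#' YAML file or from a named list. Unspecified fields fall back to the
#' shipped defaults (`inst/extdata/reference_defaults.yaml`), which carry the
#' published parameterization. Validation fails with a message naming the
#' offending field; in particular the scenario list must contain the 0%
#' baseline and every species needs parameters.
#'
#' @param config Path to a YAML file, or a named list with any of the fields
#'   `synthetic` (arguments of [habitat_gen_config()]), `monitoring`
#'   (`n_sites`, `noise_sd`), `scenarios`, `valuation_scenario`, `species`,
#'   `econ` (arguments of [econ_params()]), `rounding`, `seed`.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(config = list()) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  if (!is.list(config)) stop("`config` must be a list or a YAML path", call. = FALSE)
  defaults <- yaml::read_yaml(system.file("extdata", "reference_defaults.yaml",
                                          package = "habfish"))
  merge2 <- function(base, over) {
    for (nm in names(over))
      base[[nm]] <- if (is.list(base[[nm]]) && is.list(over[[nm]]))
        merge2(base[[nm]], over[[nm]]) else over[[nm]]
    base
  }
  cfg <- merge2(defaults, config)

  if (!0 %in% unlist(cfg$scenarios))
    stop("config field `scenarios` must contain the 0% baseline scenario",
         call. = FALSE)
  if (length(cfg$species) == 0L)
    stop("config field `species` must list at least one species", call. = FALSE)
  known <- c("perch", "pikeperch")
  if (!all(unlist(cfg$species) %in% known))
    stop("config field `species` contains unknown species: ",
         paste(setdiff(unlist(cfg$species), known), collapse = ", "),
         call. = FALSE)
  if (!cfg$valuation_scenario %in% unlist(cfg$scenarios))
    stop("config field `valuation_scenario` must be one of `scenarios`",
         call. = FALSE)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L)
    stop("config field `seed` must be a single integer", call. = FALSE)
  cfg$scenarios <- as.numeric(unlist(cfg$scenarios))
  cfg$species <- as.character(unlist(cfg$species))
  structure(cfg, class = "pipeline_config")
}

# Species parameter objects for the configured species, applying any
# per-species overrides from the config's `species_params` block.
config_species <- function(cfg) {
  out <- lapply(cfg$species, function(s) {
    sp <- species_defaults(s)
    over <- cfg$species_params[[s]]
    for (nm in intersect(names(over),
                         c("migration_distance", "biomass_factor",
                           "depth_limit", "length_proportion", "mean_weight")))
      sp[[nm]] <- over[[nm]]
    sp
  })
  stats::setNames(out, cfg$species)
}

# Econ parameter object from the config's `econ` block.
config_econ <- function(cfg) {
  e <- cfg$econ
  econ_params(wtp_eur = unlist(e$wtp_eur),
              wtp_sek_2002 = unlist(e$wtp_sek_2002),
              wpue_baseline = unlist(e$wpue_baseline),
              fx = e$fx,
              effort = unlist(e$effort),
              effort_ci95 = unlist(e$effort_ci95))
}

#' Run the full scenario pipeline
#'
#' Executes the whole chain on a synthetic landscape: landscape generation,
#' per (species, scenario, technique) habitat maps, focal habitat
#' availability within the species' migration distance, CPUE via the habitat
#' productivity functions, biomass conversion and depth masking, technique
#' ensembles (mean and 1-SE maps), study-area scenario summaries with
#' relative changes, validation of predicted against synthetic monitoring
#' CPUE at the 0% scenario, and the willingness-to-pay valuation at the
#' configured valuation scenario. All rasters are written as ASCII grids,
#' tables as CSV and reports as JSON under `out_dir`, and every output file
#' is listed in the returned manifest with its MD5 checksum; a fixed seed
#' gives bit-identical outputs. Files already present are only rewritten
#' when `overwrite = TRUE` (the default); stage results are always
#' recomputed in memory.
#'
#' @param config A [pipeline_config()], or anything it accepts.
#' @param out_dir Output directory (created if missing).
#' @param overwrite Rewrite existing output files?
#' @return Invisibly, a list with `manifest` (data.frame `path`, `md5`),
#'   `summary` (scenario summary table), `validation` (per-species
#'   [fit_obs_vs_pred()] results) and `valuation` (the [value_chain()]
#'   result).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("habfish_run_"),
                         overwrite = TRUE) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit_raster <- function(grid, name) {
    p <- file.path(out_dir, name)
    if (overwrite || !file.exists(p)) write_raster(grid, p)
    paths[[length(paths) + 1L]] <<- p
  }
  emit_text <- function(writer, name) {
    p <- file.path(out_dir, name)
    if (overwrite || !file.exists(p)) writer(p)
    paths[[length(paths) + 1L]] <<- p
  }

  gen_cfg <- do.call(habitat_gen_config,
                     c(lapply(cfg$synthetic, function(x)
                       if (is.list(x)) unlist(x) else x),
                       list(seed = as.integer(cfg$seed))))
  species <- config_species(cfg)

  message("[habfish] generating landscape (", gen_cfg$grid_size, "x",
          gen_cfg$grid_size, " cells)")
  ls <- generate_landscape(gen_cfg)
  emit_raster(ls$water_mask, "water_mask.asc")
  emit_raster(ls$depth, "depth.asc")
  emit_raster(ls$secchi_base, "secchi_base.asc")
  n_water <- sum(ls$water_mask$values == 1)
  message("[habfish] water cells: ", n_water, " of ",
          length(ls$water_mask$values))

  summaries <- list()
  validations <- list()
  cpue0_mean <- list()
  for (s in cfg$species) {
    sp <- species[[s]]
    by_scenario <- list()
    for (sc in cfg$scenarios) {
      biomass_maps <- list()
      cpue_maps <- list()
      for (tech in gen_cfg$techniques) {
        tag <- sprintf("%s_sc%+03d_%s", s, sc, tech)
        hab <- generate_habitat_map(ls, s, sc, tech, gen_cfg)
        emit_raster(hab, sprintf("habitat_%s.asc", tag))
        avail <- habitat_availability(hab, ls$water_mask, sp$migration_distance)
        emit_raster(avail, sprintf("availability_%s.asc", tag))
        cpue <- apply_depth_mask(hpf_cpue(avail, sp$hpf), ls$depth, sp)
        emit_raster(cpue, sprintf("cpue_%s.asc", tag))
        biomass_maps[[tech]] <- cpue_to_biomass(cpue, sp)
        cpue_maps[[tech]] <- cpue
      }
      ens <- technique_ensemble(biomass_maps)
      emit_raster(ens$mean, sprintf("biomass_mean_%s_sc%+03d.asc", s, sc))
      emit_raster(ens$se, sprintf("biomass_se_%s_sc%+03d.asc", s, sc))
      by_scenario[[as.character(sc)]] <- biomass_maps
      if (sc == 0)
        cpue0_mean[[s]] <- technique_ensemble(cpue_maps)$mean
    }
    summaries[[s]] <- scenario_summary(by_scenario, species = s)
    message(sprintf("[habfish] %s: baseline mean %.2f kg/ha over %d scenarios",
                    s, summaries[[s]]$mean_kg_ha[summaries[[s]]$scenario == 0],
                    length(cfg$scenarios)))

    ns <- cfg$monitoring$noise_sd
    if (is.list(ns) || length(ns) > 1L) ns <- ns[[s]]
    sites <- generate_monitoring(cpue0_mean[[s]], cfg$monitoring$n_sites, ns,
                                 split_seed(cfg$seed, "monitoring", s))
    emit_text(function(p) write_table(sites, p),
              sprintf("monitoring_%s.csv", s))
    fit <- fit_obs_vs_pred(extract_predictions(cpue0_mean[[s]], sites,
                                               exclude = cfg$validation_exclude[[s]]))
    validations[[s]] <- fit
    emit_text(function(p) jsonlite::write_json(unclass(fit), p,
                                               auto_unbox = TRUE, digits = NA),
              sprintf("validation_%s.json", s))
  }

  summary_tab <- do.call(rbind, summaries)
  rownames(summary_tab) <- NULL
  emit_text(function(p) write_table(
    summary_tab[, c("species", "scenario", "mean_kg_ha", "se_kg_ha",
                    "total_kg", "rel_change_pct")], p),
    "scenario_summary.csv")

  val <- NULL
  if (all(c("perch", "pikeperch") %in% cfg$species)) {
    rel <- vapply(c("perch", "pikeperch"), function(s) {
      tab <- summaries[[s]]
      tab$rel_change_pct[tab$scenario == cfg$valuation_scenario]
    }, numeric(1))
    val <- value_chain(rel, config_econ(cfg), rounding = isTRUE(cfg$rounding))
    emit_text(function(p) jsonlite::write_json(unclass(val), p,
                                               auto_unbox = TRUE, digits = NA),
              "valuation.json")
  }

  emit_text(function(p) yaml::write_yaml(unclass(cfg), p), "config.yaml")
  manifest <- data.frame(path = basename(paths),
                         md5 = unname(tools::md5sum(paths)))
  write_table(manifest, file.path(out_dir, "manifest.csv"))
  message("[habfish] wrote ", nrow(manifest), " files to ", out_dir)
  invisible(list(manifest = manifest, summary = summary_tab,
                 validation = validations, valuation = val,
                 out_dir = out_dir))
}
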