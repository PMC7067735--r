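# Default pipeline parameterization: the published constants of the
# habitat-productivity and valuation chain, plus the synthetic-landscape
# settings used by the demo run. Override any field via pipeline_config().
synthetic:
  grid_size: 64
  cell_size: 250
  autocorrelation_range: 1500
  base_prevalence:
    perch: 0.30
    pikeperch: 0.15
  secchi_response:
    perch: 4.0
    pikeperch: -5.0
  technique_noise: 0.5
  techniques: [gam, maxent, rf]
monitoring:
  n_sites: 11          # gillnet monitoring sites in the study area
  noise_sd:            # observation noise, CPUE units, scaled to each
    perch: 1.0         #   species' CPUE range (pikeperch CPUE is ~0.2)
    pikeperch: 0.05
scenarios: [-10, 0, 11, 20, 30, 40, 48]   # % Secchi-depth change
valuation_scenario: 11                    # BSAP target level
species: [perch, pikeperch]
species_params:
  perch:
    migration_distance: 10000   # m; 80% recapture distance
    length_cutoff: 20           # cm
    mean_weight: 0.23           # kg
    depth_limit: 10             # m; coastal 0-10 m
    hpf: {slope: 2.03, slope_se: 0.69, intercept: 9.39, intercept_se: 1.27, offset: 0.0}
    biomass_factor: 1.7407407407407407   # 9.4 kg/ha per 5.4 CPUE
    length_proportion: 0.5875            # >20 cm share of >10 cm biomass (9.4/16)
  pikeperch:
    migration_distance: 15000   # m; 75% recapture distance
    length_cutoff: 30           # cm
    mean_weight: 0.51           # kg
    depth_limit: .inf           # no depth restriction
    hpf: {slope: 0.05, slope_se: 0.02, intercept: 0.21, intercept_se: 0.04, offset: 0.02}
    biomass_factor: 4.0625               # 0.65 kg/ha per 0.16 CPUE
    length_proportion: 0.43333333333333335  # >30 cm share of >10 cm biomass (0.65/1.5)
econ:
  wtp_sek_2002: {perch: 71.6, pikeperch: 153.0}   # SEK per (kg/h), 2002 prices
  wtp_eur: {perch: 8.29, pikeperch: 18.0}         # EUR per (kg/h), 2018 prices
  wpue_baseline: {perch: 0.8, pikeperch: 0.3}     # kg per fishing hour
  fx: 10.2567                                     # SEK per EUR
  effort: {perch: 505000, pikeperch: 83000}       # gear days per year
  effort_ci95: {perch: 124000, pikeperch: 64000}  # 95% CI half-widths
validation_exclude: {}   # optional per-species site_id exclusions
rounding: true           # carry worked-example rounding through the valuation
seed: 1
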