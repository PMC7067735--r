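# habfish

Water clarity is the core indicator used to track eutrophication in the
Baltic Sea, and changing it changes fish habitat. `habfish` traces that chain
quantitatively for two coastal predatory fishes with opposite preferences —
European perch (*Perca fluviatilis*), a clear-water species, and pikeperch
(*Sander lucioperca*), which favours turbid water — from scenarios of
relative Secchi-depth change, through recruitment-habitat maps and habitat
productivity functions, to biomass maps and the economic value of the
recreational fishery. It is aimed at coastal ecologists and
ecosystem-service analysts who want to run or stress-test this kind of
scenario analysis end to end.

## The model

For every water cell the **habitat availability** *x* is the proportion of
water area within the species' typical migration distance (10 km for perch,
15 km for pikeperch) that is predicted recruitment habitat — a moving-window
(focal) statistic in which land and off-grid cells are excluded from both
numerator and denominator. Availability maps to expected adult gillnet catch
per unit effort through empirical **habitat productivity functions**:

    CPUE_perch     = 2.03 ln(x)        + 9.39
    CPUE_pikeperch = 0.05 ln(x + 0.02) + 0.21

clamped below at zero. CPUE converts linearly to biomass density (kg ha⁻¹)
with per-species calibratable factors; perch maps are restricted to 0–10 m
depth. Maps from three distribution-modelling techniques are ensembled
(cellwise mean ± 1 SE), summarized over the study area per scenario, and the
relative biomass change of a scenario feeds the **valuation**: assuming
linearity from biomass to recreational weight-per-unit-effort (WPUE) and
from WPUE to willingness-to-pay (8.29 EUR and 18.0 EUR per kg h⁻¹ for perch
and pikeperch), the species are combined via the effort-preference ratio
(perch is targeted about 6.1 times as often) into a net-benefit index.

A synthetic-data module generates spatially autocorrelated landscapes,
habitat maps whose prevalence responds to water clarity with the right sign
per species, correlated technique variants, and noisy monitoring
observations, so the whole pipeline is testable without external data.

## Worked example

The valuation chain at the water-clarity target level (a +13% perch and
−18% pikeperch biomass change):

```r
library(habfish)
value_chain(c(perch = 13, pikeperch = -18))
#>   perch      biomass +13.0% -> dWPUE +0.10 kg/h -> +0.8 EUR/h
#>   pikeperch  biomass -18.0% -> dWPUE -0.05 kg/h -> -0.9 EUR/h
#>   effort ratio 6.1 (+/- 4.9, 95% CI); net index +3.97 (net benefit)
```

Reading: a 13% perch biomass increase on a 0.8 kg/h WPUE baseline is worth
+0.8 EUR per fishing hour; the 18% pikeperch loss costs 0.9 EUR per hour;
because perch is targeted 6.1 times as often, the effort-weighted net index
is positive — a net benefit of improved water clarity for the recreational
fishery.

The full synthetic demo (64×64 landscape, 2 species × 7 scenarios × 3
techniques = 42 habitat/availability/CPUE map sets, scenario summaries,
validation and valuation reports):

```r
res <- run_pipeline(list(seed = 1), out_dir = "habfish_out")
res$summary   # 14 rows: mean ± SE kg/ha, total kg, % change per scenario
```

Single stages are exported too (`generate_landscape()`,
`habitat_availability()`, `hpf_cpue()`, `technique_ensemble()`,
`fit_obs_vs_pred()`, ...), and `inst/scripts/habfish.R` is a thin
command-line wrapper (`run-all`, `availability`, `value`).

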