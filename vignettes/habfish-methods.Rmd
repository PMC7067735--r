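---
title: "Methods: from water-clarity scenarios to fish biomass and fishery value"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from water-clarity scenarios to fish biomass and fishery value}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habfish)
```

## The inference chain

`habfish` implements a five-stage chain that turns eutrophication-mitigation
scenarios into a statement about recreational-fishery value:

1. **Scenarios.** Seven relative changes in summer Secchi depth:
   −10, 0, +11, +20, +30, +40, +48%. The 0% level is the initial condition;
   +11% and +48% are the water-clarity target and reference levels for the
   Baltic Proper. Scenarios enter only through their effect on
   recruitment-habitat maps.
2. **Habitat availability.** For each water cell, the proportion *x* of
   water area within the species' migration distance that is recruitment
   habitat, computed with a circular focal window (10 km perch, 15 km
   pikeperch, the distances within which ~80% / 75% of tagged fish are
   recaptured).
3. **Habitat productivity.** Empirical log-linear functions map *x* to
   expected adult gillnet CPUE, and a linear factor converts CPUE to biomass
   density; perch is evaluated only at 0–10 m depth.
4. **Ensemble and scenario change.** Maps from three distribution-modelling
   techniques are averaged cellwise with a 1-SE uncertainty map; study-area
   means give a per-scenario summary, and relative change is taken against
   the 0% baseline.
5. **Valuation.** Relative biomass change scales baseline
   weight-per-unit-effort (WPUE), the change is priced with the marginal
   willingness-to-pay per kg h⁻¹, and the two species are combined with the
   perch:pikeperch effort ratio into a net-benefit index.

The underlying species distribution models are deliberately out of scope:
their output maps are inputs here, and the synthetic generator stands in for
them.

## Key assumptions

* **Proportionality through the chain.** Biomass ∝ CPUE (per species), WPUE
  change ∝ biomass change, and value ∝ WPUE change. Every arrow is linear,
  which is what makes the valuation a two-line computation; none of the
  linearities is derived here, all are empirical simplifications.
* **No migration barriers.** The focal window ignores islands and land as
  barriers (no cost distance), so availability can be over- or
  under-estimated very locally. This matters little for study-area means.
* **Technique spread = uncertainty.** The only uncertainty carried through
  the ensemble is the spread across the three modelling techniques
  (1 SE = sd/√3); productivity-function coefficient SEs are reported as
  metadata but not propagated.

## Parameters

| Parameter | Perch | Pikeperch | Units | Notes |
|---|---|---|---|---|
| migration distance | 10 000 | 15 000 | m | focal window radius |
| HPF slope *a* | 2.03 (±0.69) | 0.05 (±0.02) | CPUE per ln-unit | |
| HPF intercept *b* | 9.39 (±1.27) | 0.21 (±0.04) | CPUE | value at x=1 (perch), x=0.98 (pikeperch) |
| HPF offset *c* | 0 | 0.02 | – | keeps ln finite at x=0 |
| length cutoff | >20 | >30 | cm | adult class |
| mean weight | 0.23 | 0.51 | kg | gillnet catch averages |
| depth limit | 10 | none | m | coastal distribution of perch |
| biomass factor *k* | 9.4/5.4 | 0.65/0.16 | (kg ha⁻¹)/CPUE | see below |
| length proportion *p* | 9.4/16 | 0.65/1.5 | – | >cutoff share of >10 cm biomass |
| WTP | 8.29 | 18.0 | EUR per kg h⁻¹ | 2018 prices |
| WPUE baseline | 0.8 | 0.3 | kg h⁻¹ | recreational fishery |
| effort | 505 000 ± 124 000 | 83 000 ± 64 000 | gear days yr⁻¹ | 95% CI |

The internal form of the CPUE-to-biomass conversion is not published, so `k`
is implemented as a single linear factor per species, calibrated so the
study-area mean CPUE values (5.4 perch, 0.16 pikeperch) map onto the mean
biomass densities (9.4 and 0.65 kg ha⁻¹). It is a configuration knob, not a
constant wired into logic. Likewise the 2002 SEK → 2018 EUR deflator is
back-solved from the perch pair (71.6 SEK → 8.29 EUR at 10.2567 SEK/EUR);
the pikeperch pair implies a slightly different factor (it would give 17.7
rather than 18.0 EUR), so both published EUR values are kept as defaults and
the generic `convert_wtp()` is available when a deflator is preferred. All
defaults ship in `inst/extdata/reference_defaults.yaml` and a test pins the file
to the in-code objects.

## Focal statistics: edge and land handling

The availability denominator is *observable water*: land cells and
beyond-edge cells are excluded from both counts, so near coasts and grid
edges the window simply shrinks and *x* remains an unbiased proportion of
the water actually in view. The alternative — treating off-grid cells as
zero-habitat water — would bias *x* downward at edges for no physical
reason.

Counts are exact integers by contract. The default implementation computes
both counts by FFT cross-correlation and rounds to the nearest integer
before dividing, which removes all floating-point drift; a shifted-copy
accumulation (`method = "direct"`) computes the same counts in pure integer
arithmetic. The test suite holds both equal to a per-cell double-loop count
on random masked maps, exactly, not to within tolerance.

## Numerical choices

* **Zero clamp.** The perch HPF diverges to −∞ as x→0; CPUE is clamped at 0,
  which activates exactly below x = exp(−9.39/2.03) ≈ 0.0098. The clamp
  preserves monotonicity and continuity on (0, 1].
* **Ensemble SE.** "1 standard error" across n=3 techniques is sample SD
  (n−1 denominator)/√n; plain SD is available via `se = FALSE`.
* **Order of operations.** Relative change is computed on ensemble-mean area
  summaries (mean first, then ratio), matching the order in which the
  biomass figures and the change figures are derived from one another.
* **Effort-ratio CI.** First-order delta method:
  1.96·r·√((σ₁/E₁)² + (σ₂/E₂)²), σᵢ = CIᵢ/1.96. For the survey inputs this
  gives ±4.92 against the published ±5.0; a Monte-Carlo cross-check in the
  tests confirms the formula where first-order is accurate (small CVs). The
  ratio's heavy right tail at large denominator CV is a known limitation of
  any first-order interval.
* **Reference-rounding mode.** The published worked example carries rounded
  intermediates (ΔWPUE to 2 decimals, EUR to 1 decimal:
  0.8 × 13% = 0.10 → 0.10 × 8.29 = 0.8 EUR). `rounding = TRUE` (default)
  reproduces that arithmetic exactly; full precision
  (0.8 × 0.13 × 8.29 = 0.862) is one flag away. Both are legitimate; they
  answer slightly different questions.
* **Raster serialization.** All maps are read and written as ESRI ASCII
  grids — a plain-text, GIS-readable format whose header carries the cell
  size and nodata sentinel. Values are written at full double precision, so
  round trips are exact and pipeline runs with a fixed seed produce
  bit-identical files (the manifest records MD5 checksums).

## The synthetic-data generator

The generator emulates the *statistical structure* the pipeline assumes, not
any real geography:

* **Landscape.** A land strip of smoothly varying width along one grid edge;
  depth increasing on average with distance from land (≈0.5–25 m, so the
  10 m perch limit binds); a smooth baseline Secchi field around 4 m.
* **Habitat maps.** A latent Gaussian random field (FFT-smoothed white
  noise, autocorrelation range 1500 m) shared by all techniques of a
  species, perturbed per technique by an independent field
  (sd = 0.5, giving ≈0.8 inter-technique correlation), rescaled to unit
  variance and thresholded so expected prevalence over water equals
  plogis(qlogis(p₀) + β·Δsecchi), with base prevalence p₀ = 0.30 (perch) and
  0.15 (pikeperch, concentrated in near-shore bays) and log-odds responses
  β = +4 (perch) and −5 (pikeperch) per unit relative Secchi change. The
  signs encode the species' clear- vs turbid-water preferences; the
  magnitudes are chosen so the −10…+48% scenario range moves prevalence
  substantially without saturating it. Scenarios shift prevalence only —
  no published rule describes spatial re-arrangement, so none is invented.
* **Monitoring.** Sites sampled uniformly over valid cells; observed CPUE =
  map CPUE + Gaussian noise truncated at 0, with noise sd 1.0 (perch) and
  0.05 (pikeperch), commensurate with each species' CPUE scale.
* **Seeding.** One master seed; every object hashes its label path
  (species/scenario/technique) into its own stream, so adding a scenario
  leaves all other maps bit-identical.

What the generator does *not* emulate: real archipelago geometry, island
barriers, spatially varying Secchi responses, inter-annual monitoring
variance, or the behaviour of actual GAM/Maxent/random-forest fits. Passing
tests therefore demonstrate that the machinery is correct and directionally
faithful — increasing clarity raises perch and lowers pikeperch biomass —
not that the synthetic magnitudes match any real study area. The published
headline magnitudes (+37%/−59% at the reference level) depend on the
original, non-distributed model rasters and are intentionally not a test
target.

## Problem sizes

The demo configuration is a 64×64 grid at 250 m cells: large enough that
the 10–15 km focal windows (40–60 cell radii) are genuinely smaller than the
map and availability varies spatially, small enough that the full
2 × 7 × 3 = 42-map pipeline runs in seconds. Validation-recovery simulations
use n = 200 sites over 100 replicate fits. The scaled-down pipeline test
shrinks migration distances with the grid so the focal window keeps spatial
contrast.

## Known limitations

* Availability ignores migration barriers (no cost-distance), as discussed
  above.
* The CPUE-to-biomass step reproduces the published aggregate calibration
  pair but is not the original (unpublished) conversion function.
* Validation regresses observed on predicted CPUE by OLS exactly as the
  evaluation was defined, with no errors-in-variables correction; with few
  sites (n ≈ 11) its power is limited, and the pipeline reports the fit
  rather than asserting it.
* Only technique spread enters the uncertainty bands; coefficient SEs of the
  productivity functions do not.
* The valuation covers these two species and use values only; other species
  (e.g. pike) and non-use values are outside the chain.
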