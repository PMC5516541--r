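---
title: "From heterogeneous age/sex tables to gridded demographic surfaces"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From heterogeneous age/sex tables to gridded demographic surfaces}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agestruct)
```

## The problem

Subnational data on how a population is distributed across age groups and
sexes arrive in wildly different shapes: full census tables (counts or
percentages, 1- to 5-year bins, open top bins anywhere above 65), census
microdata (one row per sampled person, typically 2–15% of the census), and
household surveys (person rows with sampling weights from stratified
two-stage cluster designs, usually under 1% of the population and
representative only at the province / admin-1 level). `agestruct`
harmonises these sources into one per-unit schema, derives dependency
ratios from it, and disaggregates a gridded population-count surface into
5-year age/sex count layers that are cell-aligned with that surface.

The pipeline is:

1. **Standardise** every source into a table with one row per
   administrative unit and fields `MPROP`, `FPROP`, `A0004` … `A65PL`
   (percent), via `rebin_to_schema()` + `counts_to_percentages()` for
   tables, `tabulate_census_microdata()` for census microdata, and
   `tabulate_weighted_survey()` for surveys. A packaged source catalogue
   (`load_catalog()`, `route_entry()`) records which of the four routes each
   of 87 African and Asian countries takes, including nine countries that
   only have a national-level fallback structure.
2. **Dependency ratios** per unit from the standardised proportions
   (`derive_triple()`, `compute_ratios()`).
3. **Grid** the unit attributes onto a template grid by cell-center
   containment (`rasterize_attribute()`), adjust the population surface to
   national reference totals (`adjust_to_national_totals()`), and multiply
   proportion layers into count layers (`disaggregate_age_sex()`).
4. **Validate**: conservation audit (`audit_conservation()`),
   subnational-vs-national comparison (`compare_to_national()`),
   between-round sensitivity differences (`round_difference()`), and an
   end-to-end parameter-recovery harness on synthetic data
   (`recover_parameters()`).

## The quantities

With $pc_{0\text{–}14}$, $pc_{15\text{–}64}$ and $pc_{65+}$ the percentage
of a unit's population in the three broad age groups,

$$\mathrm{YDR} = \frac{pc_{0\text{–}14}}{pc_{15\text{–}64}} \times 100,
\qquad
\mathrm{ODR} = \frac{pc_{65+}}{pc_{15\text{–}64}} \times 100,
\qquad
\mathrm{CDR} = \frac{pc_{0\text{–}14} + pc_{65+}}{pc_{15\text{–}64}} \times 100,$$

so that $\mathrm{CDR} = \mathrm{YDR} + \mathrm{ODR}$ holds exactly; the
package computes CDR as that sum. $pc_{15\text{–}64}$ is taken from the
explicit sum of the ten working-age fields whenever the full 14-field row
is available; the complement $100 - pc_{0\text{–}14} - pc_{65+}$ is used
only for partial rows (it is exact whenever the row sums to 100). Rows that
fail the 100% sum check are still processed with the explicit sum, with a
warning.

Gridded count layers are the cellwise product
$C_g = P_g \times N$, where $P_g$ is the rasterised proportion of age group
$g$ (constant within each unit) and $N$ the population-count surface after
national adjustment. Sex-specific layers multiply further by the unit's male/female
shares, which are applied uniformly across age groups: most sources report
only a single two-way sex split per unit, so a uniform split is the only
choice that keeps countries comparable — and it makes the male and female
stacks re-sum to the age-only stack exactly.

## Grid conventions

All layers live on one `grid_template`: geographic WGS84, square cells
(default 30 arc seconds, i.e. 1/120°), origin at the north-west corner.
Alignment is bit-exact — every operation checks template equality and the
package never resamples. Rasterisation assigns each cell to the polygon
containing its center; a center exactly on a shared edge goes to the
polygon occurring first in file order (assignment fills only still-empty
cells in polygon order), a deterministic tie-break. The nodata sentinel is
−99999 for float layers; 0 is a legal value. Proportions are stored as
fractions in rasters and as percentages in tables; conversion happens only
at the table→raster boundary. Rasters are read and written as Esri ASCII
grids, a plain-text georeferenced format that standard GIS tooling ingests
directly; boundaries travel as GeoJSON.

## The synthetic country

Because the real inputs are licensed (census microdata, DHS/MICS files),
testing uses a fully synthetic country whose statistical structure mirrors
what the pipeline assumes:

* **Boundaries**: `n_admin1` horizontal bands × `n_admin2_per_admin1`
  rectangles per band, grid-cell aligned, exactly tiling the template.
  Rectangles keep every geometric check exact; realistic boundary shapes
  would not change what the tests can show.
* **Age structure**: each admin-2 unit has proportions
  $p_g \propto e^{-\rho g}$ over bin index $g = 0 \dots 13$. A single decay
  parameter (default drawn per unit from $U(0.05, 0.30)$, a range spanning
  gently to steeply young pyramids) produces realistic monotone pyramids
  and has a closed geometric-series form that serves as an independent
  oracle — young-age dependency is strictly increasing in $\rho$. The sex
  split (default $U(0.47, 0.53)$) is uniform across bins, so the pipeline's
  sex-split step is exact on synthetic data.
* **Two layers of truth**: the exact fractions and their largest-remainder
  integer realization as person counts. A finite population cannot carry
  the exact fractions, so exact-recovery statements (census at fraction 1
  recovers truth to 1e−9) are made against the realized counts, while
  closed-form oracles target the exact layer; the two differ by less than
  one person per cell.
* **Population surface**: each unit's population is spread over its cells
  by a seeded multinomial over gamma cell weights (or uniformly on
  request); per-unit cell sums equal unit populations exactly by
  construction.
* **Census microdata**: every person is included independently with
  probability `census_sample_fraction` (default 0.10, inside the typical
  2–15% range), so fraction 1 returns the full population.
* **Survey microdata**: strata are the admin-1 units; the default design
  samples 20 of 100 PSUs per stratum and 25 of 40 households per PSU with
  mean household size 5 — about 2,500 interviewed persons per stratum,
  roughly 1% of it, matching the order of magnitude of national household
  surveys. Weights are the inverse inclusion probabilities
  $1/(\pi_{\mathrm{psu}}\pi_{\mathrm{hh}})$; a de-facto flag is Bernoulli
  (default 0.95). No published design tables exist for these parameters;
  they were fixed once at survey-typical values.

One master seed drives everything; each stage draws from a fixed substream
offset so stages can be regenerated independently, and identical spec +
seed gives byte-identical output.

**What the generator does not emulate** — and therefore what passing tests
do *not* show about real data: ages are drawn i.i.d. from the stratum
pyramid, so households have no age clustering (design-effect/variance
behaviour is untested, but point estimates, which are what feed the maps,
are unaffected); there is no age heaping, no under-enumeration of young
children, no migration-driven spatial age sorting within units; boundaries
are rectangles. The survey generator draws person rows at the admin-1
level because that is the level at which surveys are representative.

## Numerical choices

* Sum-QA tolerance on standard tables is 0.15 percentage points, sized to
  absorb 1-decimal export rounding of up to 16 rounded addends; internal
  computation is always full precision, with rounding (1 decimal for
  tables, 2 for ratios) applied only on export.
* Rebinning refuses intervals that straddle a 5-year boundary ("non-nestable
  interval") rather than interpolating: no defensible splitting rule exists
  without extra assumptions, and failing loudly beats silently inventing
  people.
* Integer apportionment (unit populations, realized structure counts,
  uniform cell spreading) uses largest-remainder rounding with a
  deterministic tie-break (larger remainder, then lower index).
* Zero-total units error by name (tables) or are excluded with a warning
  (census tabulation, when an expected-unit list is supplied); survey units
  whose de-facto weight sum is zero are an error, since silently imputing a
  structure would be worse.
* Quantiles in national comparisons use the linear-interpolation rule
  (type 7), unweighted across units; whether to population-weight the
  distribution of unit-level ratios is a genuinely open choice, and the
  unweighted form is what makes the "national value outside the
  subnational IQR" diagnostic interpretable.
* Between-round differences are *signed* percentage-point differences on
  the finer 17-bin schema, with the country `Total` row pooled from
  regional totals, not averaged over regions. Each row of differences sums
  to 0 because both rounds sum to 100.

## Problem sizes in the test suite

The packaged checks run on: a 200×200-cell country (20 units, 2M people)
for the conservation audit; 500 seeded survey replicates of the default
design for the design-bias check (the maximum per-bin absolute bias of the
weighted estimator stays below 0.3 percentage points); 100 seeded census
replicates at 10% sampling for convergence; and 1,000-row random microdata
for oracle equivalence. These sizes were chosen so each property is
measured well inside its tolerance while the whole suite stays quick to
run.

## A worked unit

```{r}
bhutan <- read.csv(system.file("extdata", "bhutan_agesex_partial.csv",
                               package = "agestruct"))
r <- compute_ratios(derive_triple(bhutan[bhutan$ADM_NAME == "BUMTHANG", ]))
round(r[, c("YDR", "ODR", "CDR")], 2)
```

BUMTHANG has 30.8% of its population under 15 and 6.2% at 65+, giving a
young-age dependency ratio near 49 dependants per 100 working-age people
and a combined ratio near 59. (The packaged Bhutan table ships only the
age columns its source prints, which is all the ratio derivation needs:
partial rows use the complement rule.)

## Known limitations

Point estimates only: the survey tabulator applies weights but does not
produce design-based variances or confidence intervals. Only the two
declared raw-table dialects are parsed; arbitrary national census layouts
need manual restructuring before entering the pipeline. Rasterisation is
cell-center containment, not area-weighted, so slivers smaller than a cell
can vanish (with a warning). The uniform sex split is an approximation
wherever the true sex ratio varies by age — its error is bounded by the
unit's age-specific sex-ratio variation, which the available sources do not
report.
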