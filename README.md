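# agestruct

Subnational age/sex structures, dependency ratios and gridded 5-year
age/sex population counts, from heterogeneous demographic sources.

## What it does

Demographers and health planners often need to know *where* the young,
working-age and elderly populations are — at finer resolution than national
statistics give. The raw material is messy: full census tables (counts or
percentages in 1- to 5-year bins), census microdata (person rows sampled at
2–15% of a census), and household surveys (weighted person rows from
stratified two-stage cluster designs). `agestruct` turns these into:

1. **Standard tables** — one row per administrative unit with the percent
   of population in each of 14 age groups (`A0004` … `A65PL`) and a
   male/female split (`MPROP`, `FPROP`);
2. **Dependency ratios** per unit — with `pc0_14`, `pc15_64`, `pc65` the
   shares of the three broad age groups,

   ```
   YDR = (pc0_14 / pc15_64) x 100      young-age dependency
   ODR = (pc65   / pc15_64) x 100      old-age dependency
   CDR = YDR + ODR                     combined
   ```

3. **Gridded count layers** — unit proportions rasterised onto a template
   grid by cell-center containment and multiplied cellwise into a
   national-adjusted population-count surface (`count_g = proportion_g x
   population`, cellwise), giving
   one count layer per age group and sex, bit-aligned with the population
   grid.

A packaged source catalogue routes each of 87 African and Asian countries
to its processing path (census table / census microdata / weighted survey /
national fallback), and a seeded synthetic-country generator (boundaries,
true pyramids, population grid, census and survey samples) makes the whole
pipeline testable without licensed data. Validation tools implement the
conservation audit, subnational-vs-national comparisons and between-round
sensitivity differences.

## Worked example

```r
library(agestruct)

# A standardised table (packaged example: Bhutan's 20 districts, with the
# columns its source prints)
bhutan <- read.csv(system.file("extdata", "bhutan_agesex_partial.csv",
                               package = "agestruct"))
r <- compute_ratios(derive_triple(bhutan[bhutan$ADM_NAME == "BUMTHANG", ]))
round(r[, c("YDR", "ODR", "CDR")], 2)
#>     YDR  ODR   CDR
#> 1 48.89 9.84 58.73
```

BUMTHANG has 30.8% of its people under 15 and 6.2% aged 65+, so there are
about 48.9 young and 9.8 old dependants per 100 working-age people — a
combined dependency ratio of 58.7.

End-to-end on synthetic data:

```r
spec <- synthetic_country_spec(seed = 1)     # 16 units, 1M people, 40x40 grid
country <- simulate_country(spec)
tab <- as_standard_table(tabulate_weighted_survey(country$survey))
head(compute_ratios(derive_triple(tab)))
rec <- recover_parameters(spec)              # simulate -> tabulate -> grid -> audit
str(rec$conservation$cellwise)
#> List of 3
#>  $ max_abs_dev: num 1.82e-12
#>  $ max_rel_dev: num 6.58e-16
#>  $ pass       : logi TRUE
```

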