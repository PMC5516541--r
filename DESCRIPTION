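Package: agestruct
Title: Subnational Age/Sex Structures, Dependency Ratios and Gridded Population Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for harmonising heterogeneous subnational age/sex data
    (census tables, census microdata, weighted household surveys) into
    standardised proportional age/sex structures per administrative unit,
    computing combined, young-age and old-age dependency ratios, and
    disaggregating a gridded population-count surface into 5-year age/sex
    count layers aligned to a template grid. Includes survey-weighted
    tabulation of person microdata, national-total adjustment, conservation
    and national-comparison validation checks, between-round sensitivity
    differences, and a seeded synthetic-country generator (boundaries, true
    structure, population grid, census and two-stage cluster survey samples)
    for end-to-end testing without licensed data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: jsonlite, stats, utils
Suggests: testthat (>= 3.0.0), withr, optparse, knitr, rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
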