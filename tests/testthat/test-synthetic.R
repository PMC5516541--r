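test_that("admin mosaic tiles the grid exactly with nested rectangles", {
  spec4 <- small_spec()  # 2 x 2 on an 8 x 8 grid
  b <- generate_admin_mosaic(spec4)
  expect_equal(nrow(b$units), 4)
  res <- spec4$grid$resolution
  expect_equal(boundary_areas(b), rep((4 * res) ^ 2, 4), tolerance = 1e-9)
  # conservation of area: union = extent (polygons are disjoint rectangles)
  expect_equal(sum(boundary_areas(b)), (8 * res) ^ 2, tolerance = 1e-9)
  # every grid cell is claimed by exactly one unit
  zones <- rasterize_zones(b, spec4$grid)
  expect_false(any(zones$values == spec4$grid$nodata))
  expect_equal(as.vector(table(zones$values)), rep(16, 4))

  # 3 bands of 2 rows each
  spec3 <- small_spec(n_admin1 = 3, n_admin2_per_admin1 = 1,
                      grid = grid_template(west = 0, north = 1,
                                           resolution = 1 / 120,
                                           n_rows = 6, n_cols = 6))
  b3 <- generate_admin_mosaic(spec3)
  expect_equal(nrow(b3$units), 3)
  expect_equal(sum(boundary_areas(b3)), (6 / 120) ^ 2, tolerance = 1e-9)
})

test_that("non-divisible partitions error naming the offending dimension", {
  expect_error(
    small_spec(grid = grid_template(west = 0, north = 1, resolution = 1 / 120,
                                    n_rows = 5, n_cols = 4)),
    "rows \\(5\\) not divisible")
  expect_error(
    small_spec(grid = grid_template(west = 0, north = 1, resolution = 1 / 120,
                                    n_rows = 4, n_cols = 6),
               n_admin2_per_admin1 = 4),
    "columns \\(6\\) not divisible")
})

test_that("exponential pyramid has the closed geometric form", {
  expect_equal(unname(pyramid_proportions(0)), rep(1 / 14, 14))
  p <- pyramid_proportions(0.2)
  # geometric-series oracle for the first bin, and direct normalisation
  expect_equal(unname(p[1]), (1 - exp(-0.2)) / (1 - exp(-2.8)),
               tolerance = 1e-12)
  q <- exp(-0.2 * (0:13))
  expect_equal(unname(p), q / sum(q), tolerance = 1e-15)
  expect_equal(sum(p), 1, tolerance = 1e-15)
  expect_error(pyramid_proportions(-0.1), ">= 0")
})

test_that("true structure cells are a distribution and counts realize it", {
  spec <- small_spec()
  st <- generate_true_structure(spec)
  expect_equal(rowSums(st$p_exact), rep(1, 4), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(st$p_exact >= 0))
  expect_equal(unname(rowSums(st$counts)), st$units$pop)
  expect_equal(sum(st$units$pop), spec$total_population)
  # integerization is within half a person per cell of the exact target
  expect_lt(max(abs(st$counts - st$p_exact * st$units$pop)), 1)
})

test_that("a 0.5 male share makes the sex stacks identical", {
  spec <- small_spec(male_share = 0.5)
  st <- generate_true_structure(spec)
  labs <- age_schema()$label
  expect_equal(st$p_exact[, paste0("M_", labs)],
               st$p_exact[, paste0("F_", labs)], ignore_attr = TRUE)
})

test_that("population grid conserves unit populations under both modes", {
  spec <- small_spec()
  b <- generate_admin_mosaic(spec)
  st <- generate_true_structure(spec)
  zones <- rasterize_zones(b, spec$grid)
  for (uniform in c(TRUE, FALSE)) {
    g <- generate_population_grid(spec, b, st, uniform = uniform)
    zs <- zonal_sum(g, zones)
    expect_equal(unname(zs), as.numeric(st$units$pop))
  }
  # uniform apportionment with a divisible population is exactly even
  spec2 <- small_spec(total_population = 6400)  # 100 per cell if even units
  st2 <- generate_true_structure(spec2)
  st2$units$pop <- rep(1600L, 4)  # 16 cells per unit -> 100 each
  g2 <- generate_population_grid(spec2, b, st2, uniform = TRUE)
  expect_true(all(g2$values == 100))
})

test_that("census sampling is seeded, sized and exact at fraction 1", {
  spec <- small_spec()
  st <- generate_true_structure(spec)
  expect_error(sample_census_microdata(st, 0, 1), "fraction")
  expect_error(sample_census_microdata(st, 1.2, 1), "fraction")

  full <- sample_census_microdata(st, 1, seed = 5)
  expect_equal(nrow(full), spec$total_population)
  # per-unit tabulation equals the realized truth exactly
  tab <- table(full$unit_id)
  expect_equal(as.vector(tab), st$units$pop)

  s1 <- sample_census_microdata(st, 0.05, seed = 8)
  s2 <- sample_census_microdata(st, 0.05, seed = 8)
  expect_identical(s1, s2)
  # row count within binomial support and near expectation
  expect_true(nrow(s1) <= spec$total_population)
  expect_lt(abs(nrow(s1) - 0.05 * spec$total_population),
            5 * sqrt(0.05 * 0.95 * spec$total_population))
})

test_that("10% census samples converge to the truth across seeds", {
  spec <- small_spec(n_admin1 = 1, n_admin2_per_admin1 = 1,
                     grid = grid_template(west = 0, north = 1,
                                          resolution = 1 / 120,
                                          n_rows = 4, n_cols = 4),
                     total_population = 50000)
  st <- generate_true_structure(spec)
  truth <- true_standard_table(st)
  cols <- c("MPROP", "FPROP", age_schema()$label)
  ok <- vapply(1:100, function(s) {
    micro <- sample_census_microdata(st, 0.10, seed = 1000 + s)
    tab <- as_standard_table(tabulate_census_microdata(micro))
    max(abs(as.matrix(tab[, cols]) - as.matrix(truth[, cols]))) < 2
  }, logical(1))
  expect_gte(sum(ok), 99)
})

test_that("survey weights are inverse inclusion probabilities", {
  spec <- small_spec()
  st <- generate_true_structure(spec)
  design <- survey_design_spec(psus_per_stratum = 4, psus_sampled = 2,
                               households_per_psu = 10, households_sampled = 5,
                               mean_household_size = 4)
  svy <- sample_survey_microdata(st, design, defacto_prob = 1, seed = 3)
  expect_true(all(svy$weight == 4))  # 1 / (0.5 * 0.5)
  expect_true(all(svy$de_facto))
  expect_setequal(unique(svy$unit_id), unique(st$units$admin1_id))
  expect_equal(length(unique(svy$psu_id)), 2 * 2)  # 2 strata x 2 PSUs

  expect_error(survey_design_spec(psus_per_stratum = 4, psus_sampled = 5),
               "psus_sampled")
  expect_error(survey_design_spec(households_per_psu = 5,
                                  households_sampled = 6),
               "households_sampled")
})

test_that("identical spec and seed give byte-identical generator output", {
  a <- simulate_country(small_spec(seed = 11))
  b <- simulate_country(small_spec(seed = 11))
  expect_identical(a$structure, b$structure)
  expect_identical(a$population$values, b$population$values)
  expect_identical(a$census, b$census)
  expect_identical(a$survey, b$survey)
  c <- simulate_country(small_spec(seed = 12))
  expect_false(identical(a$census, c$census))
})

test_that("survey tabulation recovers admin-1 truth within sampling error", {
  spec <- small_spec(seed = 2)
  st <- generate_true_structure(spec)
  truth <- true_standard_table(st, level = "admin1")
  cols <- c("MPROP", "FPROP", age_schema()$label)
  # 40 replicates: mean estimate close to truth (full 500-replicate bias
  # check runs in the acceptance suite)
  est <- 0
  n_rep <- 40
  for (s in 1:n_rep) {
    svy <- sample_survey_microdata(st, spec$survey_design, spec$defacto_prob,
                                   seed = 5000 + s)
    tab <- as_standard_table(tabulate_weighted_survey(svy))
    tab <- tab[match(truth$ADM_NAME, tab$ADM_NAME), ]
    est <- est + as.matrix(tab[, cols]) / n_rep
  }
  expect_lt(max(abs(est - as.matrix(truth[, cols]))), 0.75)
})

test_that("within-bin age draws stay inside their bins", {
  spec <- small_spec()
  st <- generate_true_structure(spec)
  micro <- sample_census_microdata(st, 0.2, seed = 6)
  schema <- age_schema()
  bin <- age_to_bin(micro$age)
  expect_true(all(micro$age >= schema$lo[bin]))
  expect_true(all(micro$age <= 84))
})
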