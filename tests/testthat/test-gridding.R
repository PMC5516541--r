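tmpl4 <- grid_template(west = 0, north = 4 / 120, resolution = 1 / 120,
                       n_rows = 4, n_cols = 4)

test_that("grid template geometry and validation", {
  cc <- cell_centers(tmpl4)
  expect_equal(cc$x[1], 0.5 / 120)
  expect_equal(cc$y[1], 3.5 / 120)
  expect_equal(length(cc$x), 4)
  expect_error(grid_template(west = 179, north = 0, resolution = 1,
                             n_rows = 2, n_cols = 4),
               "extent")
  expect_error(raster_layer(tmpl4, matrix(0, 3, 4)), "dimensions")
  expect_error(raster_layer(tmpl4, 1.5, semantics = "proportion"), "\\[0,1\\]")
  expect_error(raster_layer(tmpl4, -2, semantics = "count"), "nonnegative")
  expect_error(raster_layer(tmpl4, 1.5, semantics = "iso"), "integers")
})

test_that("rasterisation assigns cell centers to containing polygons", {
  ext <- rect_ring(0, 4 / 120, 0, 4 / 120)
  b <- admin_boundary_set(data.frame(unit_id = "A", admin1_id = "A", v = 0.3),
                          list(ext))
  r <- rasterize_attribute(b, "v", tmpl4)
  expect_true(all(r$values == 0.3))

  halves <- admin_boundary_set(
    data.frame(unit_id = c("L", "R"), admin1_id = "A", v = c(0.2, 0.8)),
    list(rect_ring(0, 2 / 120, 0, 4 / 120),
         rect_ring(2 / 120, 4 / 120, 0, 4 / 120)))
  r2 <- rasterize_attribute(halves, "v", tmpl4)
  expect_false(any(r2$values == tmpl4$nodata))
  expect_true(all(r2$values[, 1:2] == 0.2))
  expect_true(all(r2$values[, 3:4] == 0.8))

  # a sliver with no cell center: all nodata plus warning
  sliver <- admin_boundary_set(
    data.frame(unit_id = "S", admin1_id = "S", v = 1),
    list(rect_ring(0.9 / 120, 0.95 / 120, 0, 0.05 / 120)))
  expect_warning(r3 <- rasterize_attribute(sliver, "v", tmpl4), "no cell center")
  expect_true(all(r3$values == tmpl4$nodata))

  expect_error(rasterize_attribute(halves, "missing_field", tmpl4),
               "field not found")
})

test_that("rasterisation matches the containment oracle on random mosaics", {
  set.seed(17)
  tmpl <- grid_template(west = 10, north = 5, resolution = 0.05,
                        n_rows = 12, n_cols = 12)
  for (rep in 1:5) {
    # random vertical split into 2-4 bands, each split at a random cell edge
    n_bands <- sample(2:4, 1)
    edges <- sort(c(0, sample(1:11, n_bands - 1), 12)) * 0.05
    rects <- cbind(10 + edges[-length(edges)], 10 + edges[-1],
                   5 - 12 * 0.05, 5)
    vals <- runif(n_bands)
    b <- admin_boundary_set(
      data.frame(unit_id = sprintf("B%d", seq_len(n_bands)),
                 admin1_id = "A", v = vals),
      lapply(seq_len(n_bands),
             function(k) rect_ring(rects[k, 1], rects[k, 2],
                                   rects[k, 3], rects[k, 4])))
    got <- rasterize_attribute(b, "v", tmpl)$values
    want <- oracle_rasterize_rects(rects, vals, tmpl)
    expect_equal(got, want)
  }
})

test_that("rasterize then zonal mean recovers the attribute exactly", {
  spec <- small_spec()
  b <- generate_admin_mosaic(spec)
  b$units$attr <- c(10, 20, 30, 40)
  r <- rasterize_attribute(b, "attr", spec$grid, semantics = "ratio")
  zones <- rasterize_zones(b, spec$grid)
  sums <- zonal_sum(r, zones)
  cells <- table(zones$values[zones$values != spec$grid$nodata])
  expect_equal(unname(sums / as.vector(cells)), b$units$attr)
})

test_that("national-total adjustment rescales per country", {
  pop <- raster_layer(tmpl4, matrix(5, 4, 4))  # sum 80
  iso <- raster_layer(tmpl4, 1, semantics = "iso")
  adj <- adjust_to_national_totals(pop, iso, c("1" = 100))
  expect_true(all(adj$values == 6.25))  # x 1.25
  expect_equal(sum(adj$values), 100)

  same <- adjust_to_national_totals(pop, iso, c("1" = 80))
  expect_equal(same$values, pop$values)

  # two-country mask with distinct factors
  iso2 <- raster_layer(tmpl4, cbind(matrix(1, 4, 2), matrix(2, 4, 2)),
                       semantics = "iso")
  adj2 <- adjust_to_national_totals(pop, iso2, c("1" = 80, "2" = 20))
  expect_equal(unname(zonal_sum(adj2, iso2)), c(80, 20))

  zero <- raster_layer(tmpl4, cbind(matrix(0, 4, 2), matrix(5, 4, 2)))
  expect_error(adjust_to_national_totals(zero, iso2, c("1" = 10, "2" = 40)),
               "zero current population")
  expect_error(adjust_to_national_totals(pop, iso2, c("1" = 80)),
               "no national target")
})

test_that("age/sex disaggregation is a cellwise product that conserves", {
  wppc <- raster_layer(tmpl4, matrix(400, 4, 4))
  agp <- lapply(1:4, function(i) raster_layer(tmpl4, 0.25,
                                              semantics = "proportion"))
  names(agp) <- c("A", "B", "C", "D")
  agc <- disaggregate_age_sex(agp, wppc)
  expect_true(all(agc$A$values == 100))
  total <- Reduce(`+`, lapply(agc, function(l) l$values))
  expect_equal(total, wppc$values)

  sexl <- list(M = raster_layer(tmpl4, 0.6, semantics = "proportion"),
               F = raster_layer(tmpl4, 0.4, semantics = "proportion"))
  agcs <- disaggregate_age_sex(agp, wppc, sex_layers = sexl)
  expect_equal(agcs$M_A$values + agcs$F_A$values, agc$A$values)

  other <- grid_template(west = 0, north = 4 / 120, resolution = 1 / 60,
                         n_rows = 4, n_cols = 4)
  agp_bad <- agp
  agp_bad$A <- raster_layer(other, 0.25, semantics = "proportion")
  expect_error(disaggregate_age_sex(agp_bad, wppc), "misaligned")

  agp_sum <- agp
  agp_sum$A <- raster_layer(tmpl4, 0.30, semantics = "proportion")
  expect_error(disaggregate_age_sex(agp_sum, wppc), "sum to 1")
})

test_that("nodata propagates through disaggregation", {
  vals <- matrix(400, 4, 4)
  vals[1, 1] <- tmpl4$nodata
  wppc <- raster_layer(tmpl4, vals)
  agp <- list(A = raster_layer(tmpl4, 1, semantics = "proportion"))
  agc <- disaggregate_age_sex(agp, wppc)
  expect_equal(agc$A$values[1, 1], tmpl4$nodata)
  expect_true(all(agc$A$values[-1] == 400 | agc$A$values[-1] == 400))
})

test_that("country extraction partitions the data cells", {
  iso2 <- raster_layer(tmpl4, cbind(matrix(1, 4, 2), matrix(2, 4, 2)),
                       semantics = "iso")
  layer <- raster_layer(tmpl4, matrix(1:16, 4, 4))
  e1 <- extract_country(layer, iso2, 1)
  e2 <- extract_country(layer, iso2, 2)
  s <- function(l) sum(l$values[l$values != l$template$nodata])
  expect_equal(s(e1) + s(e2), sum(layer$values))

  # single-code mask: identity on data cells
  iso1 <- raster_layer(tmpl4, 1, semantics = "iso")
  expect_equal(extract_country(layer, iso1, 1)$values, layer$values)
  expect_warning(e0 <- extract_country(layer, iso1, 99), "no data cells")
  expect_true(all(e0$values == tmpl4$nodata))

  # cropping preserves alignment: origin moves a whole number of cells
  ec <- extract_country(layer, iso2, 2, crop = TRUE)
  expect_equal(ec$template$n_cols, 2)
  offset <- (ec$template$west - tmpl4$west) / tmpl4$resolution
  expect_equal(offset, round(offset))
})

test_that("ascii grid and geojson round trips preserve data and geometry", {
  spec <- small_spec()
  ctry <- simulate_country(spec)
  tmp <- withr::local_tempfile(fileext = ".asc")
  write_ascii_grid(ctry$population, tmp)
  back <- read_ascii_grid(tmp, semantics = "count")
  expect_equal(back$values, ctry$population$values)
  expect_true(same_template <- isTRUE(all.equal(back$template$west,
                                                ctry$population$template$west)))

  gj <- withr::local_tempfile(fileext = ".geojson")
  write_boundaries_geojson(ctry$boundaries, gj)
  b2 <- read_boundaries_geojson(gj)
  expect_equal(b2$units$unit_id, ctry$boundaries$units$unit_id)
  r1 <- rasterize_zones(ctry$boundaries, spec$grid)
  r2 <- rasterize_zones(b2, spec$grid)
  expect_equal(r1$values, r2$values)
})
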