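#' Rasterize a unit attribute by cell-center containment
#'
#' Each cell takes the attribute value of the polygon containing the cell
#' center; cells whose center falls in no polygon get nodata. Centers lying
#' exactly on a shared edge are assigned to the polygon occurring first in
#' file order (assignment fills only still-empty cells, in polygon order).
#' The output grid is identical to the template: same origin, resolution and
#' dimensions, no resampling.
#'
#' @param b an `admin_boundary_set` whose `units` carry the attribute.
#' @param field name of the numeric attribute column to burn in.
#' @param tmpl target `grid_template`.
#' @param semantics semantics tag of the output layer.
#' @return a `raster_layer`.
#' @export
rasterize_attribute <- function(b, field, tmpl, semantics = "proportion") {
  if (!field %in% names(b$units)) stop("field not found on polygons: ", field)
  vals <- b$units[[field]]
  if (!is.numeric(vals)) stop("field must be numeric: ", field)
  if (any(is.na(vals))) stop("field has missing values on some polygons: ", field)
  cc <- cell_centers(tmpl)
  px <- rep(cc$x, each = tmpl$n_rows)       # column-major over (row, col)
  py <- rep(cc$y, times = tmpl$n_cols)
  out <- rep(tmpl$nodata, length(px))
  assigned <- rep(FALSE, length(px))
  for (i in seq_along(b$rings)) {
    hit <- !assigned & point_in_ring(px, py, b$rings[[i]])
    out[hit] <- vals[i]
    assigned <- assigned | hit
  }
  if (!any(assigned)) warning("no cell center falls inside any polygon")
  raster_layer(tmpl, matrix(out, tmpl$n_rows, tmpl$n_cols),
               semantics = semantics)
}

#' Rasterize unit identity (zone raster)
#'
#' Convenience wrapper burning the row index of each unit, used as the zone
#' layer for zonal statistics.
#'
#' @param b an `admin_boundary_set`.
#' @param tmpl target `grid_template`.
#' @return an integer-valued `raster_layer` (semantics `"iso"`), cell value =
#'   polygon index in file order.
#' @export
rasterize_zones <- function(b, tmpl) {
  bb <- b
  bb$units$.zone <- seq_len(nrow(b$units))
  rasterize_attribute(bb, ".zone", tmpl, semantics = "iso")
}

#' Zonal sums of a layer
#'
#' @param layer a `raster_layer` (nodata cells contribute 0).
#' @param zones an aligned integer zone layer (e.g. [rasterize_zones()] or an
#'   ISO mask).
#' @return named numeric vector of per-zone sums (names = zone values).
#' @export
zonal_sum <- function(layer, zones) {
  if (!same_template(layer$template, zones$template)) {
    stop("zone layer is not aligned with the data layer")
  }
  v <- values_or_na(layer)
  z <- values_or_na(zones)
  keep <- !is.na(z) & !is.na(v)
  s <- tapply(v[keep], z[keep], sum)
  stats::setNames(as.numeric(s), names(s))
}

#' Adjust a population layer to national totals
#'
#' Cells of each country are multiplied by target / current country sum so
#' that post-adjustment country totals equal the supplied national reference
#' estimates.
#'
#' @param pop a count `raster_layer`.
#' @param iso an aligned integer country-code layer.
#' @param targets named numeric vector: country code -> target persons.
#' @return adjusted count `raster_layer`.
#' @export
adjust_to_national_totals <- function(pop, iso, targets) {
  if (!same_template(pop$template, iso$template)) {
    stop("iso mask is not aligned with the population layer")
  }
  sums <- zonal_sum(pop, iso)
  codes <- names(sums)
  miss <- setdiff(codes, names(targets))
  if (length(miss) > 0) {
    stop("no national target for country code(s): ", paste(miss, collapse = ", "))
  }
  zero <- codes[sums[codes] == 0 & targets[codes] > 0]
  if (length(zero) > 0) {
    stop("country code(s) with zero current population but positive target: ",
         paste(zero, collapse = ", "))
  }
  factor <- targets[codes] / sums[codes]
  v <- values_or_na(pop)
  z <- values_or_na(iso)
  idx <- match(z, as.numeric(codes))
  scale <- factor[idx]
  out <- v * ifelse(is.na(scale), 1, scale)
  out[is.na(out)] <- pop$template$nodata
  raster_layer(pop$template, out, semantics = "count")
}

#' Disaggregate a population surface into age/sex count layers
#'
#' Cellwise product of each gridded proportion layer with the population
#' count surface: count_g = proportion_g x population. If per-unit sex
#' proportion layers are supplied, each age layer is further split into male
#' and female stacks (the sex split is uniform across ages within a unit).
#' Nodata in any factor propagates.
#'
#' @param agp_stack named list of aligned proportion `raster_layer`s, one per
#'   age group; per-cell sums over the stack must be 1 (within `tol`) where
#'   data exist.
#' @param wppc the aligned population-count `raster_layer`.
#' @param sex_layers optional named list with proportion layers `M` and `F`.
#' @param tol tolerance on the per-cell proportion-sum precondition.
#' @return named list of count `raster_layer`s (names preserved from
#'   `agp_stack`; with `sex_layers`, names are `M_<group>` and `F_<group>`).
#' @export
disaggregate_age_sex <- function(agp_stack, wppc, sex_layers = NULL,
                                 tol = 1e-6) {
  for (nm in names(agp_stack)) {
    if (!same_template(agp_stack[[nm]]$template, wppc$template)) {
      stop(sprintf(
        "misaligned grids: layer '%s' (%dx%d at %.8g) vs population (%dx%d at %.8g)",
        nm, agp_stack[[nm]]$template$n_rows, agp_stack[[nm]]$template$n_cols,
        agp_stack[[nm]]$template$resolution,
        wppc$template$n_rows, wppc$template$n_cols, wppc$template$resolution))
    }
  }
  props <- lapply(agp_stack, values_or_na)
  psum <- Reduce(`+`, props)
  data <- !is.na(psum)
  if (any(abs(psum[data] - 1) > tol)) {
    stop("age-group proportion layers do not sum to 1 per cell")
  }
  pop <- values_or_na(wppc)
  nodata <- wppc$template$nodata
  make_layer <- function(v) {
    v[is.na(v)] <- nodata
    raster_layer(wppc$template, v, semantics = "count")
  }
  agc <- lapply(props, function(p) make_layer(p * pop))
  names(agc) <- names(agp_stack)
  if (is.null(sex_layers)) return(agc)
  if (!all(c("M", "F") %in% names(sex_layers))) {
    stop("sex_layers must contain proportion layers 'M' and 'F'")
  }
  m <- values_or_na(sex_layers$M)
  f <- values_or_na(sex_layers$F)
  out <- list()
  for (nm in names(agc)) {
    a <- values_or_na(agc[[nm]])
    out[[paste0("M_", nm)]] <- make_layer(a * m)
    out[[paste0("F_", nm)]] <- make_layer(a * f)
  }
  out
}

#' Extract one country from a continental layer
#'
#' Keeps cells whose ISO mask value equals `code`; everything else becomes
#' nodata. Optionally crops to the country's bounding box while preserving
#' grid alignment (the cropped origin is a whole number of cells from the
#' template origin).
#'
#' @param layer a `raster_layer`.
#' @param iso aligned integer country-code layer.
#' @param code country code to extract.
#' @param crop if `TRUE`, crop to the bounding rows/cols of the country.
#' @return a `raster_layer`.
#' @export
extract_country <- function(layer, iso, code, crop = FALSE) {
  if (!same_template(layer$template, iso$template)) {
    stop("iso mask is not aligned with the data layer")
  }
  z <- values_or_na(iso)
  v <- values_or_na(layer)
  v[is.na(z) | z != code] <- NA_real_
  if (!any(!is.na(v))) {
    warning("country code ", code, " selects no data cells")
  }
  tmpl <- layer$template
  if (crop && any(!is.na(v))) {
    rows <- range(which(rowSums(!is.na(v)) > 0))
    cols <- range(which(colSums(!is.na(v)) > 0))
    v <- v[rows[1]:rows[2], cols[1]:cols[2], drop = FALSE]
    tmpl <- grid_template(
      west = tmpl$west + (cols[1] - 1) * tmpl$resolution,
      north = tmpl$north - (rows[1] - 1) * tmpl$resolution,
      resolution = tmpl$resolution,
      n_rows = nrow(v), n_cols = ncol(v), nodata = tmpl$nodata,
      crs = tmpl$crs)
  }
  v[is.na(v)] <- tmpl$nodata
  raster_layer(tmpl, v, semantics = layer$semantics)
}
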