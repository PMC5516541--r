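#' Grid template
#'
#' Defines an axis-aligned geographic (WGS84 lon/lat) grid: origin at the
#' north-west corner, square cells of `resolution` degrees. Cell (r, c)
#' spans x in [west + (c-1) res, west + c res) and y in
#' (north - r res, north - (r-1) res]. All layers in a pipeline share one
#' template; alignment is bit-exact and no resampling ever occurs.
#'
#' @param west,north north-west corner, degrees.
#' @param resolution cell size in degrees (default 30 arc seconds = 1/120).
#' @param n_rows,n_cols grid dimensions.
#' @param nodata nodata sentinel for float layers; 0 is a legal data value.
#' @param crs coordinate reference system label (geographic WGS84).
#' @return object of class `grid_template`.
#' @export
grid_template <- function(west, north, resolution = 1 / 120, n_rows, n_cols,
                          nodata = -99999, crs = "GCS WGS 1984") {
  stopifnot(resolution > 0, n_rows >= 1, n_cols >= 1)
  east <- west + n_cols * resolution
  south <- north - n_rows * resolution
  if (west < -180 || east > 180 || north > 90 || south < -90) {
    stop("grid extent must lie within [-180,180] x [-90,90]")
  }
  structure(list(west = west, north = north, resolution = resolution,
                 n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 nodata = nodata, crs = crs),
            class = "grid_template")
}

#' @export
print.grid_template <- function(x, ...) {
  cat(sprintf("grid_template: %d x %d cells, res %.8g deg, NW corner (%.6g, %.6g), nodata %g\n",
              x$n_rows, x$n_cols, x$resolution, x$west, x$north, x$nodata))
  invisible(x)
}

same_template <- function(a, b, tol = 1e-12) {
  abs(a$west - b$west) <= tol && abs(a$north - b$north) <= tol &&
    abs(a$resolution - b$resolution) <= tol &&
    a$n_rows == b$n_rows && a$n_cols == b$n_cols
}

#' Cell-center coordinates of a grid template
#'
#' @param tmpl a `grid_template`.
#' @return list with vectors `x` (length n_cols, west to east) and `y`
#'   (length n_rows, north to south).
#' @export
cell_centers <- function(tmpl) {
  list(x = tmpl$west + (seq_len(tmpl$n_cols) - 0.5) * tmpl$resolution,
       y = tmpl$north - (seq_len(tmpl$n_rows) - 0.5) * tmpl$resolution)
}

#' Raster layer
#'
#' A single-band raster: a numeric matrix (rows = north to south) plus its
#' grid template and a semantics tag. Proportion layers hold fractions in
#' [0,1]; ratio layers hold dimensionless ratios x 100; count layers hold
#' persons per cell; iso layers hold integer country codes.
#'
#' @param template a `grid_template`.
#' @param values numeric matrix `n_rows` x `n_cols` (or a scalar, recycled).
#' @param semantics one of `"proportion"`, `"ratio"`, `"count"`, `"iso"`.
#' @return object of class `raster_layer`.
#' @export
raster_layer <- function(template, values,
                         semantics = c("count", "proportion", "ratio", "iso")) {
  semantics <- match.arg(semantics)
  if (length(values) == 1) {
    values <- matrix(values, template$n_rows, template$n_cols)
  }
  values <- as.matrix(values)
  if (nrow(values) != template$n_rows || ncol(values) != template$n_cols) {
    stop("values matrix does not match template dimensions")
  }
  data <- values != template$nodata & !is.na(values)
  if (semantics == "proportion" &&
      any(values[data] < 0 | values[data] > 1)) {
    stop("proportion layer values must lie in [0,1]")
  }
  if (semantics == "count" && any(values[data] < 0)) {
    stop("count layer values must be nonnegative")
  }
  if (semantics == "iso" && any(values[data] != floor(values[data]))) {
    stop("iso layer values must be integers")
  }
  structure(list(template = template, values = values, semantics = semantics),
            class = "raster_layer")
}

#' @export
print.raster_layer <- function(x, ...) {
  d <- values_or_na(x)
  cat(sprintf("raster_layer [%s]: %d x %d, %d data cells, range [%.6g, %.6g]\n",
              x$semantics, x$template$n_rows, x$template$n_cols,
              sum(!is.na(d)),
              suppressWarnings(min(d, na.rm = TRUE)),
              suppressWarnings(max(d, na.rm = TRUE))))
  invisible(x)
}

# matrix of values with nodata replaced by NA
values_or_na <- function(layer) {
  v <- layer$values
  v[v == layer$template$nodata] <- NA_real_
  v
}

#' Write / read a raster layer as an Esri ASCII grid
#'
#' Plain-text georeferenced raster format (`ncols`/`nrows`/`xllcorner`/
#' `yllcorner`/`cellsize`/`NODATA_value` header followed by rows north to
#' south), readable by standard GIS tooling.
#'
#' @param layer a `raster_layer`.
#' @param path file path (conventionally `.asc`).
#' @param semantics semantics tag to attach on read.
#' @param nodata nodata sentinel to use if the file header lacks one.
#' @return `read_ascii_grid()` returns a `raster_layer`.
#' @export
write_ascii_grid <- function(layer, path) {
  t <- layer$template
  header <- c(
    sprintf("ncols %d", t$n_cols),
    sprintf("nrows %d", t$n_rows),
    sprintf("xllcorner %.12g", t$west),
    sprintf("yllcorner %.12g", t$north - t$n_rows * t$resolution),
    sprintf("cellsize %.12g", t$resolution),
    sprintf("NODATA_value %.12g", t$nodata))
  rows <- apply(layer$values, 1, function(r) paste(format(r, trim = TRUE,
                                                          digits = 15),
                                                   collapse = " "))
  writeLines(c(header, rows), path)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @export
read_ascii_grid <- function(path, semantics = "count", nodata = -99999) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    hdr[[tolower(kv[1])]] <- as.numeric(kv[2])
    i <- i + 1
  }
  if (!is.null(hdr$nodata_value)) nodata <- hdr$nodata_value
  vals <- matrix(scan(text = lines[i:length(lines)], quiet = TRUE),
                 nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  tmpl <- grid_template(west = hdr$xllcorner,
                        north = hdr$yllcorner + hdr$nrows * hdr$cellsize,
                        resolution = hdr$cellsize,
                        n_rows = hdr$nrows, n_cols = hdr$ncols,
                        nodata = nodata)
  raster_layer(tmpl, vals, semantics = semantics)
}
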