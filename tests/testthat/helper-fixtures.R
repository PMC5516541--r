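# Small synthetic-country spec used across tests: 2 x 2 admin units on an
# 8 x 8 grid, 20k people, a light two-stage survey design.
small_spec <- function(seed = 42, ...) {
  args <- list(
    seed = seed,
    n_admin1 = 2, n_admin2_per_admin1 = 2,
    grid = grid_template(west = 30, north = 10, resolution = 1 / 120,
                         n_rows = 8, n_cols = 8),
    total_population = 20000,
    survey_design = survey_design_spec(psus_per_stratum = 50,
                                       psus_sampled = 10,
                                       households_per_psu = 20,
                                       households_sampled = 10,
                                       mean_household_size = 4))
  args[names(list(...))] <- list(...)
  do.call(synthetic_country_spec, args)
}

# Random person microdata for oracle comparisons.
random_microdata <- function(n, n_units = 3, weighted = FALSE, seed = 1) {
  set.seed(seed)
  out <- data.frame(
    unit_id = sample(sprintf("U%02d", seq_len(n_units)), n, replace = TRUE),
    age = sample(0:90, n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE),
    stringsAsFactors = FALSE)
  if (weighted) {
    out$weight <- stats::runif(n, 0.5, 5)
    out$de_facto <- stats::runif(n) < 0.9
  }
  out
}

# Independent brute-force cross-tabulation oracle: nested loops over units
# and schema bins, no shared code with the tabulators.
oracle_crosstab <- function(data, weighted = FALSE) {
  if (weighted) data <- data[data$de_facto, , drop = FALSE]
  w <- if (weighted) data$weight else rep(1, nrow(data))
  schema <- age_schema()
  units <- sort(unique(data$unit_id))
  out <- matrix(NA_real_, length(units), 16,
                dimnames = list(units, c(schema$label, "MPROP", "FPROP")))
  for (u in units) {
    in_u <- data$unit_id == u
    tot <- sum(w[in_u])
    for (g in seq_len(14)) {
      hi <- if (is.finite(schema$hi[g])) schema$hi[g] else Inf
      in_g <- in_u & data$age >= schema$lo[g] & data$age < hi
      out[u, g] <- 100 * sum(w[in_g]) / tot
    }
    out[u, "MPROP"] <- 100 * sum(w[in_u & data$sex == "male"]) / tot
    out[u, "FPROP"] <- 100 * sum(w[in_u & data$sex == "female"]) / tot
  }
  out
}

# Independent cell-center containment oracle for axis-aligned rectangles
# given as (xmin, xmax, ymin, ymax) rows; returns the value of the first
# containing rectangle per cell, or nodata.
oracle_rasterize_rects <- function(rects, values, tmpl) {
  cc <- cell_centers(tmpl)
  out <- matrix(tmpl$nodata, tmpl$n_rows, tmpl$n_cols)
  for (r in seq_len(tmpl$n_rows)) {
    for (c in seq_len(tmpl$n_cols)) {
      for (k in seq_len(nrow(rects))) {
        if (cc$x[c] > rects[k, 1] && cc$x[c] < rects[k, 2] &&
            cc$y[r] > rects[k, 3] && cc$y[r] < rects[k, 4]) {
          out[r, c] <- values[k]
          break
        }
      }
    }
  }
  out
}

rect_ring <- function(xmin, xmax, ymin, ymax) {
  matrix(c(xmin, ymin, xmax, ymin, xmax, ymax, xmin, ymax),
         ncol = 2, byrow = TRUE)
}

# Sorted-array quantile oracle (type-7 linear interpolation), written
# directly from the h = (n-1)p + 1 definition.
oracle_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}
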