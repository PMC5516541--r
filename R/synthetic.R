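#' Exponential pyramid proportions
#'
#' Single-parameter age pyramid over the 14 standard bins: the proportion in
#' bin g (g = 0...13) is proportional to exp(-rho * g). rho = 0 gives a
#' uniform pyramid; larger rho gives a younger population (a steeper
#' pyramid), so young-age dependency increases monotonically in rho. The
#' normalising constant has the closed geometric-series form
#' (1 - exp(-rho)) / (1 - exp(-14 rho)) for rho > 0.
#'
#' @param rho decay per 5-year bin, >= 0.
#' @return numeric vector of 14 proportions summing to 1, named by bin label.
#' @export
pyramid_proportions <- function(rho) {
  if (length(rho) != 1 || !is.finite(rho)) stop("rho must be a finite scalar")
  if (rho < 0) stop("pyramid decay rho must be >= 0")
  p <- if (rho == 0) rep(1 / 14, 14) else {
    q <- exp(-rho * (0:13))
    q / sum(q)
  }
  stats::setNames(p, age_schema()$label)
}

# Largest-remainder (Hamilton) apportionment of `total` into parts
# proportional to `shares`. Deterministic tie-break: larger remainder first,
# then lower index.
largest_remainder <- function(shares, total) {
  if (any(shares < 0) || sum(shares) <= 0) stop("shares must be nonnegative, not all zero")
  quota <- total * shares / sum(shares)
  base <- floor(quota)
  left <- round(total - sum(base))
  if (left > 0) {
    ord <- order(-(quota - base), seq_along(quota))
    base[ord[seq_len(left)]] <- base[ord[seq_len(left)]] + 1
  }
  as.integer(base)
}

# Substream seed for a named generator stage; keeps results of one stage
# stable when another stage is re-run.
substream <- function(seed, stage) {
  offsets <- c(mosaic = 1L, structure = 2L, popgrid = 3L, census = 4L,
               survey = 5L)
  if (!stage %in% names(offsets)) stop("unknown stage: ", stage)
  (as.integer(seed) + offsets[[stage]]) %% .Machine$integer.max
}

#' Two-stage survey design specification
#'
#' Describes a stratified two-stage cluster design: within each stratum
#' (admin-1 unit), `psus_sampled` of `psus_per_stratum` primary sampling
#' units are drawn, then `households_sampled` of `households_per_psu`
#' households within each sampled PSU; every member of a sampled household is
#' interviewed. Weights are the inverse inclusion probabilities
#' 1 / (pi_psu * pi_hh), constant within design cells.
#'
#' @param psus_per_stratum,psus_sampled PSU frame and sample size per stratum.
#' @param households_per_psu,households_sampled household frame and sample
#'   size per PSU.
#' @param mean_household_size mean persons per household (household size is
#'   1 + Poisson(mean - 1)).
#' @return object of class `survey_design_spec`.
#' @export
survey_design_spec <- function(psus_per_stratum = 100, psus_sampled = 20,
                               households_per_psu = 40, households_sampled = 25,
                               mean_household_size = 5) {
  if (psus_sampled > psus_per_stratum) {
    stop("psus_sampled must be <= psus_per_stratum")
  }
  if (households_sampled > households_per_psu) {
    stop("households_sampled must be <= households_per_psu")
  }
  if (psus_sampled < 1 || households_sampled < 1 || mean_household_size < 1) {
    stop("sample sizes and household size must be >= 1")
  }
  structure(list(psus_per_stratum = as.integer(psus_per_stratum),
                 psus_sampled = as.integer(psus_sampled),
                 households_per_psu = as.integer(households_per_psu),
                 households_sampled = as.integer(households_sampled),
                 mean_household_size = mean_household_size),
            class = "survey_design_spec")
}

#' Synthetic country specification
#'
#' Fully determines a synthetic country: a rectangular admin hierarchy tiling
#' a template grid, per-unit exponential age pyramids and sex splits, a
#' population-count surface, and census / household-survey samples. One
#' global seed drives everything; each generator stage uses a fixed substream
#' offset so stages can be regenerated independently.
#'
#' Defaults emulate the structure of the real inputs: census microdata
#' sampled at 10% of the population (typical census microdata cover 2-15%),
#' a two-stage stratified cluster survey interviewing roughly 1% of each
#' stratum, and admin-1-level survey representativeness.
#'
#' @param seed integer master seed.
#' @param n_admin1 number of admin-1 units (horizontal bands of the grid).
#' @param n_admin2_per_admin1 admin-2 units per admin-1 (vertical slices).
#' @param grid a `grid_template`; rows must divide by `n_admin1` and columns
#'   by `n_admin2_per_admin1`.
#' @param total_population country population, persons.
#' @param pyramid_decay per-unit decay rho (scalar recycled or one value per
#'   admin-2 unit); default drawn from the seed, uniform on [0.05, 0.30].
#' @param male_share per-unit male fraction in (0,1); default drawn from the
#'   seed, uniform on [0.47, 0.53].
#' @param census_sample_fraction person sampling fraction in (0, 1].
#' @param survey_design a [survey_design_spec()].
#' @param defacto_prob probability a sampled person is a de-facto member.
#' @return object of class `synthetic_country_spec`.
#' @export
synthetic_country_spec <- function(seed = 1L,
                                   n_admin1 = 4L,
                                   n_admin2_per_admin1 = 4L,
                                   grid = grid_template(west = 30, north = 10,
                                                        resolution = 1 / 120,
                                                        n_rows = 40, n_cols = 40),
                                   total_population = 1e6,
                                   pyramid_decay = NULL,
                                   male_share = NULL,
                                   census_sample_fraction = 0.10,
                                   survey_design = survey_design_spec(),
                                   defacto_prob = 0.95) {
  if (total_population <= 0) stop("total_population must be > 0")
  if (census_sample_fraction <= 0 || census_sample_fraction > 1) {
    stop("census_sample_fraction must be in (0, 1]")
  }
  if (defacto_prob <= 0 || defacto_prob > 1) {
    stop("defacto_prob must be in (0, 1]")
  }
  if (grid$n_rows %% n_admin1 != 0) {
    stop(sprintf("grid rows (%d) not divisible by n_admin1 (%d)",
                 grid$n_rows, n_admin1))
  }
  if (grid$n_cols %% n_admin2_per_admin1 != 0) {
    stop(sprintf("grid columns (%d) not divisible by n_admin2_per_admin1 (%d)",
                 grid$n_cols, n_admin2_per_admin1))
  }
  n_units <- n_admin1 * n_admin2_per_admin1
  # defaults come from a fixed substream of the master seed; the stream
  # consumption (2 * n_units uniforms) is the same whether or not defaults
  # are overridden, keeping later stages reproducible either way
  set.seed(substream(seed, "structure"))
  rho_default <- stats::runif(n_units, 0.05, 0.30)
  male_default <- stats::runif(n_units, 0.47, 0.53)
  if (is.null(pyramid_decay)) pyramid_decay <- rho_default
  pyramid_decay <- rep_len(pyramid_decay, n_units)
  if (any(!is.finite(pyramid_decay)) || any(pyramid_decay < 0)) {
    stop("pyramid_decay must be finite and >= 0")
  }
  if (is.null(male_share)) male_share <- male_default
  male_share <- rep_len(male_share, n_units)
  if (any(male_share <= 0) || any(male_share >= 1)) {
    stop("male_share must lie in (0, 1)")
  }
  stopifnot(inherits(survey_design, "survey_design_spec"))
  structure(list(seed = as.integer(seed), n_admin1 = as.integer(n_admin1),
                 n_admin2_per_admin1 = as.integer(n_admin2_per_admin1),
                 grid = grid, total_population = total_population,
                 pyramid_decay = pyramid_decay, male_share = male_share,
                 census_sample_fraction = census_sample_fraction,
                 survey_design = survey_design, defacto_prob = defacto_prob),
            class = "synthetic_country_spec")
}

synthetic_unit_ids <- function(spec) {
  a1 <- rep(seq_len(spec$n_admin1), each = spec$n_admin2_per_admin1)
  a2 <- rep(seq_len(spec$n_admin2_per_admin1), times = spec$n_admin1)
  list(unit_id = sprintf("U%02d%02d", a1, a2),
       admin1_id = sprintf("S%02d", a1), a1 = a1, a2 = a2)
}

#' Generate the rectangular admin mosaic of a synthetic country
#'
#' Splits the grid extent into `n_admin1` horizontal bands and each band into
#' `n_admin2_per_admin1` vertical rectangles, all grid-cell aligned, exactly
#' tiling the extent with no overlap.
#'
#' @param spec a `synthetic_country_spec`.
#' @return an `admin_boundary_set` in unit order (admin-1 major).
#' @export
generate_admin_mosaic <- function(spec) {
  g <- spec$grid
  rows_per_band <- g$n_rows / spec$n_admin1
  cols_per_unit <- g$n_cols / spec$n_admin2_per_admin1
  ids <- synthetic_unit_ids(spec)
  rings <- vector("list", length(ids$unit_id))
  for (i in seq_along(ids$unit_id)) {
    x0 <- g$west + (ids$a2[i] - 1) * cols_per_unit * g$resolution
    x1 <- g$west + ids$a2[i] * cols_per_unit * g$resolution
    y1 <- g$north - (ids$a1[i] - 1) * rows_per_band * g$resolution
    y0 <- g$north - ids$a1[i] * rows_per_band * g$resolution
    rings[[i]] <- matrix(c(x0, y0, x1, y0, x1, y1, x0, y1),
                         ncol = 2, byrow = TRUE)
  }
  admin_boundary_set(
    data.frame(unit_id = ids$unit_id, admin1_id = ids$admin1_id,
               stringsAsFactors = FALSE),
    rings)
}

#' Generate the true age/sex structure of a synthetic country
#'
#' Each admin-2 unit gets an exponential pyramid (decay `rho`) and a sex
#' split applied uniformly across age bins. The structure carries two layers:
#' the exact fractions (`p_exact`, rows sum to 1) and their largest-remainder
#' integer realization as person counts (`counts`, rows sum to the unit
#' population), because a finite population cannot carry the exact fractions.
#' Unit populations apportion `total_population` by seeded log-normal size
#' weights.
#'
#' @param spec a `synthetic_country_spec`.
#' @return object of class `true_structure`: `$units` (unit_id, admin1_id,
#'   pop, rho, male_share), `$p_exact` and `$counts` (units x 28 matrices,
#'   columns `M_A0004` ... `F_A65PL`).
#' @export
generate_true_structure <- function(spec) {
  ids <- synthetic_unit_ids(spec)
  n <- length(ids$unit_id)
  set.seed(substream(spec$seed, "structure"))
  # burn the draws the spec constructor consumed for defaults
  stats::runif(2 * n)
  size_w <- stats::rlnorm(n, meanlog = 0, sdlog = 0.5)
  pop <- largest_remainder(size_w, spec$total_population)
  labs <- age_schema()$label
  cols <- c(paste0("M_", labs), paste0("F_", labs))
  p_exact <- matrix(0, n, 28, dimnames = list(ids$unit_id, cols))
  counts <- matrix(0L, n, 28, dimnames = list(ids$unit_id, cols))
  for (i in seq_len(n)) {
    p_age <- pyramid_proportions(spec$pyramid_decay[i])
    p <- c(p_age * spec$male_share[i], p_age * (1 - spec$male_share[i]))
    p_exact[i, ] <- p
    counts[i, ] <- largest_remainder(p, pop[i])
  }
  structure(list(
    units = data.frame(unit_id = ids$unit_id, admin1_id = ids$admin1_id,
                       pop = pop, rho = spec$pyramid_decay,
                       male_share = spec$male_share,
                       stringsAsFactors = FALSE),
    p_exact = p_exact, counts = counts), class = "true_structure")
}

#' Standard table of the true structure
#'
#' Tabulates the realized person counts of a `true_structure` into the
#' standard age/sex percentage schema, at admin-2 or admin-1 level (admin-1
#' aggregates member units' counts, so it is the population-weighted truth a
#' survey representative at admin-1 estimates).
#'
#' @param structure a `true_structure`.
#' @param level `"admin2"` or `"admin1"`.
#' @param name value for the `NAME` column.
#' @return a standard age/sex table (full precision).
#' @export
true_standard_table <- function(structure, level = c("admin2", "admin1"),
                                name = "synthetic") {
  level <- match.arg(level)
  counts <- structure$counts
  units <- structure$units$unit_id
  if (level == "admin1") {
    counts <- rowsum(counts, structure$units$admin1_id)
    units <- rownames(counts)
  }
  labs <- age_schema()$label
  m <- counts[, paste0("M_", labs), drop = FALSE]
  f <- counts[, paste0("F_", labs), drop = FALSE]
  total <- rowSums(m) + rowSums(f)
  out <- data.frame(NAME = name, ADM_NAME = units,
                    MPROP = 100 * rowSums(m) / total,
                    FPROP = 100 * rowSums(f) / total,
                    stringsAsFactors = FALSE)
  age_pct <- 100 * (m + f) / total
  colnames(age_pct) <- labs
  rownames(out) <- NULL
  cbind(out, as.data.frame(age_pct, row.names = FALSE))
}

#' Generate the population-count grid of a synthetic country
#'
#' Apportions each unit's true population over the unit's grid cells:
#' uniformly (largest remainder of equal shares) or with seeded multinomial
#' spatial noise over seeded gamma cell weights. Per-unit cell sums equal
#' unit populations exactly; cells outside the extent would be nodata (the
#' mosaic tiles the extent, so none are).
#'
#' @param spec a `synthetic_country_spec`.
#' @param boundaries the unit mosaic from [generate_admin_mosaic()].
#' @param structure the truth from [generate_true_structure()].
#' @param uniform if `TRUE`, apportion evenly across the unit's cells.
#' @return a count `raster_layer` on `spec$grid`.
#' @export
generate_population_grid <- function(spec, boundaries, structure,
                                     uniform = FALSE) {
  zones <- rasterize_zones(boundaries, spec$grid)
  z <- as.vector(zones$values)
  v <- rep(spec$grid$nodata, length(z))
  set.seed(substream(spec$seed, "popgrid"))
  for (i in seq_len(nrow(structure$units))) {
    cells <- which(z == i)
    if (length(cells) == 0) {
      stop("unit has no grid cells: ", structure$units$unit_id[i])
    }
    pop <- structure$units$pop[i]
    if (uniform) {
      v[cells] <- largest_remainder(rep(1, length(cells)), pop)
    } else {
      w <- stats::rgamma(length(cells), shape = 1, rate = 1)
      v[cells] <- as.vector(stats::rmultinom(1, size = pop, prob = w / sum(w)))
    }
  }
  raster_layer(spec$grid, matrix(v, spec$grid$n_rows, spec$grid$n_cols),
               semantics = "count")
}

# Draw a uniform integer age within each bin; the open 65+ bin draws
# uniformly on 65-84. Rebinned results are invariant to this choice.
draw_age_in_bin <- function(bin, schema = age_schema()) {
  lo <- schema$lo[bin]
  hi <- ifelse(is.finite(schema$hi[bin]), schema$hi[bin], 85)
  lo + floor(stats::runif(length(bin)) * (hi - lo))
}

#' Sample census-style person microdata
#'
#' Each member of the realized population is included independently with the
#' given probability, so expected per-unit sample size is fraction x unit
#' population and fraction = 1 returns the full population. Rows carry the
#' admin-2 unit, an integer age drawn uniformly within the person's bin, and
#' sex.
#'
#' @param structure a `true_structure`.
#' @param fraction sampling fraction in (0, 1].
#' @param seed integer seed (the census substream of the master seed is used
#'   when a `synthetic_country_spec` is passed).
#' @return person microdata data frame: `unit_id`, `age`, `sex`.
#' @export
sample_census_microdata <- function(structure, fraction, seed) {
  if (fraction <= 0 || fraction > 1) stop("fraction must be in (0, 1]")
  if (inherits(seed, "synthetic_country_spec")) {
    seed <- substream(seed$seed, "census")
  }
  set.seed(seed)
  counts <- structure$counts
  n_cells <- length(counts)
  k <- if (fraction == 1) as.vector(counts) else {
    stats::rbinom(n_cells, size = as.vector(counts), prob = fraction)
  }
  # expand (unit, bin-sex cell) pairs, one row per sampled person
  unit_idx <- rep(as.vector(row(counts)), times = k)
  cell_idx <- rep(as.vector(col(counts)), times = k)
  bin <- ifelse(cell_idx > 14, cell_idx - 14L, cell_idx)
  sex <- ifelse(cell_idx > 14, "female", "male")
  out <- data.frame(unit_id = structure$units$unit_id[unit_idx],
                    age = draw_age_in_bin(bin), sex = sex,
                    stringsAsFactors = FALSE)
  out[order(out$unit_id), , drop = FALSE]
}

#' Sample two-stage stratified household-survey microdata
#'
#' Strata are the admin-1 units. Within each stratum, PSUs and then
#' households are drawn by simple random sampling without replacement at the
#' design's rates; every member of a sampled household becomes a row with
#' weight 1 / (pi_psu * pi_hh), stratum and PSU identifiers, and a Bernoulli
#' de-facto flag. Household sizes are 1 + Poisson(mean_household_size - 1);
#' member ages and sexes are i.i.d. draws from the stratum's realized
#' pyramid, so the design is unbiased for the admin-1 structure (household
#' clustering of ages is not emulated; see the package vignette).
#'
#' @param structure a `true_structure`.
#' @param design a [survey_design_spec()].
#' @param defacto_prob Bernoulli probability of the de-facto flag.
#' @param seed integer seed (or a `synthetic_country_spec`, whose survey
#'   substream is used).
#' @return person microdata: `unit_id` (admin-1), `age`, `sex`, `weight`,
#'   `stratum_id`, `psu_id`, `de_facto`.
#' @export
sample_survey_microdata <- function(structure, design, defacto_prob, seed) {
  stopifnot(inherits(design, "survey_design_spec"))
  if (defacto_prob <= 0 || defacto_prob > 1) {
    stop("defacto_prob must be in (0, 1]")
  }
  if (inherits(seed, "synthetic_country_spec")) {
    seed <- substream(seed$seed, "survey")
  }
  set.seed(seed)
  strata <- sort(unique(structure$units$admin1_id))
  counts1 <- rowsum(structure$counts, structure$units$admin1_id)
  pi_psu <- design$psus_sampled / design$psus_per_stratum
  pi_hh <- design$households_sampled / design$households_per_psu
  w <- 1 / (pi_psu * pi_hh)
  labs <- age_schema()$label
  pieces <- vector("list", length(strata) * design$psus_sampled)
  k <- 0
  for (s in strata) {
    p <- counts1[s, ] / sum(counts1[s, ])
    psus <- sort(sample.int(design$psus_per_stratum, design$psus_sampled))
    for (psu in psus) {
      hh_sizes <- 1 + stats::rpois(design$households_sampled,
                                   design$mean_household_size - 1)
      n_persons <- sum(hh_sizes)
      cell <- sample.int(28, n_persons, replace = TRUE, prob = p)
      bin <- ifelse(cell > 14, cell - 14L, cell)
      k <- k + 1
      pieces[[k]] <- data.frame(
        unit_id = s,
        age = draw_age_in_bin(bin),
        sex = ifelse(cell > 14, "female", "male"),
        weight = w,
        stratum_id = s,
        psu_id = sprintf("%s_P%03d", s, psu),
        hh_id = rep(seq_along(hh_sizes), times = hh_sizes),
        de_facto = stats::runif(n_persons) < defacto_prob,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, pieces)
}

#' Simulate a complete synthetic country
#'
#' Runs all generator stages: mosaic, true structure, population grid, ISO
#' mask (a single country code over the extent), census microdata and survey
#' microdata.
#'
#' @param spec a `synthetic_country_spec`.
#' @param iso_code integer country code for the mask.
#' @param uniform_grid apportion population uniformly over cells.
#' @return list with `spec`, `boundaries`, `structure`, `population`
#'   (raster), `iso` (raster), `census`, `survey`.
#' @export
simulate_country <- function(spec, iso_code = 1L, uniform_grid = FALSE) {
  boundaries <- generate_admin_mosaic(spec)
  structure <- generate_true_structure(spec)
  population <- generate_population_grid(spec, boundaries, structure,
                                         uniform = uniform_grid)
  iso <- raster_layer(spec$grid, iso_code, semantics = "iso")
  census <- sample_census_microdata(structure, spec$census_sample_fraction,
                                    spec)
  survey <- sample_survey_microdata(structure, spec$survey_design,
                                    spec$defacto_prob, spec)
  list(spec = spec, boundaries = boundaries, structure = structure,
       population = population, iso = iso, census = census, survey = survey)
}
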