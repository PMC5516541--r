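#' Conservation audit of a gridded age/sex stack
#'
#' The production check on the gridded outputs: all age/sex count layers are
#' summed into a single surface and subtracted from the population-count
#' layer cellwise, and per-country zonal totals are compared with the
#' national reference estimates.
#'
#' @param agc_stack named list of count `raster_layer`s (all age/sex groups).
#' @param wppc the population-count `raster_layer` the stack was derived
#'   from.
#' @param iso aligned integer country-code layer.
#' @param targets named numeric vector of national reference totals.
#' @param tol relative tolerance for both checks.
#' @return object of class `conservation_report`: `$cellwise` (max absolute
#'   and relative cell deviation, pass flag) and `$countries` (per-country
#'   totals vs targets; countries with no data cells reported with
#'   `status = "no-data"`).
#' @export
audit_conservation <- function(agc_stack, wppc, iso, targets, tol = 1e-6) {
  total <- Reduce(`+`, lapply(agc_stack, values_or_na))
  pop <- values_or_na(wppc)
  data <- !is.na(total) & !is.na(pop)
  dev <- total[data] - pop[data]
  rel <- abs(dev) / pmax(abs(pop[data]), 1)
  cellwise <- list(max_abs_dev = max(abs(dev)), max_rel_dev = max(rel),
                   pass = all(rel <= tol))
  sums <- zonal_sum(raster_layer(wppc$template,
                                 ifelse(is.na(total), wppc$template$nodata,
                                        total),
                                 semantics = "count"),
                    iso)
  codes <- union(names(targets), names(sums))
  countries <- data.frame(country = codes,
                          total = as.numeric(sums[codes]),
                          target = as.numeric(targets[codes]),
                          stringsAsFactors = FALSE)
  countries$rel_dev <- abs(countries$total - countries$target) /
    pmax(abs(countries$target), 1)
  countries$status <- ifelse(is.na(countries$total), "no-data",
                             ifelse(countries$rel_dev <= tol, "pass", "fail"))
  structure(list(cellwise = cellwise, countries = countries, tol = tol),
            class = "conservation_report")
}

#' @export
print.conservation_report <- function(x, ...) {
  cat(sprintf("conservation audit (tol %.1g): cellwise max rel dev %.3g [%s]\n",
              x$tol, x$cellwise$max_rel_dev,
              if (x$cellwise$pass) "pass" else "FAIL"))
  for (i in seq_len(nrow(x$countries))) {
    cat(sprintf("  country %s: total %.6g vs target %.6g [%s]\n",
                x$countries$country[i], x$countries$total[i],
                x$countries$target[i], x$countries$status[i]))
  }
  invisible(x)
}

#' Compare subnational ratio values to a national reference
#'
#' Five-number summary of the unit-level values (unweighted across units,
#' linear-interpolation quantiles) with a flag raised when the national
#' reference falls outside the interquartile range -- the signature of
#' national averages dominated by dense areas.
#'
#' @param values numeric vector of unit-level ratio values for one country.
#' @param reference the national reference value (user supplied).
#' @return data frame with `min`, `q1`, `median`, `q3`, `max`, `n_units`,
#'   `reference`, `reference_outside_iqr`.
#' @export
compare_to_national <- function(values, reference) {
  values <- values[!is.na(values)]
  if (length(values) == 0) stop("no unit values supplied")
  q <- stats::quantile(values, probs = c(0, 0.25, 0.5, 0.75, 1),
                       names = FALSE, type = 7)
  data.frame(min = q[1], q1 = q[2], median = q[3], q3 = q[4], max = q[5],
             n_units = length(values), reference = reference,
             reference_outside_iqr = reference < q[2] | reference > q[4])
}

#' Between-round differences in age-group percentage points
#'
#' For two rounds of per-region proportional age structures on the fine
#' 17-bin schema, computes the signed percentage-point difference
#' round2 - round1 per region and age group, plus a `Total` row computed from
#' country-pooled proportions (pooling regional counts by the supplied
#' per-region totals), not from the mean of regional differences. Because
#' both rounds sum to 100 per region, each row of differences sums to ~0.
#'
#' @param std_t1,std_t2 data frames with a `region` column, a `total` column
#'   (persons or weighted persons, used for country pooling) and one percent
#'   column per 17-bin label (see [age_schema_17()]).
#' @return data frame: `region` (regions then `"Total"`) and the 17 signed
#'   difference columns.
#' @export
round_difference <- function(std_t1, std_t2) {
  labs <- age_schema_17()$label
  for (tab in list(std_t1, std_t2)) {
    miss <- setdiff(c("region", "total", labs), names(tab))
    if (length(miss) > 0) {
      stop("round table missing columns: ", paste(miss, collapse = ", "))
    }
  }
  extra1 <- setdiff(std_t1$region, std_t2$region)
  extra2 <- setdiff(std_t2$region, std_t1$region)
  if (length(extra1) > 0 || length(extra2) > 0) {
    stop("mismatched region sets; only in round 1: [",
         paste(extra1, collapse = ", "), "]; only in round 2: [",
         paste(extra2, collapse = ", "), "]")
  }
  std_t2 <- std_t2[match(std_t1$region, std_t2$region), , drop = FALSE]
  diff <- as.matrix(std_t2[, labs]) - as.matrix(std_t1[, labs])
  pooled <- function(tab) {
    counts <- as.matrix(tab[, labs]) * tab$total / 100
    100 * colSums(counts) / sum(tab$total)
  }
  total_row <- pooled(std_t2) - pooled(std_t1)
  out <- data.frame(region = c(std_t1$region, "Total"),
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(rbind(diff, total_row), row.names = FALSE,
                           check.names = FALSE))
}

#' End-to-end parameter-recovery harness
#'
#' Runs the full pipeline on a synthetic country -- simulate, tabulate (by
#' data route), derive ratios, rasterize, disaggregate, audit -- and reports
#' the maximum absolute error of recovered proportions and ratios against
#' the realized true structure, per route.
#'
#' @param spec a `synthetic_country_spec`.
#' @param routes character subset of `c("census_table", "census_microdata",
#'   "survey")`.
#' @return list with per-route elements: `max_abs_err_pct` (percentage
#'   points, over all units x bins incl. MPROP/FPROP), `max_abs_err_ydr`,
#'   plus `conservation` (the grid audit) when the census table route runs.
#' @export
recover_parameters <- function(spec,
                               routes = c("census_table", "census_microdata",
                                          "survey")) {
  routes <- match.arg(routes, several.ok = TRUE)
  country <- simulate_country(spec)
  labs <- age_schema()$label
  truth2 <- true_standard_table(country$structure, "admin2")
  truth1 <- true_standard_table(country$structure, "admin1")
  err <- function(est, truth) {
    est <- est[match(truth$ADM_NAME, est$ADM_NAME), , drop = FALSE]
    cols <- c("MPROP", "FPROP", labs)
    prop_err <- max(abs(as.matrix(est[, cols]) - as.matrix(truth[, cols])))
    r_est <- compute_ratios(derive_triple(est))
    r_true <- compute_ratios(derive_triple(truth))
    list(max_abs_err_pct = prop_err,
         max_abs_err_ydr = max(abs(r_est$YDR - r_true$YDR)))
  }
  out <- list()
  if ("census_table" %in% routes) {
    # full-population tabulation standardised through the table route,
    # then gridded and audited
    census_full <- sample_census_microdata(country$structure, 1,
                                           substream(spec$seed, "census"))
    tab <- as_standard_table(tabulate_census_microdata(census_full))
    out$census_table <- err(tab, truth2)

    b <- country$boundaries
    for (lab in labs) b$units[[lab]] <- tab[[lab]][match(b$units$unit_id,
                                                         tab$ADM_NAME)] / 100
    b$units$MSHARE <- tab$MPROP[match(b$units$unit_id, tab$ADM_NAME)] / 100
    b$units$FSHARE <- 1 - b$units$MSHARE
    agp <- lapply(labs, function(l) rasterize_attribute(b, l, spec$grid))
    names(agp) <- labs
    sexl <- list(M = rasterize_attribute(b, "MSHARE", spec$grid),
                 F = rasterize_attribute(b, "FSHARE", spec$grid))
    targets <- c("1" = sum(country$structure$units$pop))
    pop_adj <- adjust_to_national_totals(country$population, country$iso,
                                         targets)
    agc <- disaggregate_age_sex(agp, pop_adj, sex_layers = sexl)
    out$conservation <- audit_conservation(agc, pop_adj, country$iso, targets)

    # zonal recovery: per-unit age-group sums vs unit population x true share
    zones <- rasterize_zones(country$boundaries, spec$grid)
    zerr <- 0
    for (g in seq_along(labs)) {
      zs <- zonal_sum(agc[[paste0("M_", labs[g])]], zones) +
        zonal_sum(agc[[paste0("F_", labs[g])]], zones)
      expected <- country$structure$units$pop *
        (tab[[labs[g]]][match(country$structure$units$unit_id,
                              tab$ADM_NAME)] / 100)
      zerr <- max(zerr, max(abs(zs - expected) / pmax(expected, 1)))
    }
    out$zonal_max_rel_err <- zerr
  }
  if ("census_microdata" %in% routes) {
    tab <- as_standard_table(
      tabulate_census_microdata(country$census))
    out$census_microdata <- err(tab, truth2)
  }
  if ("survey" %in% routes) {
    tab <- as_standard_table(tabulate_weighted_survey(country$survey))
    out$survey <- err(tab, truth1)
  }
  out
}
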