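#' Rebin a raw age table onto the standard 14-bin schema
#'
#' Raw subnational tables arrive with heterogeneous age intervals: single
#' years, 5-year groups, or finer splits, with an open top bin anywhere at or
#' above 65. This maps every raw interval into the standard schema. A raw
#' interval must nest inside a single standard bin (or lie entirely at
#' age >= 65); no interpolation is performed across non-nested intervals.
#'
#' @param raw data frame with columns `NAME`, `ADM_NAME`, `age_lo`
#'   (inclusive, integer years), `age_hi` (exclusive; `Inf` or `NA` for an
#'   open interval) and `value` (count or percentage).
#' @param schema the standard schema, from [age_schema()].
#' @return data frame with one row per unit: `NAME`, `ADM_NAME` and the 14
#'   schema columns; values are summed raw values (totals conserved exactly).
#' @export
rebin_to_schema <- function(raw, schema = age_schema()) {
  req <- c("NAME", "ADM_NAME", "age_lo", "age_hi", "value")
  if (!all(req %in% names(raw))) {
    stop("raw table must have columns: ", paste(req, collapse = ", "))
  }
  raw$age_hi[is.na(raw$age_hi)] <- Inf
  if (any(raw$age_lo < 0) || any(raw$age_lo >= raw$age_hi)) {
    stop("invalid age interval: require 0 <= age_lo < age_hi")
  }
  if (any(raw$age_lo != floor(raw$age_lo)) ||
      any(is.finite(raw$age_hi) & raw$age_hi != floor(raw$age_hi))) {
    stop("age interval boundaries must be whole years")
  }
  open_top <- schema$lo[nrow(schema)]
  # bin of the interval start; intervals at or above the open bin all collapse
  bin_lo <- findInterval(pmin(raw$age_lo, open_top), schema$lo)
  bin_hi_end <- pmin(ifelse(is.finite(raw$age_hi), raw$age_hi - 1, open_top),
                     open_top)
  bin_hi <- findInterval(bin_hi_end, schema$lo)
  bad <- which(bin_lo != bin_hi)
  if (length(bad) > 0) {
    b <- bad[1]
    stop(sprintf(
      "non-nestable interval [%s, %s) in unit %s/%s straddles a 5-year boundary",
      raw$age_lo[b], raw$age_hi[b], raw$NAME[b], raw$ADM_NAME[b]))
  }
  key <- paste(raw$NAME, raw$ADM_NAME, sep = "\r")
  units <- unique(key)
  out <- matrix(0, nrow = length(units), ncol = nrow(schema),
                dimnames = list(NULL, schema$label))
  for (i in seq_along(raw$value)) {
    u <- match(key[i], units)
    out[u, bin_lo[i]] <- out[u, bin_lo[i]] + raw$value[i]
  }
  first <- match(units, key)
  cbind(data.frame(NAME = raw$NAME[first], ADM_NAME = raw$ADM_NAME[first],
                   stringsAsFactors = FALSE),
        as.data.frame(out))
}

#' Convert per-unit binned counts to the standard percentage table
#'
#' Divides each unit's 14 bin counts by the unit total and scales to
#' percent. The male/female split is taken from optional `male`/`female`
#' count columns; if absent an even 50/50 split is recorded. Values are kept
#' at full precision; rounding to 1 decimal happens only on export
#' ([write_standard_table()]).
#'
#' @param binned data frame from [rebin_to_schema()] (counts), optionally
#'   with `male` and `female` per-unit count columns.
#' @return a standard age/sex table: `NAME`, `ADM_NAME`, `MPROP`, `FPROP`,
#'   `A0004` ... `A65PL`, all in percent.
#' @export
counts_to_percentages <- function(binned) {
  labs <- age_schema()$label
  if (!all(labs %in% names(binned))) stop("binned table missing schema columns")
  counts <- as.matrix(binned[, labs])
  total <- rowSums(counts)
  if (any(total <= 0)) {
    bad <- which(total <= 0)[1]
    stop(sprintf("unit %s/%s has zero total count",
                 binned$NAME[bad], binned$ADM_NAME[bad]))
  }
  pct <- 100 * counts / total
  if (all(c("male", "female") %in% names(binned))) {
    mf <- binned$male + binned$female
    if (any(mf <= 0)) stop("male + female must be positive where supplied")
    mprop <- 100 * binned$male / mf
  } else {
    mprop <- rep(50, nrow(binned))
  }
  out <- data.frame(NAME = binned$NAME, ADM_NAME = binned$ADM_NAME,
                    MPROP = mprop, FPROP = 100 - mprop,
                    stringsAsFactors = FALSE)
  cbind(out, as.data.frame(pct))
}

#' QA check of a standard age/sex table
#'
#' Verifies per unit that (i) the 14 age-group percentages sum to 100 and
#' (ii) MPROP + FPROP sum to 100, within `tol` percentage points (the default
#' absorbs 1-decimal rounding of up to 16 addends).
#'
#' @param table a standard age/sex table.
#' @param tol tolerance in percentage points on both sum checks.
#' @param tolerate if `FALSE` (default) any failing unit raises an error
#'   (pipeline halt); if `TRUE` the report is returned with failures flagged.
#' @return data frame: `NAME`, `ADM_NAME`, `age_sum_dev`, `sex_sum_dev`,
#'   `age_ok`, `sex_ok`, `pass`.
#' @export
validate_standard_table <- function(table, tol = 0.15, tolerate = FALSE) {
  labs <- age_schema()$label
  age_dev <- rowSums(as.matrix(table[, labs])) - 100
  sex_dev <- table$MPROP + table$FPROP - 100
  rep <- data.frame(
    NAME = table$NAME, ADM_NAME = table$ADM_NAME,
    age_sum_dev = age_dev, sex_sum_dev = sex_dev,
    age_ok = abs(age_dev) <= tol, sex_ok = abs(sex_dev) <= tol,
    stringsAsFactors = FALSE)
  rep$pass <- rep$age_ok & rep$sex_ok
  if (!tolerate && !all(rep$pass)) {
    bad <- rep[!rep$pass, ]
    stop(sprintf(
      "standard table QA failed for %d unit(s), first: %s/%s (age dev %.3f, sex dev %.3f)",
      nrow(bad), bad$NAME[1], bad$ADM_NAME[1], bad$age_sum_dev[1], bad$sex_sum_dev[1]))
  }
  rep
}

#' Apply the uniform sex split to a standard table
#'
#' Most subnational sources report age structure for both sexes combined plus
#' a single two-way sex split; the split is therefore applied uniformly
#' across all age groups within each unit: share(g, male) = A_g * MPROP/100.
#' The male and female stacks re-sum to the age-only stack exactly.
#'
#' @param table a standard age/sex table (percent).
#' @return data frame with `NAME`, `ADM_NAME` and 28 percentage columns
#'   `M_A0004` ... `M_A65PL`, `F_A0004` ... `F_A65PL`.
#' @export
apply_uniform_sex_split <- function(table) {
  labs <- age_schema()$label
  a <- as.matrix(table[, labs])
  m <- a * table$MPROP / 100
  f <- a * table$FPROP / 100
  colnames(m) <- paste0("M_", labs)
  colnames(f) <- paste0("F_", labs)
  cbind(data.frame(NAME = table$NAME, ADM_NAME = table$ADM_NAME,
                   stringsAsFactors = FALSE),
        as.data.frame(m), as.data.frame(f))
}

#' Read / write standard age/sex tables
#'
#' CSV round trip in the standard dialect. `write_standard_table()` rounds
#' all percentage fields to 1 decimal on export; computation upstream is at
#' full precision.
#'
#' @param path file path.
#' @param table a standard age/sex table.
#' @return `read_standard_table()` returns the table as a data frame.
#' @export
read_standard_table <- function(path) {
  tab <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(standard_columns(), names(tab))
  if (length(miss) > 0) {
    stop("standard table missing columns: ", paste(miss, collapse = ", "))
  }
  tab[, standard_columns()]
}

#' @rdname read_standard_table
#' @export
write_standard_table <- function(table, path) {
  tab <- table[, standard_columns()]
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], round, digits = 1)
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
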