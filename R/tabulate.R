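#' Validate person-level microdata
#'
#' Person microdata have one row per person: administrative unit, age in
#' completed years, sex, and (for surveys) a sampling weight, design
#' identifiers and a de-facto residence flag. Missing survey columns are
#' filled with census defaults (weight 1, de facto TRUE).
#'
#' @param data data frame with columns `unit_id`, `age`, `sex`
#'   (`"male"`/`"female"`), and optionally `weight`, `stratum_id`, `psu_id`,
#'   `de_facto`.
#' @return the data with defaults filled, after validation.
#' @export
validate_microdata <- function(data) {
  req <- c("unit_id", "age", "sex")
  miss <- setdiff(req, names(data))
  if (length(miss) > 0) stop("microdata missing columns: ",
                             paste(miss, collapse = ", "))
  if (any(is.na(data$unit_id)) || any(data$unit_id == "")) {
    stop("unit_id must be non-empty")
  }
  if (any(data$age < 0) || any(data$age != floor(data$age))) {
    stop("age must be a non-negative integer")
  }
  if (any(!data$sex %in% c("male", "female"))) {
    stop("sex must be 'male' or 'female'")
  }
  if (is.null(data$weight)) data$weight <- 1
  if (any(data$weight <= 0)) stop("weights must be positive")
  if (is.null(data$de_facto)) data$de_facto <- TRUE
  data
}

# Shared core of the two tabulators: the indicator-column workflow.
# One binary column per (age bin x sex) cell is populated per person and
# summed by unit with the given weights; proportions divide by the per-unit
# weight total.
tabulate_indicators <- function(data, weights) {
  schema <- age_schema()
  labs <- schema$label
  bin <- age_to_bin(data$age, schema)
  units <- sort(unique(data$unit_id))
  u <- match(data$unit_id, units)
  nu <- length(units)

  # indicator matrix person x (14 bins + 2 sexes), 0/1
  ind <- matrix(0, nrow = nrow(data), ncol = 16,
                dimnames = list(NULL, c(labs, "male", "female")))
  ind[cbind(seq_len(nrow(data)), bin)] <- 1
  ind[cbind(seq_len(nrow(data)), 14L + (data$sex == "female") + 1L)] <- 1

  wsum <- rowsum(ind * weights, group = u, reorder = TRUE)
  total_w <- as.vector(rowsum(weights, group = u, reorder = TRUE))
  n <- as.vector(rowsum(rep(1L, nrow(data)), group = u, reorder = TRUE))

  pct_age <- 100 * wsum[, labs, drop = FALSE] / total_w
  mprop <- 100 * wsum[, "male"] / total_w

  result <- data.frame(unit_id = units, n = n, total_weight = total_w,
                       MPROP = unname(mprop), FPROP = 100 - unname(mprop),
                       stringsAsFactors = FALSE)
  result <- cbind(result, as.data.frame(pct_age))
  counts <- cbind(data.frame(unit_id = units, stringsAsFactors = FALSE),
                  as.data.frame(wsum))
  structure(list(proportions = result, weighted_counts = counts),
            class = "tabulation")
}

#' Tabulate census-style microdata into per-unit age/sex proportions
#'
#' Implements the standard census-microdata workflow: a binary indicator per
#' 5-year age group and sex class is populated for every person row, the
#' indicators are summed by administrative unit (the row count per unit gives
#' the total sampled population), and proportions are the sums divided by the
#' unit count. Weights and de-facto flags, if present, are ignored: census
#' microdata are self-weighting for this purpose.
#'
#' @param data person microdata (see [validate_microdata()]).
#' @param expected_units optional vector of unit ids that should be present;
#'   units with zero sampled records are excluded from the result with a
#'   warning and listed in the QA report attribute `empty_units`.
#' @return an object of class `tabulation`: `$proportions` holds per-unit
#'   percentages (`MPROP`, `FPROP`, `A0004` ... `A65PL`), sampled count `n`
#'   and `total_weight`; `$weighted_counts` the underlying per-unit sums.
#' @export
tabulate_census_microdata <- function(data, expected_units = NULL) {
  data <- validate_microdata(data)
  empty <- character(0)
  if (!is.null(expected_units)) {
    empty <- as.character(setdiff(expected_units, unique(data$unit_id)))
    if (length(empty) > 0) {
      warning("unit(s) with zero sampled records excluded: ",
              paste(empty, collapse = ", "))
    }
  }
  res <- tabulate_indicators(data, weights = rep(1, nrow(data)))
  res$mode <- "census"
  qa <- qaqc_tabulation(res)
  if (!all(qa$pass)) stop("internal QA failure in census tabulation")
  attr(qa, "empty_units") <- empty
  res$qa <- qa
  res
}

#' Tabulate weighted household-survey microdata
#'
#' Rows flagged as not de facto (the person did not sleep in the household
#' the night before the interview) are dropped first; sampling weights are
#' then applied so that weighted tallies estimate population quantities:
#' the percentage for age group g in unit a is
#' 100 * sum(w_i over rows in a with age in g) / sum(w_i over rows in a).
#' Stratum and PSU identifiers are carried for reporting only; point
#' estimates are produced, no design-based variances.
#'
#' @param data person microdata with `weight` and `de_facto` columns.
#' @return an object of class `tabulation` (see
#'   [tabulate_census_microdata()]), computed on de-facto rows only.
#' @export
tabulate_weighted_survey <- function(data) {
  if (is.null(data$weight)) stop("survey microdata must carry a weight column")
  if (is.null(data$de_facto)) stop("survey microdata must carry a de_facto flag")
  data <- validate_microdata(data)
  units_in <- unique(data$unit_id)
  data <- data[data$de_facto, , drop = FALSE]
  gone <- setdiff(units_in, unique(data$unit_id))
  if (length(gone) > 0) {
    stop("unit(s) with zero de-facto weight: ", paste(gone, collapse = ", "))
  }
  res <- tabulate_indicators(data, weights = data$weight)
  res$mode <- "survey"
  res$qa <- qaqc_tabulation(res)
  res
}

#' QA report for a tabulation
#'
#' Asserts, per unit, that the 14 weighted age-group sums add up to the unit
#' weight total and that male + female weighted sums do too (the two
#' bookkeeping identities of the tabulation workflow).
#'
#' @param result a `tabulation` object.
#' @param tol absolute tolerance on the weighted-sum identities.
#' @return data frame with per-unit deviations and pass/fail flags.
#' @export
qaqc_tabulation <- function(result, tol = 1e-9) {
  stopifnot(inherits(result, "tabulation"))
  labs <- age_schema()$label
  wc <- result$weighted_counts
  total <- result$proportions$total_weight
  age_dev <- rowSums(as.matrix(wc[, labs])) - total
  sex_dev <- wc$male + wc$female - total
  scale <- pmax(total, 1)
  rep <- data.frame(unit_id = wc$unit_id,
                    age_sum_dev = age_dev, sex_sum_dev = sex_dev,
                    age_ok = abs(age_dev) <= tol * scale,
                    sex_ok = abs(sex_dev) <= tol * scale,
                    stringsAsFactors = FALSE)
  rep$pass <- rep$age_ok & rep$sex_ok
  rep
}

#' Convert a tabulation to the standard age/sex table schema
#'
#' @param result a `tabulation` object.
#' @param name value for the `NAME` column (e.g. the country).
#' @return a standard age/sex table with one row per unit (`ADM_NAME` =
#'   unit id).
#' @export
as_standard_table <- function(result, name = "synthetic") {
  stopifnot(inherits(result, "tabulation"))
  p <- result$proportions
  out <- data.frame(NAME = name, ADM_NAME = as.character(p$unit_id),
                    MPROP = p$MPROP, FPROP = p$FPROP,
                    stringsAsFactors = FALSE)
  cbind(out, p[, age_schema()$label])
}
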