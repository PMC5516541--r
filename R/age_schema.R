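#' Standard 14-bin age schema
#'
#' The standard schema used throughout the pipeline: thirteen 5-year age
#' groups from 0-4 up to 60-64 plus an open-ended 65+ group. Labels follow
#' the standard table dialect (`A0004` ... `A65PL`).
#'
#' @return A data frame with columns `label`, `lo` (inclusive lower bound in
#'   years) and `hi` (exclusive upper bound; `Inf` for the open top bin).
#' @examples
#' age_schema()
#' @export
age_schema <- function() {
  lo <- c(seq(0, 60, by = 5), 65)
  hi <- c(seq(5, 65, by = 5), Inf)
  labels <- c(sprintf("A%02d%02d", lo[1:13], hi[1:13] - 1), "A65PL")
  data.frame(label = labels, lo = lo, hi = hi, stringsAsFactors = FALSE)
}

#' Fine 17-bin age schema for between-round comparisons
#'
#' Seventeen groups: `<5`, `5-9`, ..., `75-79`, `80+`. This is the finer
#' schema used for sensitivity comparisons of survey rounds over time.
#'
#' @return A data frame with columns `label`, `lo`, `hi` (`Inf` for `80+`).
#' @export
age_schema_17 <- function() {
  lo <- c(seq(0, 75, by = 5), 80)
  hi <- c(seq(5, 80, by = 5), Inf)
  labels <- c("<5", paste(lo[2:16], hi[2:16] - 1, sep = "-"), "80+")
  data.frame(label = labels, lo = lo, hi = hi, stringsAsFactors = FALSE)
}

#' Assign integer ages to schema bins
#'
#' @param age integer vector of ages in completed years (>= 0).
#' @param schema a schema data frame from [age_schema()] or [age_schema_17()].
#' @return integer vector of bin indices into `schema`.
#' @export
age_to_bin <- function(age, schema = age_schema()) {
  if (any(age < 0)) stop("ages must be >= 0")
  if (any(age != floor(age))) stop("ages must be integer years")
  idx <- findInterval(age, schema$lo)
  stopifnot(all(idx >= 1L), all(idx <= nrow(schema)))
  idx
}

# Column order of the standard per-unit table (Table-3 dialect).
standard_columns <- function() {
  c("NAME", "ADM_NAME", "MPROP", "FPROP", age_schema()$label)
}
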