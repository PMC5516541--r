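#' Load a source catalogue
#'
#' The catalogue records, per country, which kind of age/sex source feeds the
#' pipeline (full census table, census microdata, one of the household survey
#' programmes, or a UN national-level fallback), the collection year and the
#' administrative level of the data. Packaged catalogues for Africa and Asia
#' ship under `inst/extdata` (see [catalog_path()]).
#'
#' @param path CSV file with columns `country`, `continent`, `data_type`,
#'   `year`, `admin_level`, `source`.
#' @return validated data frame of catalogue entries.
#' @export
load_catalog <- function(path) {
  cat <- utils::read.csv(path, stringsAsFactors = FALSE)
  req <- c("country", "continent", "data_type", "year", "admin_level", "source")
  miss <- setdiff(req, names(cat))
  if (length(miss) > 0) {
    stop("catalogue missing columns: ", paste(miss, collapse = ", "))
  }
  if (nrow(cat) == 0) return(cat[, req])
  types <- c("Census", "Census microdata", "DHS", "MIS", "AIS", "SIS", "MICS", "UN")
  bad <- which(!cat$data_type %in% types)
  if (length(bad) > 0) {
    stop(sprintf("row %d: unknown data_type '%s'", bad[1], cat$data_type[bad[1]]))
  }
  bad <- which(!(cat$admin_level %in% 0:3))
  if (length(bad) > 0) {
    stop(sprintf("row %d: admin_level must be 0-3, got %s",
                 bad[1], cat$admin_level[bad[1]]))
  }
  # national fallback and level 0 imply each other
  bad <- which((cat$data_type == "UN") != (cat$admin_level == 0))
  if (length(bad) > 0) {
    stop(sprintf("row %d (%s): admin_level 0 iff data_type UN",
                 bad[1], cat$country[bad[1]]))
  }
  dup <- duplicated(cat$country)
  if (any(dup)) {
    stop("duplicate countries in catalogue: ",
         paste(unique(cat$country[dup]), collapse = ", "))
  }
  cat[, req]
}

#' Path to a packaged source catalogue
#'
#' @param continent `"africa"` or `"asia"`.
#' @return path to the packaged CSV.
#' @export
catalog_path <- function(continent = c("africa", "asia")) {
  continent <- match.arg(continent)
  system.file("extdata", paste0("sources_", continent, ".csv"),
              package = "agestruct", mustWork = TRUE)
}

#' Count catalogue entries by data type
#'
#' @param entries catalogue data frame from [load_catalog()].
#' @return named integer vector, one element per data type present; the
#'   counts sum to `nrow(entries)`.
#' @export
count_by_type <- function(entries) {
  tab <- table(entries$data_type)
  stats::setNames(as.integer(tab), names(tab))
}

#' Route a catalogue entry to its processing path
#'
#' Full census tables are standardised directly; census microdata go through
#' unweighted person-level tabulation; the household survey programmes (DHS,
#' MIS, AIS, SIS, MICS) through weighted de-facto tabulation; UN entries get
#' the national-level fallback.
#'
#' @param entry one catalogue row (or a data frame of rows).
#' @return character vector of routes: one of `"standardize_table"`,
#'   `"tabulate_census_microdata"`, `"tabulate_weighted_survey"`,
#'   `"national_fallback"`.
#' @export
route_entry <- function(entry) {
  routes <- c(
    "Census" = "standardize_table",
    "Census microdata" = "tabulate_census_microdata",
    "DHS" = "tabulate_weighted_survey",
    "MIS" = "tabulate_weighted_survey",
    "AIS" = "tabulate_weighted_survey",
    "SIS" = "tabulate_weighted_survey",
    "MICS" = "tabulate_weighted_survey",
    "UN" = "national_fallback")
  if (any(!entry$data_type %in% names(routes))) {
    stop("unknown data_type: ",
         paste(setdiff(entry$data_type, names(routes)), collapse = ", "))
  }
  unname(routes[entry$data_type])
}
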