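#' Derive the dependency proportion triple from a standard table
#'
#' Collapses the 14 age-group percentages of each unit into the three broad
#' groups that define dependency ratios: ages 0-14 (A0004 + A0509 + A1014),
#' working ages 15-64 (the ten middle groups) and ages 65 and over (A65PL).
#' When a row passes the sum QA the middle share equals the complement
#' 100 - pc0_14 - pc65; rows failing QA get the explicit middle-field sum
#' with a warning. Rows missing any middle field (partial tables) use the
#' complement, which is exact whenever the full row sums to 100.
#'
#' @param table a standard age/sex table (percent).
#' @param tol tolerance used for the internal sum QA.
#' @return data frame with `NAME`, `ADM_NAME`, `pc0_14`, `pc15_64`, `pc65`
#'   and a logical `undefined` flag marking units with no working-age share.
#' @export
derive_triple <- function(table, tol = 0.15) {
  labs <- age_schema()$label
  young <- c("A0004", "A0509", "A1014")
  mid <- setdiff(labs, c(young, "A65PL"))
  pc0_14 <- rowSums(as.matrix(table[, young]))
  pc65 <- table[["A65PL"]]
  if (all(mid %in% names(table))) {
    explicit <- rowSums(as.matrix(table[, mid]))
    row_ok <- abs(pc0_14 + explicit + pc65 - 100) <= tol
    if (any(!row_ok)) {
      warning(sprintf(
        "%d unit(s) fail the 100%% sum check; using explicit working-age sum",
        sum(!row_ok)))
    }
    pc15_64 <- explicit
  } else {
    pc15_64 <- 100 - pc0_14 - pc65
  }
  out <- data.frame(NAME = table$NAME, ADM_NAME = table$ADM_NAME,
                    pc0_14 = pc0_14, pc15_64 = pc15_64, pc65 = pc65,
                    stringsAsFactors = FALSE)
  out$undefined <- out$pc15_64 <= 0
  if (any(out$undefined)) {
    warning("unit(s) with zero working-age share flagged: ",
            paste(out$ADM_NAME[out$undefined], collapse = ", "))
  }
  out
}

#' Compute combined, young-age and old-age dependency ratios
#'
#' For each unit: YDR = (pc0_14 / pc15_64) x 100, ODR = (pc65 / pc15_64) x
#' 100, CDR = ((pc0_14 + pc65) / pc15_64) x 100 = YDR + ODR. The triple may
#' be in percent or fractions; the ratios are scale invariant.
#'
#' @param triple data frame with `pc0_14`, `pc15_64`, `pc65` (from
#'   [derive_triple()] or supplied directly).
#' @return data frame with the triple's identifier columns plus `CDR`,
#'   `YDR`, `ODR` at full precision (round on export only).
#' @export
compute_ratios <- function(triple) {
  req <- c("pc0_14", "pc15_64", "pc65")
  if (!all(req %in% names(triple))) {
    stop("triple must have columns pc0_14, pc15_64, pc65")
  }
  if (any(triple$pc15_64 <= 0)) {
    bad <- which(triple$pc15_64 <= 0)[1]
    id <- if (!is.null(triple$ADM_NAME)) triple$ADM_NAME[bad] else bad
    stop(sprintf("dependency ratio undefined: unit %s has no working-age population", id))
  }
  keep <- setdiff(names(triple), c(req, "undefined"))
  out <- triple[, keep, drop = FALSE]
  out$YDR <- 100 * triple$pc0_14 / triple$pc15_64
  out$ODR <- 100 * triple$pc65 / triple$pc15_64
  out$CDR <- out$YDR + out$ODR
  out
}

#' Dependency ratios from a national (admin level 0) structure
#'
#' Countries without usable subnational age/sex data fall back to a single
#' national structure: the same formulas applied to one row, flagged
#' `admin_level = 0` so downstream rasters are spatially constant within the
#' country.
#'
#' @param national a one-row standard age/sex table for the country.
#' @return one-row data frame of ratios with `admin_level = 0`.
#' @export
national_fallback <- function(national) {
  if (nrow(national) != 1) stop("national structure must be a single row")
  out <- compute_ratios(derive_triple(national))
  out$admin_level <- 0L
  out
}

#' Aggregate unit-level structures to a national dependency ratio
#'
#' National ratios are computed from the population-weighted mean of the unit
#' triples (weights = unit populations) and then the ratio of the aggregated
#' triple -- not the mean of unit-level ratios, which would weight small and
#' large units equally.
#'
#' @param triple per-unit triples (`pc0_14`, `pc15_64`, `pc65`).
#' @param unit_populations positive weights, one per row of `triple`.
#' @return one-row data frame with the aggregated triple and `CDR`, `YDR`,
#'   `ODR`.
#' @export
aggregate_national <- function(triple, unit_populations) {
  if (length(unit_populations) != nrow(triple)) {
    stop("need one population per unit")
  }
  if (any(unit_populations < 0) || sum(unit_populations) <= 0) {
    stop("unit populations must be nonnegative with positive total")
  }
  w <- unit_populations / sum(unit_populations)
  agg <- data.frame(pc0_14 = sum(w * triple$pc0_14),
                    pc15_64 = sum(w * triple$pc15_64),
                    pc65 = sum(w * triple$pc65))
  cbind(agg, compute_ratios(agg))
}

#' Write dependency ratios to CSV
#'
#' Ratios are exported rounded to 2 decimals.
#'
#' @param ratios data frame from [compute_ratios()].
#' @param path output CSV path.
#' @export
write_ratios <- function(ratios, path) {
  out <- ratios
  for (col in intersect(c("CDR", "YDR", "ODR"), names(out))) {
    out[[col]] <- round(out[[col]], 2)
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
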