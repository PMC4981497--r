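# tabulation of high-resolution localization classifications

#' Read a localization-classification table
#'
#' Loads a table of manually curated high-resolution localization records
#' (one row per protein/isoform) with logical category flags `broad`,
#' `narrow`, `focal`, `boundary` (heterochromatin patterns, not mutually
#' exclusive) and `pan_nuclear`, `nucleolar`, `foci_outside_hc` (other
#' localizations). The package ships a curated fixture of the published
#' classifications.
#'
#' @param path CSV path; default the packaged table
#' @return data.frame of localization records
#' @export
read_localization_table <- function(path = system.file(
    "extdata", "table3_localization.csv", package = "hetscreen")) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("gene_name", "isoform", "reason", "previously_known",
            "broad", "narrow", "focal", "boundary")
  missing_cols <- setdiff(need, names(tab))
  if (length(missing_cols))
    stop("localization table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  tab
}

hc_categories <- function() c("broad", "narrow", "focal", "boundary")

# heterochromatic = any of the four heterochromatin pattern flags
is_heterochromatic <- function(records) {
  Reduce(`|`, lapply(hc_categories(), function(c_) records[[c_]]))
}

#' Tally heterochromatin localization categories
#'
#' Counts, over heterochromatic records (any of broad/narrow/focal/boundary
#' set), how many records carry each category flag. Categories are not
#' mutually exclusive, so one record may increment several counts.
#'
#' @param records localization records ([read_localization_table()])
#' @return named integer vector: `broad`, `narrow`, `focal`, `boundary`
#' @export
tally_categories <- function(records) {
  if (!nrow(records))
    return(setNames(integer(4L), hc_categories()))
  het <- records[is_heterochromatic(records), , drop = FALSE]
  vapply(setNames(hc_categories(), hc_categories()),
         function(c_) sum(het[[c_]]), integer(1))
}

#' Fraction of subdomain-forming heterochromatin proteins
#'
#' Among heterochromatic records of a cohort, the fraction classified as
#' subdomain-forming (narrow OR focal OR boundary, as opposed to broad-only
#' distribution across the holodomain).
#'
#' @param records localization records
#' @param cohort optional logical vector (length `nrow(records)`) or
#'   filter function selecting the cohort; default all records
#' @return list with `k` (subdomain-forming), `n` (heterochromatic records
#'   in cohort), `fraction`
#' @export
subdomain_fraction <- function(records, cohort = NULL) {
  keep <- if (is.null(cohort)) rep(TRUE, nrow(records))
          else if (is.function(cohort)) cohort(records)
          else cohort
  sub <- records[keep, , drop = FALSE]
  sub <- sub[is_heterochromatic(sub), , drop = FALSE]
  n <- nrow(sub)
  if (n == 0L) stop("cohort contains no heterochromatic records")
  k <- sum(sub$narrow | sub$focal | sub$boundary)
  list(k = k, n = n, fraction = k / n)
}
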