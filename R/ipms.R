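# IP-MS candidate-selection arithmetic

#' Is a protein enriched in one IP-MS experiment?
#'
#' Enriched iff the bait IP carries at least two unique peptides AND at
#' least 3-fold as many unique peptides as the mock control (a control count
#' of zero is passed by any bait count >= 2). Vectorized.
#'
#' @param bait_peptides,control_peptides non-negative integer unique-peptide
#'   counts
#' @return logical
#' @export
is_enriched <- function(bait_peptides, control_peptides) {
  stopifnot(all(bait_peptides >= 0), all(control_peptides >= 0),
            all(bait_peptides == round(bait_peptides)),
            all(control_peptides == round(control_peptides)))
  bait_peptides >= 2 & bait_peptides >= 3 * control_peptides
}

#' Recurrently enriched HP1a interactors
#'
#' Filters a protein-evidence table (long format: one row per protein x
#' experiment with bait and control unique-peptide counts) to proteins
#' enriched, per [is_enriched()], in at least `min_experiments` experiments,
#' excluding common contaminants (ribosomal, tubulin, other flagged
#' classes).
#'
#' @param evidence data.frame with columns `protein_id`, `experiment`,
#'   `bait_peptides`, `control_peptides`, and optionally `contaminant_class`
#'   (`"none"` or absent = keep)
#' @param min_experiments minimum experiments with enrichment (default 2)
#' @param exclude_contaminants drop proteins with a non-`"none"`
#'   contaminant class
#' @return data.frame: `protein_id`, `n_enriched`, sorted by `n_enriched`
#'   decreasing (detection-frequency ranking)
#' @export
recurrent_hpips <- function(evidence, min_experiments = 2L,
                            exclude_contaminants = TRUE) {
  stopifnot(all(c("protein_id", "experiment", "bait_peptides",
                  "control_peptides") %in% names(evidence)))
  if (max(table(evidence$protein_id)) > 6L)
    warning("some proteins have more than 6 experiment rows")
  enr <- is_enriched(evidence$bait_peptides, evidence$control_peptides)
  counts <- tapply(enr, evidence$protein_id, sum)
  keep <- names(counts)[counts >= min_experiments]
  if (exclude_contaminants && "contaminant_class" %in% names(evidence)) {
    cls <- tapply(as.character(evidence$contaminant_class),
                  evidence$protein_id, function(x) x[1L])
    keep <- keep[cls[keep] %in% c(NA, "none")]
  }
  out <- data.frame(protein_id = keep,
                    n_enriched = as.integer(counts[keep]),
                    row.names = NULL, stringsAsFactors = FALSE)
  out[order(-out$n_enriched, out$protein_id), , drop = FALSE]
}
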