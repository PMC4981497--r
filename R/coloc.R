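# low-resolution colocalization screen: per-nucleus PCC distributions per
# construct, compared to a reference construct by a rank test

#' Per-nucleus PCC distribution for one well
#'
#' Segments nuclei on the mCherry-HP1a channel, gates on roundness
#' (P^2/A), background intensity (GFP mean < 4000 AU, mCherry mean <
#' 3000 AU discarded) and 16-bit saturation, and computes the Pearson
#' correlation coefficient between the two channels over each passing
#' nucleus's pixels. Wells with fewer than 10 passing nuclei are discarded.
#'
#' @param fields list of two-channel [image_field()]s (`mcherry`, `gfp`)
#' @param construct_id identifier of the construct in the well
#' @param threshold segmentation threshold (AU) on background-subtracted
#'   mCherry; default derived per well from background statistics
#'   ([background_threshold()]), which captures the whole nucleus rather
#'   than only the bright HP1a compartment
#' @param sigma,min_area,h segmentation parameters
#' @param min_nuclei discard wells with fewer passing nuclei (default 10)
#' @param gfp_floor,mcherry_floor,saturation,max_roundness QC gates
#' @return a `coloc_well`: list with `construct_id`, `pcc` (per-nucleus
#'   values), `n_nuclei`, `discarded`, `reason`
#' @export
compute_well_pcc <- function(fields, construct_id = NA_character_,
                             threshold = NULL, sigma = 25, min_area = 60,
                             h = 0.3, min_nuclei = 10L,
                             gfp_floor = 4000, mcherry_floor = 3000,
                             saturation = 65535, max_roundness = 8 * pi) {
  if (inherits(fields, "image_field")) fields <- list(fields)
  for (f in fields)
    if (!all(c("mcherry", "gfp") %in% f$channel_names))
      stop("colocalization fields need channels 'mcherry' and 'gfp'")
  if (is.null(threshold))
    threshold <- background_threshold(lapply(fields, function(f)
      f$channels$mcherry), sigma = sigma)
  pcc <- numeric(0)
  for (f in fields) {
    msk <- segment_nuclei(f$channels$mcherry, threshold, min_area = min_area,
                          sigma = sigma, h = h)
    msk <- qc_filter(msk, f,
                     min_mean = c(gfp = gfp_floor, mcherry = mcherry_floor),
                     saturation = saturation, max_roundness = max_roundness)
    labs <- msk$shape$label[msk$shape$label %in%
                              unique(as.integer(msk$labels[msk$labels > 0]))]
    for (l in labs) {
      pix <- msk$labels == l
      pcc <- c(pcc, pearson_cc(f$channels$mcherry[pix], f$channels$gfp[pix]))
    }
  }
  pcc <- pcc[!is.na(pcc)]
  discarded <- length(pcc) < min_nuclei
  structure(list(construct_id = construct_id, pcc = pcc,
                 n_nuclei = length(pcc), discarded = discarded,
                 reason = if (discarded)
                   sprintf("fewer than %d nuclei", min_nuclei) else NA_character_),
            class = "coloc_well")
}

#' Build a `coloc_well` from precomputed per-nucleus PCC values
#'
#' @param pcc numeric vector of per-nucleus PCCs in `[-1, 1]`
#' @param construct_id construct identifier
#' @param min_nuclei discard threshold
#' @return a `coloc_well`
#' @export
coloc_well <- function(pcc, construct_id = NA_character_, min_nuclei = 10L) {
  stopifnot(all(pcc >= -1 & pcc <= 1, na.rm = TRUE))
  pcc <- pcc[!is.na(pcc)]
  discarded <- length(pcc) < min_nuclei
  structure(list(construct_id = construct_id, pcc = pcc,
                 n_nuclei = length(pcc), discarded = discarded,
                 reason = if (discarded)
                   sprintf("fewer than %d nuclei", min_nuclei) else NA_character_),
            class = "coloc_well")
}

#' @export
print.coloc_well <- function(x, ...) {
  cat(sprintf("coloc_well %s: %d nuclei, median PCC %.3f%s\n",
              x$construct_id, x$n_nuclei,
              if (x$n_nuclei) median(x$pcc) else NA,
              if (x$discarded) " [discarded]" else ""))
  invisible(x)
}

#' Call a construct as an HP1a colocalizer
#'
#' Two-sided unpaired Mann-Whitney test of the query construct's
#' per-nucleus PCC sample against the reference construct (GFP-modulo in
#' the original screen). The construct is a colocalizer iff p < `alpha` AND
#' its median PCC exceeds the reference median (the test is two-sided but
#' the call requires significantly *higher* correlation). Ties are handled
#' by the test's exact/normal-approximation switch (exact for smaller
#' tie-free samples, normal approximation with continuity correction
#' otherwise).
#'
#' @param query,reference `coloc_well` objects (not discarded)
#' @param alpha significance level (default 0.05)
#' @return a `coloc_call`: list with `construct_id`, `reference_id`, `p`,
#'   `U`, `median_query`, `median_reference`, `colocalizer`
#' @export
call_colocalizer <- function(query, reference, alpha = 0.05) {
  stopifnot(inherits(query, "coloc_well"), inherits(reference, "coloc_well"))
  if (query$discarded || reference$discarded)
    stop("cannot call a discarded well (",
         if (query$discarded) query$reason else reference$reason, ")")
  wt <- suppressWarnings(wilcox.test(query$pcc, reference$pcc,
                                     alternative = "two.sided"))
  mq <- median(query$pcc); mr <- median(reference$pcc)
  structure(list(construct_id = query$construct_id,
                 reference_id = reference$construct_id,
                 p = wt$p.value, U = unname(wt$statistic),
                 median_query = mq, median_reference = mr,
                 colocalizer = wt$p.value < alpha && mq > mr),
            class = "coloc_call")
}

#' @export
print.coloc_call <- function(x, ...) {
  cat(sprintf("%s vs %s: U=%g p=%.3g median %.3f vs %.3f -> %s\n",
              x$construct_id, x$reference_id, x$U, x$p,
              x$median_query, x$median_reference,
              if (x$colocalizer) "colocalizer" else "not a colocalizer"))
  invisible(x)
}

#' Pick the highest-scoring well among duplicates of one construct
#'
#' When a construct was transfected in duplicate the highest scoring well
#' is used: lowest Mann-Whitney p against the reference, ties broken by the
#' higher median PCC.
#'
#' @param wells list of `coloc_well`s of one construct
#' @param reference reference `coloc_well`
#' @param alpha significance level
#' @return the winning `coloc_call`
#' @export
best_duplicate_call <- function(wells, reference, alpha = 0.05) {
  wells <- Filter(function(w) !w$discarded, wells)
  if (!length(wells)) stop("all duplicate wells discarded")
  calls <- lapply(wells, call_colocalizer, reference = reference,
                  alpha = alpha)
  ord <- order(vapply(calls, `[[`, numeric(1), "p"),
               -vapply(calls, `[[`, numeric(1), "median_query"))
  calls[[ord[1L]]]
}
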