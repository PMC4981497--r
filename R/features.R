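# per-nucleus feature extraction and per-well aggregation

#' Canonical imaging feature names
#'
#' The 33 per-nucleus imaging features: eight intensity descriptors for each
#' of the three screen channels (DAPI, HP1a, gamma-H2Av), six shape
#' descriptors, and the three pairwise per-nucleus Pearson correlations.
#'
#' @return character vector of length 33
#' @export
canonical_features <- function() {
  ints <- c("mean", "max", "total", "sd", "relative_max", "kurtosis",
            "skew", "edge_center_ratio")
  c(as.vector(t(outer(ints, c("dapi", "hp1a", "gh2av"), paste, sep = "_"))),
    "area", "perimeter", "roundness", "eccentricity", "solidity",
    "equiv_diameter",
    "pcc_hp1a_dapi", "pcc_hp1a_gh2av", "pcc_dapi_gh2av")
}

#' HP1a-only feature subset
#'
#' All canonical features except those associated with the gamma-H2Av
#' channel (its intensity descriptors and the correlations involving it).
#'
#' @return character vector
#' @export
hp1a_only_features <- function() {
  f <- canonical_features()
  f[!grepl("gh2av", f)]
}

#' Per-nucleus Pearson correlation coefficient
#'
#' Standard product-moment correlation over paired pixel intensities.
#' Returns `NA` when either vector is constant (undefined correlation).
#'
#' @param a,b equal-length numeric vectors (>= 2 values)
#' @return correlation in `[-1, 1]`, or `NA`
#' @export
pearson_cc <- function(a, b) {
  if (length(a) != length(b)) stop("inputs must have equal length")
  if (length(a) < 2L) stop("need at least 2 paired values")
  if (sd(a) == 0 || sd(b) == 0) return(NA_real_)
  da <- a - mean(a); db <- b - mean(b)
  sum(da * db) / sqrt(sum(da^2) * sum(db^2))
}

# population moments: excess kurtosis and skewness, 0 for constant input
excess_kurtosis <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(0)
  mean((x - mean(x))^4) / m2^2 - 3
}
skewness <- function(x) {
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) return(0)
  mean((x - mean(x))^3) / m2^1.5
}

#' Extract per-nucleus imaging features
#'
#' Computes the 33 canonical features for every label in the mask: per
#' channel mean/max/total/sd, relative maximum (max/mean), excess (Fisher)
#' kurtosis, skewness and edge-to-center intensity ratio; nucleus shape
#' (area, Crofton perimeter, roundness P^2/A, eccentricity, solidity,
#' equivalent diameter); and the pairwise per-nucleus Pearson correlations
#' between channels. Kurtosis and skewness are defined as 0 for constant
#' regions; relative maximum is 1 there.
#'
#' @param mask a `nucleus_mask`
#' @param field an [image_field()] with channels `dapi`, `hp1a`, `gh2av`
#'   (or the two-channel colocalization naming)
#' @param channels channels to use; defaults to the field's channels
#' @return data.frame, one row per nucleus: `label` plus feature columns
#' @export
extract_features <- function(mask, field,
                             channels = field$channel_names) {
  stopifnot(inherits(mask, "nucleus_mask"), inherits(field, "image_field"))
  if (!identical(dim(mask$labels), field$dim))
    stop("mask and field dimensions differ")
  missing_ch <- setdiff(channels, field$channel_names)
  if (length(missing_ch))
    stop("channel absent from field: ", paste(missing_ch, collapse = ", "))
  sh <- mask$shape
  sh <- sh[sh$label %in% unique(as.integer(mask$labels[mask$labels > 0])), ,
           drop = FALSE]
  if (!nrow(sh)) {
    out <- as.data.frame(matrix(numeric(0), 0L, length(canonical_features()) + 1L))
    names(out) <- c("label", canonical_features())
    return(out)
  }
  lab <- mask$labels
  # edge pixels: region pixels with a 4-neighbour outside the same label
  n <- nrow(lab); m <- ncol(lab)
  shift <- function(x, di, dj) {
    out <- matrix(0L, n, m)
    ri <- seq_len(n) + di; cj <- seq_len(m) + dj
    ok_r <- ri >= 1L & ri <= n; ok_c <- cj >= 1L & cj <= m
    out[ok_r, ok_c] <- x[ri[ok_r], cj[ok_c]]
    out
  }
  interior <- lab > 0 &
    shift(lab, 1L, 0L) == lab & shift(lab, -1L, 0L) == lab &
    shift(lab, 0L, 1L) == lab & shift(lab, 0L, -1L) == lab
  rows <- lapply(sh$label, function(l) {
    pix <- lab == l
    vals <- lapply(channels, function(ch) field$channels[[ch]][pix])
    names(vals) <- channels
    fv <- list(label = l)
    for (ch in channels) {
      v <- vals[[ch]]
      mu <- mean(v)
      fv[[paste0("mean_", ch)]] <- mu
      fv[[paste0("max_", ch)]] <- max(v)
      fv[[paste0("total_", ch)]] <- sum(v)
      fv[[paste0("sd_", ch)]] <- sd(v)
      fv[[paste0("relative_max_", ch)]] <- if (mu > 0) max(v) / mu else 1
      fv[[paste0("kurtosis_", ch)]] <- excess_kurtosis(v)
      fv[[paste0("skew_", ch)]] <- skewness(v)
      edge_v <- field$channels[[ch]][pix & !interior]
      int_v <- field$channels[[ch]][pix & interior]
      fv[[paste0("edge_center_ratio_", ch)]] <-
        if (length(int_v) && mean(int_v) > 0 && length(edge_v))
          mean(edge_v) / mean(int_v) else 1
    }
    srow <- sh[sh$label == l, ]
    fv$area <- srow$area; fv$perimeter <- srow$perimeter
    fv$roundness <- srow$roundness; fv$eccentricity <- srow$eccentricity
    fv$solidity <- srow$solidity; fv$equiv_diameter <- srow$equiv_diameter
    combos <- list(c("hp1a", "dapi"), c("hp1a", "gh2av"), c("dapi", "gh2av"))
    for (cc in combos) {
      nm <- paste0("pcc_", cc[1L], "_", cc[2L])
      fv[[nm]] <- if (all(cc %in% channels))
        pearson_cc(vals[[cc[1L]]], vals[[cc[2L]]]) else NA_real_
    }
    as.data.frame(fv)
  })
  out <- do.call(rbind, rows)
  keep <- c("label", intersect(canonical_features(), names(out)))
  out[, keep, drop = FALSE]
}

#' Aggregate per-nucleus features into a well summary
#'
#' The per-well aggregate entering Rank Product is the median of each
#' feature over QC-passing nuclei (robust to residual segmentation debris).
#' Wells with zero passing nuclei get `NA` aggregates.
#'
#' @param records data.frame of per-nucleus features ([extract_features()])
#' @param layout_row list/data.frame row with `well`, `amplicon_id`, `role`,
#'   and optionally `replicate`
#' @param agg aggregator function, default [median()]
#' @return one-row data.frame: well metadata, `n_nuclei`, aggregates
#' @export
aggregate_well <- function(records, layout_row, agg = median) {
  feat <- setdiff(names(records), "label")
  n <- nrow(records)
  vals <- if (n > 0L) lapply(records[feat], function(x) agg(x, na.rm = TRUE))
          else as.list(setNames(rep(NA_real_, length(feat)), feat))
  out <- data.frame(well = layout_row$well,
                    amplicon_id = layout_row$amplicon_id,
                    role = layout_row$role,
                    replicate = if (!is.null(layout_row$replicate))
                      layout_row$replicate else NA_integer_,
                    n_nuclei = n, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(vals))
}

#' Segment, QC, extract and aggregate one well of screen fields
#'
#' Convenience wrapper running the full imaging chain on the fields of one
#' well: segmentation on DAPI at a constant threshold, QC gating, feature
#' extraction, and median aggregation.
#'
#' @param fields list of [image_field()]s (one well)
#' @param layout_row well metadata (see [aggregate_well()])
#' @param threshold constant segmentation threshold (AU)
#' @param sigma,min_area,h segmentation parameters ([segment_nuclei()])
#' @param ... passed to [qc_filter()]
#' @return list with `summary` (one-row data.frame) and `nuclei`
#'   (per-nucleus feature records)
#' @export
summarize_well <- function(fields, layout_row, threshold,
                           sigma = 25, min_area = 60, h = 0.3, ...) {
  recs <- list()
  for (f in fields) {
    msk <- segment_nuclei(f$channels$dapi, threshold, min_area = min_area,
                          sigma = sigma, h = h)
    msk <- qc_filter(msk, f, ...)
    fe <- extract_features(msk, f)
    if (nrow(fe)) recs[[length(recs) + 1L]] <- fe
  }
  nuclei <- if (length(recs)) do.call(rbind, recs) else
    extract_features(new_nucleus_mask(matrix(0L, 2L, 2L)),
                     image_field(list(dapi = matrix(0, 2L, 2L),
                                      hp1a = matrix(0, 2L, 2L),
                                      gh2av = matrix(0, 2L, 2L))))
  list(summary = aggregate_well(nuclei[setdiff(names(nuclei), character(0))],
                                layout_row),
       nuclei = nuclei)
}
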