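# replicate-aware normalization: Rank Product with permutation p-values,
# and the robust z-score baseline

#' Within-replicate well ranks for one feature
#'
#' Ranks each replicate's wells by their aggregate value of `feature`.
#' Direction `"decrease"` ranks the smallest value 1 (strongest decrease
#' first); `"increase"` ranks the largest value 1. Ties get average ranks.
#' Wells missing from any replicate are dropped with a warning.
#'
#' @param summaries well-summary data.frame (columns `well`, `replicate`,
#'   and the feature), one row per well x replicate
#' @param feature feature column name
#' @param direction `"decrease"` or `"increase"`
#' @return matrix wells x replicates of ranks, rownames = wells
#' @export
rank_wells <- function(summaries, feature, direction = c("decrease",
                                                         "increase")) {
  direction <- match.arg(direction)
  stopifnot(feature %in% names(summaries))
  reps <- sort(unique(summaries$replicate))
  wells_by_rep <- lapply(reps, function(r)
    summaries$well[summaries$replicate == r])
  common <- Reduce(intersect, wells_by_rep)
  all_wells <- unique(summaries$well)
  if (length(common) < length(all_wells))
    warning(length(all_wells) - length(common),
            " wells absent from some replicate were dropped")
  if (length(common) < 2L) stop("need at least 2 wells present in every replicate")
  out <- sapply(reps, function(r) {
    sub <- summaries[summaries$replicate == r, ]
    v <- sub[[feature]][match(common, sub$well)]
    if (direction == "decrease") rank(v, ties.method = "average")
    else rank(-v, ties.method = "average")
  })
  rownames(out) <- common
  colnames(out) <- paste0("rep", reps)
  out
}

#' Rank Product statistic with permutation p-values
#'
#' The rank product of a well is the geometric mean of its within-replicate
#' ranks; replicate-consistent extreme wells get small rank products. The
#' null density is built by `n_perm` independent within-replicate rank
#' shuffles (preserving the rank marginals), pooling the null rank products
#' of all wells; the p-value uses the add-one estimator
#' `p = (1 + #null <= rp) / (1 + n * n_perm)` so p is never exactly 0.
#'
#' @param rank_matrix wells x replicates rank matrix from [rank_wells()]
#' @param n_perm number of permutations (default 100)
#' @param seed integer seed for the permutation null
#' @return data.frame: `well`, `rank` (of rp), `rp`, `p`, `n_perm`
#' @export
rank_product <- function(rank_matrix, n_perm = 100L, seed = 1L) {
  stopifnot(is.matrix(rank_matrix), n_perm >= 1L)
  n <- nrow(rank_matrix); R <- ncol(rank_matrix)
  rp <- exp(rowMeans(log(rank_matrix)))
  null_rp <- with_seed(seed, {
    out <- matrix(NA_real_, n, n_perm)
    for (b in seq_len(n_perm)) {
      perm <- vapply(seq_len(R), function(r) sample(rank_matrix[, r]),
                     numeric(n))
      out[, b] <- exp(rowMeans(log(perm)))
    }
    out
  })
  sorted_null <- sort(as.numeric(null_rp))
  cnt <- findInterval(rp, sorted_null)
  p <- (1 + cnt) / (1 + n * n_perm)
  data.frame(well = rownames(rank_matrix), rank = rank(rp, ties.method = "min"),
             rp = rp, p = p, n_perm = n_perm, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Rank Product over a set of features and directions
#'
#' Runs [rank_wells()] + [rank_product()] for each requested
#' feature/direction pair (one-directional results are kept separate, as
#' every hit rule is one-directional).
#'
#' @param summaries well summaries (see [rank_wells()])
#' @param metrics data.frame with columns `feature` and `direction`
#' @param n_perm permutations per feature
#' @param seed integer seed
#' @return data.frame: `feature`, `direction`, `well`, `rank`, `rp`, `p`
#' @export
rank_product_screen <- function(summaries, metrics, n_perm = 100L, seed = 1L) {
  out <- list()
  for (i in seq_len(nrow(metrics))) {
    rm_ <- rank_wells(summaries, metrics$feature[i], metrics$direction[i])
    rp <- rank_product(rm_, n_perm = n_perm,
                       seed = child_seed(seed, i))
    rp$feature <- metrics$feature[i]
    rp$direction <- metrics$direction[i]
    out[[i]] <- rp
  }
  do.call(rbind, out)[, c("feature", "direction", "well", "rank", "rp", "p",
                          "n_perm")]
}

#' Per-well rank-product matrix over many features
#'
#' The geometric-mean across-replicate rank of each well for each feature
#' (direction `"decrease"`), normalized by the well count to `(0, 1]`. This
#' is the monotone rank encoding used as input by the SVM and clustering
#' hit callers.
#'
#' @param summaries well summaries
#' @param features feature names (default all 33 canonical features)
#' @return matrix wells x features of normalized rank products
#' @export
rank_product_matrix <- function(summaries, features = canonical_features()) {
  mats <- lapply(features, function(f)
    exp(rowMeans(log(rank_wells(summaries, f, "decrease")))))
  X <- do.call(cbind, mats)
  colnames(X) <- features
  X / length(unique(summaries$well))
}

#' Robust z-score normalization
#'
#' `(x - median) / (1.4826 * MAD)`. When the MAD is zero the scores are
#' undefined and `NA` is returned for every well, with a warning.
#'
#' @param values numeric vector of well aggregates (>= 3 wells)
#' @return numeric vector of robust z-scores
#' @export
robust_zscore <- function(values) {
  if (length(values) < 3L) stop("need at least 3 wells")
  med <- median(values, na.rm = TRUE)
  m <- median(abs(values - med), na.rm = TRUE)
  if (m == 0) {
    warning("MAD is zero; robust z-scores undefined")
    return(rep(NA_real_, length(values)))
  }
  (values - med) / (1.4826 * m)
}

#' Benchmark Rank Product against the robust z-score
#'
#' For a screen with labeled positive controls, computes each well's
#' position in the hit list sorted by (a) Rank Product p-value and (b) the
#' robust z-score of the replicate-averaged aggregate, and reports the
#' positions of the positive controls under each method.
#'
#' @param summaries well summaries with a `role` column
#' @param feature feature to rank (default `mean_hp1a`)
#' @param direction hit direction (default `"decrease"`)
#' @param positive_role role labelling positive controls
#' @param n_perm,seed passed to [rank_product()]
#' @return data.frame: `method`, `well`, `position`, `is_positive`
#' @export
rank_vs_zscore_benchmark <- function(summaries, feature = "mean_hp1a",
                                     direction = "decrease",
                                     positive_role = "pos_hp1a",
                                     n_perm = 100L, seed = 1L) {
  rm_ <- rank_wells(summaries, feature, direction)
  rp <- rank_product(rm_, n_perm = n_perm, seed = seed)
  roles <- summaries$role[match(rp$well, summaries$well)]
  ord_rp <- order(rp$p, rp$rp)
  avg <- tapply(summaries[[feature]], summaries$well, mean)
  avg <- avg[rp$well]
  z <- robust_zscore(as.numeric(avg))
  ord_z <- if (direction == "decrease") order(z) else order(-z)
  rbind(
    data.frame(method = "rank_product", well = rp$well[ord_rp],
               position = seq_along(ord_rp),
               is_positive = roles[ord_rp] == positive_role),
    data.frame(method = "robust_zscore", well = rp$well[ord_z],
               position = seq_along(ord_z),
               is_positive = roles[ord_z] == positive_role))
}
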