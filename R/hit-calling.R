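# the three hit-identification schemes: intensity cutoffs, control-trained
# polynomial-kernel SVMs, and multi-metric distance rules with
# randomization-calibrated p-values

#' Rank Product p-value cutoffs for the intensity hit rule
#'
#' Defaults are the cutoffs used for the original genome-wide screen:
#' decreased relative HP1a maximum 1.5e-3, increased HP1a kurtosis 5.0e-4,
#' decreased HP1a mean 6.3e-4, decreased HP1a maximum 3.8e-4; the
#' increased-HP1a (negative regulator) rule uses 0.05 on both mean and max,
#' and decreased-cell-number exclusion uses 0.05.
#'
#' @param p_dec_relative_max,p_inc_kurtosis,p_dec_mean,p_dec_max cutoffs for
#'   the four HP1a metrics
#' @param p_increase_rule cutoff for increased mean AND max
#' @param p_cellnum cutoff for the decreased-cell-number exclusion
#' @return named list of cutoffs
#' @export
intensity_cutoffs <- function(p_dec_relative_max = 1.5e-3,
                              p_inc_kurtosis = 5.0e-4,
                              p_dec_mean = 6.3e-4,
                              p_dec_max = 3.8e-4,
                              p_increase_rule = 0.05,
                              p_cellnum = 0.05) {
  out <- list(p_dec_relative_max = p_dec_relative_max,
              p_inc_kurtosis = p_inc_kurtosis,
              p_dec_mean = p_dec_mean, p_dec_max = p_dec_max,
              p_increase_rule = p_increase_rule, p_cellnum = p_cellnum)
  stopifnot(all(unlist(out) > 0), all(unlist(out) < 1))
  out
}

#' Feature/direction pairs required by the intensity hit rule
#'
#' The four HP1a metrics in their hit directions, plus the nucleus-count
#' and increased-intensity metrics used by the exclusion and
#' negative-regulator rules.
#'
#' @return data.frame with columns `feature`, `direction`
#' @export
intensity_metrics <- function() {
  data.frame(
    feature = c("relative_max_hp1a", "kurtosis_hp1a", "mean_hp1a",
                "max_hp1a", "n_nuclei", "mean_hp1a", "max_hp1a"),
    direction = c("decrease", "increase", "decrease", "decrease",
                  "decrease", "increase", "increase"),
    stringsAsFactors = FALSE)
}

rp_pvec <- function(rp, feature, direction) {
  sub <- rp[rp$feature == feature & rp$direction == direction, ]
  if (!nrow(sub)) stop("rank-product results missing metric ", feature,
                       " (", direction, ")")
  setNames(sub$p, sub$well)
}

#' Call screen hits from the four HP1a intensity metrics
#'
#' Positive regulators (HP1a-lowering depletions): union of wells passing
#' any of the four one-directional cutoffs (decreased relative maximum,
#' increased kurtosis, decreased mean, decreased maximum), minus wells with
#' a cell-death signature (decreased nucleus count p below `p_cellnum`
#' together with aberrant nuclear morphology: well median nuclear area below
#' half the screen median). Negative regulators: increased mean AND
#' increased max p below `p_increase_rule`, excluding decreased-cell-number
#' wells.
#'
#' @param rp result of [rank_product_screen()] over [intensity_metrics()]
#' @param summaries well summaries (for the area morphology gate and
#'   amplicon/role metadata)
#' @param cutoffs an [intensity_cutoffs()] list
#' @return data.frame: `well`, `amplicon_id`, `role`, `direction`
#'   (`positive_regulator` / `negative_regulator`), `metrics` (comma list of
#'   passing metrics), `min_p`, `cell_death`
#' @export
call_hits_intensity <- function(rp, summaries, cutoffs = intensity_cutoffs()) {
  p_rel <- rp_pvec(rp, "relative_max_hp1a", "decrease")
  p_kur <- rp_pvec(rp, "kurtosis_hp1a", "increase")
  p_mean <- rp_pvec(rp, "mean_hp1a", "decrease")
  p_max <- rp_pvec(rp, "max_hp1a", "decrease")
  p_cnt <- rp_pvec(rp, "n_nuclei", "decrease")
  p_mean_i <- rp_pvec(rp, "mean_hp1a", "increase")
  p_max_i <- rp_pvec(rp, "max_hp1a", "increase")
  wells <- names(p_mean)

  med_area <- tapply(summaries$area, summaries$well, median)[wells]
  cell_death <- p_cnt[wells] < cutoffs$p_cellnum &
    !is.na(med_area) & med_area < 0.5 * median(med_area, na.rm = TRUE)

  pass <- cbind(dec_relative_max = p_rel[wells] < cutoffs$p_dec_relative_max,
                inc_kurtosis = p_kur[wells] < cutoffs$p_inc_kurtosis,
                dec_mean = p_mean[wells] < cutoffs$p_dec_mean,
                dec_max = p_max[wells] < cutoffs$p_dec_max)
  pos_hit <- rowSums(pass) > 0 & !cell_death
  neg_hit <- p_mean_i[wells] < cutoffs$p_increase_rule &
    p_max_i[wells] < cutoffs$p_increase_rule &
    !(p_cnt[wells] < cutoffs$p_cellnum)

  meta <- summaries[match(wells, summaries$well),
                    c("well", "amplicon_id", "role")]
  mk <- function(idx, dir_, pmat) {
    if (!any(idx)) return(NULL)
    data.frame(meta[idx, ], direction = dir_,
               metrics = apply(pass[idx, , drop = FALSE], 1L, function(z)
                 paste(colnames(pass)[z], collapse = ",")),
               min_p = apply(pmat[idx, , drop = FALSE], 1L, min),
               cell_death = cell_death[idx], row.names = NULL)
  }
  pos <- mk(pos_hit, "positive_regulator",
            cbind(p_rel[wells], p_kur[wells], p_mean[wells], p_max[wells]))
  neg <- mk(neg_hit, "negative_regulator",
            cbind(p_mean_i[wells], p_max_i[wells]))
  if (!is.null(neg)) neg$metrics <- "inc_mean,inc_max"
  out <- rbind(pos, neg)
  if (is.null(out))
    out <- data.frame(well = character(0), amplicon_id = character(0),
                      role = character(0), direction = character(0),
                      metrics = character(0), min_p = numeric(0),
                      cell_death = logical(0))
  out
}

#' Calibrate intensity cutoffs from positive controls
#'
#' Reproduces the original screen's cutoff-selection rule: each of the four
#' HP1a-metric cutoffs is chosen for maximal inclusion of HP1a
#' positive-control wells, i.e. set just above the largest positive-control
#' p-value not exceeding `cap`.
#'
#' @param rp result of [rank_product_screen()] over [intensity_metrics()]
#' @param roles named character vector well -> role
#' @param positive_role role marking HP1a-RNAi wells
#' @param cap never raise a cutoff beyond this (default 0.05)
#' @return an [intensity_cutoffs()] list
#' @export
calibrate_intensity_cutoffs <- function(rp, roles, positive_role = "pos_hp1a",
                                        cap = 0.05) {
  pos <- names(roles)[roles == positive_role]
  if (!length(pos)) stop("no positive-control wells in roles")
  pick <- function(feature, direction) {
    p <- rp_pvec(rp, feature, direction)[pos]
    p <- p[!is.na(p) & p <= cap]
    if (!length(p)) return(cap * 1e-2)
    min(max(p) * 1.0000001, cap)
  }
  intensity_cutoffs(
    p_dec_relative_max = pick("relative_max_hp1a", "decrease"),
    p_inc_kurtosis = pick("kurtosis_hp1a", "increase"),
    p_dec_mean = pick("mean_hp1a", "decrease"),
    p_dec_max = pick("max_hp1a", "decrease"))
}

#' Polynomial-kernel SVM specification
#'
#' @param kernel_parameter scale coefficient of the polynomial kernel
#'   (0.8 for all imaging features, 0.4 for the HP1a-only feature set)
#' @param ridge ridge (regularization floor) recorded with the model
#' @param degree polynomial degree
#' @param features feature names the classifier uses
#' @return an `svm_spec` list
#' @export
svm_spec <- function(kernel_parameter = 0.8, ridge = 1e-8, degree = 2L,
                     features = canonical_features()) {
  stopifnot(kernel_parameter > 0, ridge > 0, degree >= 1L)
  structure(list(kernel_parameter = kernel_parameter, ridge = ridge,
                 degree = degree, features = features), class = "svm_spec")
}

#' Train the control-based polynomial-kernel SVM
#'
#' Fits a polynomial-kernel max-margin classifier on control wells
#' (positives = HP1a-RNAi, negatives = mock/GFP/Rho1/Thread RNAi) using the
#' normalized rank-product feature matrix. A held-out subset of the
#' positives is withheld from training and the regularization level is
#' chosen along a path of candidate values to maximize identification of
#' those withheld HP1a knockdowns; the final model is refit on all controls.
#'
#' @param X wells x features matrix from [rank_product_matrix()]
#' @param roles named character vector well -> role
#' @param spec an [svm_spec()]
#' @param positive_role,negative_roles control role labels
#' @param holdout_fraction fraction of positives withheld for tuning
#' @param C_path candidate regularization values
#' @param seed integer seed (holdout split)
#' @return `control_svm` object: the fitted model, chosen C, spec, and the
#'   withheld-positive recall achieved during tuning
#' @export
train_control_svm <- function(X, roles, spec = svm_spec(),
                              positive_role = "pos_hp1a",
                              negative_roles = c("neg_mock", "neg_gfp",
                                                 "neg_rho1", "neg_thread"),
                              holdout_fraction = 0.5,
                              C_path = 10^seq(-1, 5, by = 1),
                              seed = 1L) {
  stopifnot(is.matrix(X), !is.null(rownames(X)))
  X <- X[, spec$features, drop = FALSE]
  pos <- intersect(rownames(X), names(roles)[roles == positive_role])
  neg <- intersect(rownames(X), names(roles)[roles %in% negative_roles])
  if (length(pos) < 2L || length(neg) < 2L)
    stop("need >= 2 positive and >= 2 negative control wells")
  n_hold <- max(1L, floor(length(pos) * holdout_fraction))
  if (length(pos) - n_hold < 1L) n_hold <- length(pos) - 1L
  held <- with_seed(seed, sample(pos, n_hold))
  train_pos <- setdiff(pos, held)

  fit <- function(wells_pos, wells_neg, C) {
    xt <- X[c(wells_pos, wells_neg), , drop = FALSE]
    yt <- factor(rep(c("pos", "neg"), c(length(wells_pos),
                                        length(wells_neg))),
                 levels = c("neg", "pos"))
    kernlab::ksvm(xt, yt, kernel = "polydot",
                  kpar = list(degree = spec$degree,
                              scale = spec$kernel_parameter, offset = 1),
                  C = C, scaled = FALSE)
  }
  score <- vapply(C_path, function(C) {
    m <- try(fit(train_pos, neg, C), silent = TRUE)
    if (inherits(m, "try-error")) return(-Inf)
    pred_h <- kernlab::predict(m, X[held, , drop = FALSE])
    pred_n <- kernlab::predict(m, X[neg, , drop = FALSE])
    mean(pred_h == "pos") + 0.1 * mean(pred_n == "neg")
  }, numeric(1))
  C_best <- C_path[which.max(score)]
  model <- fit(pos, neg, C_best)
  structure(list(model = model, spec = spec, C = C_best,
                 withheld = held,
                 withheld_recall = {
                   m0 <- fit(train_pos, neg, C_best)
                   mean(kernlab::predict(
                     m0, X[held, , drop = FALSE]) == "pos")
                 },
                 positive_role = positive_role,
                 negative_roles = negative_roles),
            class = "control_svm")
}

#' Apply the control-trained SVM to the whole screen
#'
#' Classifies every well; wells on the positive (HP1a-knockdown-like) side
#' are flagged as SVM hits.
#'
#' @param classifier a `control_svm` from [train_control_svm()]
#' @param X wells x features matrix (same feature space as training)
#' @return data.frame: `well`, `svm_positive`
#' @export
call_hits_svm <- function(classifier, X) {
  stopifnot(inherits(classifier, "control_svm"))
  feats <- classifier$spec$features
  if (!all(feats %in% colnames(X)))
    stop("feature mismatch between classifier and input matrix")
  pred <- kernlab::predict(classifier$model, X[, feats, drop = FALSE])
  data.frame(well = rownames(X), svm_positive = pred == "pos",
             row.names = NULL, stringsAsFactors = FALSE)
}

# ---- distance metrics and randomization calibration ----

#' Ledoit-Wolf-style shrinkage covariance
#'
#' Shrinks the sample covariance toward a scaled identity with the
#' analytically estimated optimal intensity; used by the Mahalanobis
#' distance, where wells >> features is not guaranteed.
#'
#' @param X observations x variables matrix
#' @param lambda optional fixed shrinkage intensity in `[0, 1]`
#' @return list with `cov` (shrunk covariance) and `lambda`
#' @export
cov_shrink <- function(X, lambda = NULL) {
  n <- nrow(X); p <- ncol(X)
  Xc <- scale(X, center = TRUE, scale = FALSE)
  S <- crossprod(Xc) / n
  mu <- mean(diag(S))
  if (is.null(lambda)) {
    d2 <- sum((S - diag(mu, p))^2) / p
    b2 <- 0
    for (i in seq_len(n)) {
      xi <- Xc[i, ]
      b2 <- b2 + sum((tcrossprod(xi) - S)^2) / p
    }
    b2 <- b2 / n^2
    lambda <- if (d2 > 0) min(b2 / d2, 1) else 1
  }
  list(cov = (1 - lambda) * S + lambda * diag(mu, p), lambda = lambda)
}

#' Pairwise distances between well profiles
#'
#' @param X wells x features matrix
#' @param metric one of `"euclidean"`, `"pearson"`, `"spearman"`,
#'   `"mahalanobis"` (correlation metrics use 1 - correlation; Mahalanobis
#'   whitens with the shrinkage covariance, or a supplied one)
#' @param cov_matrix optional covariance override for Mahalanobis (identity
#'   reduces it to Euclidean)
#' @return symmetric distance matrix
#' @export
pairwise_distances <- function(X, metric = c("euclidean", "pearson",
                                             "spearman", "mahalanobis"),
                               cov_matrix = NULL) {
  metric <- match.arg(metric)
  D <- switch(metric,
    euclidean = as.matrix(dist(X)),
    pearson = 1 - cor(t(X)),
    spearman = 1 - cor(t(X), method = "spearman"),
    mahalanobis = {
      Sig <- if (is.null(cov_matrix)) cov_shrink(X)$cov else cov_matrix
      R <- chol(Sig)
      Xw <- t(backsolve(R, t(X), transpose = TRUE))
      as.matrix(dist(Xw))
    })
  dimnames(D) <- list(rownames(X), rownames(X))
  D
}

#' Calibrate a distance-to-p-value map by feature randomization
#'
#' Null distances are generated by independently permuting each feature
#' column across wells (repeatedly) and measuring all pairwise distances.
#' The map is the empirical quantile of the pooled null, anchored so the
#' 1-percentile null distance corresponds to p = 0.01; below the smallest
#' null distance the left tail is extrapolated by a power law fitted to the
#' lower tail of the null (log p vs log distance).
#'
#' @param X wells x features matrix (>= 100 wells)
#' @param metric distance metric (see [pairwise_distances()])
#' @param n_randomizations number of feature shuffles (>= 10)
#' @param seed integer seed
#' @return `distance_calibration` object
#' @export
calibrate_distance_pvalues <- function(X, metric = "euclidean",
                                       n_randomizations = 20L, seed = 1L) {
  if (nrow(X) < 100L) stop("calibration needs >= 100 wells")
  if (n_randomizations < 10L) stop("need >= 10 randomizations")
  nulls <- with_seed(seed, {
    out <- vector("list", n_randomizations)
    for (b in seq_len(n_randomizations)) {
      Xp <- apply(X, 2L, sample)
      D <- pairwise_distances(Xp, metric)
      out[[b]] <- D[upper.tri(D)]
    }
    sort(unlist(out))
  })
  N <- length(nulls)
  m <- max(20L, ceiling(0.005 * N))
  lo <- nulls[seq_len(m)]
  lo <- lo[lo > 0]
  tail_fit <- if (length(lo) >= 5L)
    coef(lm(log(seq_along(lo) / N) ~ log(lo))) else c(log(1 / N), 0)
  structure(list(null = nulls, n = N, metric = metric,
                 tail_intercept = unname(tail_fit[1L]),
                 tail_slope = unname(tail_fit[2L])),
            class = "distance_calibration")
}

#' Map distances to calibrated p-values
#'
#' @param calibration a `distance_calibration`
#' @param d numeric vector of distances
#' @return p-values in `(0, 1]`, monotone non-decreasing in distance
#' @export
distance_pvalue <- function(calibration, d) {
  stopifnot(inherits(calibration, "distance_calibration"))
  cnt <- findInterval(d, calibration$null)
  p <- cnt / calibration$n
  below <- cnt == 0L
  if (any(below)) {
    dmin <- calibration$null[1L]
    pb <- ifelse(d[below] <= 0, .Machine$double.xmin,
                 exp(calibration$tail_intercept +
                     calibration$tail_slope * log(d[below])))
    p[below] <- pmin(pmax(pb, .Machine$double.xmin), 1 / calibration$n)
  }
  pmin(pmax(p, .Machine$double.xmin), 1)
}

#' Call hits by multi-metric distance to HP1a-depletion controls
#'
#' A well is flagged by the pairwise rule if, for at least `min_metrics`
#' distance metrics, its calibrated pairwise p-value against at least
#' `min_controls` distinct HP1a-RNAi control wells falls below `p_cutoff`.
#' Additionally, average-linkage agglomerative clustering on the Pearson
#' correlation distance is cut at the smallest cluster number for which
#' every HP1a (and, if present, Su(var)3-9) control sits in a terminal
#' cluster holding at most `dendro_max_frac` of all wells; wells sharing a
#' terminal cluster with those controls are flagged with the corresponding
#' label.
#'
#' @param X wells x features matrix ([rank_product_matrix()]; run once with
#'   all features and once with the HP1a-only set)
#' @param roles named character vector well -> role
#' @param p_cutoff calibrated pairwise p cutoff (default 5e-7)
#' @param metrics distance metrics to use
#' @param n_randomizations,seed calibration settings
#' @param min_controls,min_metrics pairwise rule thresholds
#' @param control_role,suvar_role control role labels
#' @param dendro_max_frac terminal-cluster size bound for the dendrogram cut
#' @return data.frame per well: `pairwise_hit`, `n_metrics` (metrics
#'   supporting the pairwise rule), `dendro_hp1a`, `dendro_suvar39`
#' @export
call_hits_clustering <- function(X, roles, p_cutoff = 5e-7,
                                 metrics = c("spearman", "mahalanobis",
                                             "euclidean", "pearson"),
                                 n_randomizations = 20L, seed = 1L,
                                 min_controls = 5L, min_metrics = 2L,
                                 control_role = "pos_hp1a",
                                 suvar_role = "pos_suvar39",
                                 dendro_max_frac = 0.05) {
  wells <- rownames(X)
  ctrl <- intersect(wells, names(roles)[roles == control_role])
  if (length(ctrl) < min_controls)
    stop("need >= ", min_controls, " HP1a control wells")
  support <- matrix(0L, length(wells), length(metrics),
                    dimnames = list(wells, metrics))
  for (k in seq_along(metrics)) {
    D <- pairwise_distances(X, metrics[k])
    cal <- calibrate_distance_pvalues(X, metrics[k],
                                      n_randomizations = n_randomizations,
                                      seed = child_seed(seed, k))
    P <- matrix(distance_pvalue(cal, D[, ctrl, drop = FALSE]),
                nrow = length(wells))
    rownames(P) <- wells
    # a control is trivially distance 0 to itself; drop self-comparisons
    for (cw in ctrl) P[cw, match(cw, ctrl)] <- NA
    n_close <- rowSums(P < p_cutoff, na.rm = TRUE)
    support[, k] <- as.integer(n_close >= min_controls)
  }
  pair_hit <- rowSums(support) >= min_metrics

  Dmat <- 1 - cor(t(X))
  hc <- hclust(as.dist(Dmat), method = "average")
  suv <- intersect(wells, names(roles)[roles == suvar_role])
  max_size <- max(2L, floor(dendro_max_frac * length(wells)))
  dendro_hp1a <- dendro_suv <- rep(FALSE, length(wells))
  for (k in 2:length(wells)) {
    cl <- cutree(hc, k = k)
    names(cl) <- wells
    anchors <- unique(cl[c(ctrl, suv)])
    ok <- vapply(anchors, function(a) {
      mem <- which(cl == a)
      # small enough, or a zero-diameter block of identical profiles that
      # no cut should tear apart
      length(mem) <= max_size ||
        max(Dmat[mem, mem]) < 1e-10
    }, logical(1))
    if (all(ok)) {
      dendro_hp1a <- cl %in% unique(cl[ctrl])
      if (length(suv)) dendro_suv <- cl %in% unique(cl[suv])
      break
    }
  }
  data.frame(well = wells, pairwise_hit = pair_hit,
             n_metrics = rowSums(support),
             dendro_hp1a = dendro_hp1a, dendro_suvar39 = dendro_suv,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Combine hit subsets from the three calling methods
#'
#' @param subsets named list, method -> character vector of hit wells (or a
#'   data.frame with a `well` column)
#' @return list with `hits` (data.frame: `well`, `methods`, `n_methods`) and
#'   `venn` (named counts per method combination)
#' @export
combine_hits <- function(subsets) {
  sets <- lapply(subsets, function(s)
    unique(if (is.data.frame(s)) s$well else as.character(s)))
  all_wells <- sort(unique(unlist(sets)))
  member <- sapply(sets, function(s) all_wells %in% s)
  if (length(all_wells) == 1L) member <- matrix(member, nrow = 1L,
                                                dimnames = list(NULL, names(sets)))
  methods_str <- apply(member, 1L, function(z)
    paste(names(sets)[z], collapse = "+"))
  venn <- table(methods_str)
  list(hits = data.frame(well = all_wells, methods = methods_str,
                         n_methods = rowSums(member), row.names = NULL,
                         stringsAsFactors = FALSE),
       venn = setNames(as.integer(venn), names(venn)))
}
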