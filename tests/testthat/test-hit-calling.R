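# intensity cutoffs, control SVM, distance calibration, clustering rule

fake_rp <- function(wells, p_by_metric) {
  met <- intensity_metrics()
  do.call(rbind, lapply(seq_len(nrow(met)), function(i) {
    key <- paste(met$feature[i], met$direction[i], sep = ".")
    p <- p_by_metric[[key]]
    if (is.null(p)) p <- rep(0.5, length(wells))
    data.frame(feature = met$feature[i], direction = met$direction[i],
               well = wells, rank = rank(p), rp = rank(p), p = p,
               n_perm = 100L)
  }))
}

fake_summaries <- function(wells, area = rep(240, length(wells))) {
  data.frame(well = wells, amplicon_id = paste0("A_", wells),
             role = "sample", replicate = 1L, n_nuclei = 100L, area = area)
}

test_that("intensity rule applies the four cutoffs and exclusions", {
  wells <- sprintf("W%02d", 1:6)
  p <- list(
    "mean_hp1a.decrease" = c(5e-4, 0.5, 0.5, 0.5, 0.5, 2e-4),
    "relative_max_hp1a.decrease" = c(0.5, 1.4e-3, 0.5, 0.5, 0.5, 0.5),
    "kurtosis_hp1a.increase" = c(0.5, 0.5, 6e-4, 0.5, 0.5, 0.5),
    "n_nuclei.decrease" = c(0.5, 0.5, 0.5, 0.5, 0.5, 0.01),
    "mean_hp1a.increase" = c(0.5, 0.5, 0.5, 0.01, 0.01, 0.5),
    "max_hp1a.increase" = c(0.5, 0.5, 0.5, 0.01, 0.01, 0.5))
  area <- c(240, 240, 240, 240, 240, 80)  # W6: shrunken nuclei
  hits <- call_hits_intensity(fake_rp(wells, p), fake_summaries(wells, area))

  pos <- hits$well[hits$direction == "positive_regulator"]
  # W1 passes dec-mean at 5e-4 < 6.3e-4; W2 passes rel-max 1.4e-3 < 1.5e-3
  expect_true(all(c("W01", "W02") %in% pos))
  # W3 kurtosis 6e-4 is NOT below the 5e-4 kurtosis cutoff
  expect_false("W03" %in% pos)
  # W6 would pass dec-mean but carries the cell-death signature
  expect_false("W06" %in% pos)

  neg <- hits$well[hits$direction == "negative_regulator"]
  expect_setequal(neg, c("W04", "W05"))

  # the same increased wells are excluded when cell number drops
  p2 <- p; p2[["n_nuclei.decrease"]] <- c(0.5, 0.5, 0.5, 0.01, 0.5, 0.01)
  hits2 <- call_hits_intensity(fake_rp(wells, p2),
                               fake_summaries(wells, area))
  neg2 <- hits2$well[hits2$direction == "negative_regulator"]
  expect_setequal(neg2, "W05")

  expect_error(call_hits_intensity(fake_rp(wells, p)[1:6, ],
                                   fake_summaries(wells)), "missing metric")
})

test_that("cutoff calibration sets each metric just above its worst
          positive control", {
  wells <- sprintf("W%02d", 1:10)
  p <- list("mean_hp1a.decrease" = c(1e-4, 3e-4, seq(0.1, 0.8, length.out = 8)))
  rp <- fake_rp(wells, p)
  roles <- setNames(c("pos_hp1a", "pos_hp1a", rep("sample", 8)), wells)
  cf <- calibrate_intensity_cutoffs(rp, roles)
  expect_gte(cf$p_dec_mean, 3e-4)
  expect_lt(cf$p_dec_mean, 4e-4)
})

test_that("control SVM separates controls and flags planted wells", {
  sim <- simulate_screen(n_wells = 150, n_pos = 10, n_neg = 8,
                         n_planted = 8, seed = 900)
  X <- rank_product_matrix(sim$summaries)
  roles <- setNames(sim$truth$role, sim$truth$well)
  sv <- train_control_svm(X, roles, svm_spec(), seed = 1)
  # training data (controls) must be classified correctly
  pred <- call_hits_svm(sv, X)
  ctrl_pos <- sim$truth$well[sim$truth$role == "pos_hp1a"]
  expect_true(all(pred$svm_positive[pred$well %in% ctrl_pos]))
  expect_gte(sv$withheld_recall, 0.8)
  # planted wells resemble the positive controls
  planted <- sim$truth$well[sim$truth$planted]
  expect_gte(mean(pred$svm_positive[pred$well %in% planted]), 0.75)
  # feature mismatch fails
  expect_error(call_hits_svm(sv, X[, 1:5]), "mismatch")
  # HP1a-only variant (kernel parameter 0.4) also works
  Xh <- rank_product_matrix(sim$summaries, hp1a_only_features())
  svh <- train_control_svm(Xh, roles,
                           svm_spec(kernel_parameter = 0.4,
                                    features = hp1a_only_features()),
                           seed = 1)
  predh <- call_hits_svm(svh, Xh)
  expect_gte(mean(predh$svm_positive[predh$well %in% planted]), 0.5)
  expect_error(train_control_svm(X[1:4, ], roles[1:2]), "control wells")
})

test_that("SVM hit rate on null sample wells is low, and permuted labels
          carry no signal", {
  sim <- simulate_screen(n_wells = 150, n_pos = 10, n_neg = 8, seed = 901)
  X <- rank_product_matrix(sim$summaries)
  roles <- setNames(sim$truth$role, sim$truth$well)
  sv <- train_control_svm(X, roles, seed = 2)
  pred <- call_hits_svm(sv, X)
  samp <- sim$truth$well[sim$truth$role == "sample"]
  expect_lte(mean(pred$svm_positive[pred$well %in% samp]), 0.05)

  # permuted control labels: withheld-recall tuning cannot find real signal;
  # prediction on held-out samples is near chance
  acc <- vapply(1:5, function(s) {
    roles_p <- roles
    ctrl <- names(roles)[roles != "sample"]
    roles_p[ctrl] <- withr::with_seed(s, sample(roles[ctrl]))
    svp <- train_control_svm(X, roles_p, seed = s)
    predp <- call_hits_svm(svp, X)
    truly_pos <- names(roles)[roles == "pos_hp1a"]
    pos_rate_true <- mean(predp$svm_positive[predp$well %in% truly_pos])
    pos_rate_true
  }, numeric(1))
  expect_lt(mean(acc), 0.75)  # nowhere near the 1.0 of informative labels
})

test_that("shrinkage covariance reduces Mahalanobis to Euclidean under
          identity covariance", {
  X <- withr::with_seed(5, matrix(rnorm(200), 40, 5))
  rownames(X) <- sprintf("W%02d", 1:40)
  Dm <- pairwise_distances(X, "mahalanobis", cov_matrix = diag(5))
  De <- pairwise_distances(X, "euclidean")
  expect_equal(Dm, De, tolerance = 1e-12)
  cs <- cov_shrink(X)
  expect_gte(cs$lambda, 0); expect_lte(cs$lambda, 1)
  expect_true(isSymmetric(cs$cov))
  # correlation distances are in [0, 2]
  Dp <- pairwise_distances(X, "pearson")
  expect_true(all(Dp >= -1e-12 & Dp <= 2 + 1e-12))
})

test_that("distance calibration anchors the 1-percentile to p = 0.01 and is
          monotone", {
  X <- withr::with_seed(7, matrix(runif(120 * 10), 120, 10))
  rownames(X) <- sprintf("W%03d", 1:120)
  cal <- calibrate_distance_pvalues(X, "euclidean", n_randomizations = 10,
                                    seed = 3)
  q01 <- quantile(cal$null, 0.01, type = 1)
  expect_equal(distance_pvalue(cal, q01), 0.01, tolerance = 2 / cal$n)
  d <- seq(0, max(cal$null), length.out = 200)
  p <- distance_pvalue(cal, d)
  expect_true(all(diff(p) >= 0))
  expect_true(all(p > 0 & p <= 1))
  expect_lte(distance_pvalue(cal, 0), min(p))
  expect_error(calibrate_distance_pvalues(X[1:50, ], "euclidean"), "100")
  expect_error(calibrate_distance_pvalues(X, n_randomizations = 3), "10")
})

test_that("clustering rule needs five close controls and two metrics", {
  # 110 wells; 6 HP1a controls share one tight profile; one sample well
  # copies it exactly, another is close to only 4 controls
  n <- 110
  X <- withr::with_seed(11, matrix(runif(n * 8), n, 8))
  rownames(X) <- sprintf("W%03d", 1:n)
  proto <- X[1, ]
  ctrl <- sprintf("W%03d", 1:6)
  for (w in ctrl) X[w, ] <- proto
  X["W007", ] <- proto                  # exact copy: distance 0 to 6 controls
  roles <- setNames(rep("sample", n), rownames(X))
  roles[ctrl] <- "pos_hp1a"
  cl <- call_hits_clustering(X, roles, seed = 4)
  expect_true(cl$pairwise_hit[cl$well == "W007"])
  # controls themselves: self-distance excluded but 5 other controls remain
  expect_true(all(cl$pairwise_hit[cl$well %in% ctrl]))
  # dendrogram flags the cluster-mates of the controls
  expect_true(cl$dendro_hp1a[cl$well == "W007"])

  # close to only 4 distinct controls: not flagged by the pairwise rule
  X2 <- X
  X2[ctrl[5:6], ] <- withr::with_seed(12, runif(16))  # only 4 identical left
  cl2 <- call_hits_clustering(X2, roles, seed = 4)
  expect_false(cl2$pairwise_hit[cl2$well == "W007"])

  expect_error(call_hits_clustering(X[, ], roles[
    c(ctrl[1:4], sprintf("W%03d", 7:110))], seed = 1), ">= 5")
})

test_that("combine_hits unions subsets with per-method provenance", {
  co <- combine_hits(list(intensity = c("g1", "g2"), svm = c("g2", "g3"),
                          clustering = "g1"))
  expect_setequal(co$hits$well, c("g1", "g2", "g3"))
  expect_equal(co$hits$n_methods[co$hits$well == "g2"], 2)
  expect_equal(sum(co$venn), 3L)

  disj <- combine_hits(list(a = c("x", "y"), b = c("z")))
  expect_equal(nrow(disj$hits), 3L)
  all3 <- combine_hits(list(a = "g", b = "g", c = "g"))
  expect_equal(all3$hits$n_methods, 3)
})
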