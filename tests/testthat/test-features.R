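# per-nucleus features and well aggregation

test_that("pearson_cc matches its closed form and obeys invariances", {
  a <- c(1, 2, 3, 4); b <- c(1, 2, 3, 5)
  expect_equal(pearson_cc(a, b), pearson_sum_formula(a, b),
               tolerance = 1e-12)
  expect_equal(pearson_cc(a, b), 0.9827076, tolerance = 1e-6)
  expect_identical(pearson_cc(a, a), 1)
  expect_identical(pearson_cc(a, -a + 70000), -1)
  expect_true(is.na(pearson_cc(a, rep(2, 4))))
  expect_error(pearson_cc(a, c(1, 2)), "equal length")
  # symmetry and positive-affine invariance on random draws
  for (s in 1:5) {
    v <- withr::with_seed(s, list(x = rnorm(30), y = rnorm(30)))
    expect_equal(pearson_cc(v$x, v$y), pearson_cc(v$y, v$x))
    expect_equal(pearson_cc(v$x, v$y), pearson_cc(3.7 * v$x + 11, v$y),
                 tolerance = 1e-12)
  }
})

test_that("extract_features yields the 33 canonical features with correct
          degenerate-case conventions", {
  expect_length(canonical_features(), 33L)
  expect_false(any(grepl("gh2av", hp1a_only_features())))

  disk <- disk_mask(10)
  f <- flat_field(disk, list(dapi = 500, hp1a = 700, gh2av = 300))
  fe <- extract_features(new_nucleus_mask(disk), f)
  expect_equal(nrow(fe), 1L)
  expect_setequal(setdiff(names(fe), "label"), canonical_features())
  expect_equal(fe$relative_max_hp1a, 1)
  expect_equal(fe$kurtosis_hp1a, 0)
  expect_equal(fe$sd_hp1a, 0)
  expect_equal(fe$edge_center_ratio_dapi, 1)
  expect_true(is.na(fe$pcc_hp1a_dapi))  # constant channels: undefined

  expect_error(extract_features(new_nucleus_mask(disk), f,
                                channels = c("dapi", "mcherry")), "absent")
})

test_that("kurtosis equals the direct-summation oracle on a 5x5 patch", {
  patch <- matrix(c(10, 12, 11, 13, 14,
                    12, 15, 16, 14, 13,
                    11, 16, 40, 15, 12,
                    12, 14, 15, 13, 11,
                    10, 13, 12, 11, 10), 5, 5)
  lab <- matrix(1L, 5, 5)
  f <- image_field(list(dapi = patch, hp1a = patch, gh2av = patch))
  fe <- extract_features(new_nucleus_mask(lab), f)
  x <- as.numeric(patch)
  s2 <- sum((x - mean(x))^2) / length(x)
  k_oracle <- sum((x - mean(x))^4) / (length(x) * s2^2) - 3
  expect_equal(fe$kurtosis_dapi, k_oracle, tolerance = 1e-12)
  sk_oracle <- sum((x - mean(x))^3) / (length(x) * s2^1.5)
  expect_equal(fe$skew_dapi, sk_oracle, tolerance = 1e-12)
  # extraction is reproducible bit-for-bit
  expect_identical(fe, extract_features(new_nucleus_mask(lab), f))
})

test_that("well aggregation is the median and robust to outliers", {
  one <- data.frame(label = 1, mean_hp1a = 5, area = 100)
  row <- list(well = "W1", amplicon_id = "A", role = "sample",
              replicate = 1L)
  ag <- aggregate_well(one, row)
  expect_equal(ag$mean_hp1a, 5)
  expect_equal(ag$n_nuclei, 1L)

  vals <- c(1:7)
  with_outlier <- data.frame(label = 1:7, mean_hp1a = c(1:6, 1e6))
  expect_equal(aggregate_well(with_outlier, row)$mean_hp1a, median(vals))

  # order-statistic calibration: median of 101 nuclei ~ N(2000, 100^2)
  meds <- vapply(1:40, function(s) {
    x <- withr::with_seed(s, rnorm(101, 2000, 100))
    aggregate_well(data.frame(label = 1:101, mean_hp1a = x), row)$mean_hp1a
  }, numeric(1))
  expect_true(all(meds > 1950 & meds < 2050))
  expect_true(mean(meds > 1970 & meds < 2030) > 0.9)

  empty <- aggregate_well(with_outlier[0, ], row)
  expect_equal(empty$n_nuclei, 0L)
  expect_true(is.na(empty$mean_hp1a))
})

test_that("per-nucleus PCC ordering across coloc patterns holds", {
  med <- function(pat) {
    pcc <- c()
    for (s in 1:6) {
      g <- generate_coloc_pair(pat, seed = 40 + s)
      w <- compute_well_pcc(list(g$field), pat)
      pcc <- c(pcc, w$pcc)
    }
    expect_gte(length(pcc), 50L)
    median(pcc)
  }
  m_broad <- med("broad"); m_narrow <- med("narrow")
  m_pan <- med("pan_nuclear")
  expect_gt(m_broad, 0.8)
  expect_gt(m_broad, m_narrow)
  expect_gt(m_narrow, m_pan)
})
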