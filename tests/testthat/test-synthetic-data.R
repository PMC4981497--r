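# generators: determinism, ground truth bookkeeping, planted-effect
# calibration

test_that("nuclei field generator plants the requested ground truth", {
  cfg <- screen_sim_config()
  g <- generate_nuclei_field(10, cfg, seed = 1)
  expect_length(unique(g$truth$mask[g$truth$mask > 0]), 10L)
  expect_identical(dim(g$field$channels$dapi), dim(g$truth$mask))
  expect_true(all(g$field$channels$hp1a >= 0 & g$field$channels$hp1a <= 65535))

  blank <- generate_nuclei_field(0, cfg, seed = 2)
  expect_identical(sum(blank$truth$mask), 0L)
  expect_equal(nrow(blank$truth$centers), 0L)

  g2 <- generate_nuclei_field(10, cfg, seed = 1)
  expect_identical(g$field$channels, g2$field$channels)
  g3 <- generate_nuclei_field(10, cfg, seed = 99)
  expect_false(identical(g$field$channels$dapi, g3$field$channels$dapi))
})

test_that("impossible nucleus placement fails loudly, not by truncation", {
  cfg <- screen_sim_config(field_size_px = 48L)
  expect_error(generate_nuclei_field(60, cfg, seed = 1), "cannot place")
})

test_that("screen plate carries layout, replicates and planted factors", {
  cfg <- screen_sim_config(n_wells_per_plate = 8L, n_fields_per_well = 1L,
                           nuclei_per_field = list(mean = 6, dispersion = 8),
                           field_size_px = 128L, seed = 5L)
  pl <- generate_screen_plate(cfg)
  expect_length(pl$fields, 2L)
  expect_identical(names(pl$fields[[1]]), pl$layout$well)
  expect_identical(pl$truth$effect[pl$truth$role == "pos_hp1a"],
                   rep(0.4, 2))
  # replicates share layout but differ in pixels
  w <- pl$layout$well[1]
  expect_false(identical(pl$fields[[1]][[w]][[1]]$field$channels$dapi,
                         pl$fields[[2]][[w]][[1]]$field$channels$dapi))
  # a layout without controls is rejected
  bad <- pl$layout; bad$role <- "sample"
  expect_error(generate_screen_plate(cfg, bad), "control")
})

test_that("planted multiplicative HP1a factor is recovered from images", {
  # factor 0.5 wells vs untreated wells, >= 200 nuclei per arm
  cfg <- screen_sim_config()
  med_hp1a <- function(effect, seeds) {
    v <- c()
    for (s in seeds) {
      g <- generate_nuclei_field(12, cfg, seed = s, effect = effect,
                                 touching_fraction = 0)
      thr <- plate_threshold(list(g$field$channels$dapi), sigma = 25)
      m <- segment_nuclei(g$field$channels$dapi, thr, sigma = 25)
      fe <- extract_features(m, g$field)
      v <- c(v, fe$mean_hp1a)
    }
    v
  }
  a <- med_hp1a(0.5, 1:18)
  b <- med_hp1a(1.0, 101:118)
  expect_gte(length(a), 200L)
  expect_gte(length(b), 200L)
  ratio <- mean(a) / mean(b)
  expect_gte(ratio, 0.45)
  expect_lte(ratio, 0.55)
})

test_that("well-level screen simulator is exchangeable under the null", {
  sim <- simulate_screen(n_wells = 60, n_pos = 0, n_neg = 0, seed = 42)
  expect_equal(nrow(sim$summaries), 120L)
  # Welch tests between random halves of the wells: no systematic effect
  s1 <- sim$summaries[sim$summaries$replicate == 1, ]
  ps <- vapply(1:20, function(i) {
    idx <- withr::with_seed(i, sample(nrow(s1), nrow(s1) / 2))
    t.test(s1$mean_hp1a[idx], s1$mean_hp1a[-idx])$p.value
  }, numeric(1))
  expect_gt(mean(ps), 0.2)       # roughly uniform, not piled near 0
  expect_lt(mean(ps < 0.05), 0.25)
  # planted factor shifts the HP1a features in the right directions
  eff <- simulate_screen(n_wells = 60, n_pos = 10, n_neg = 0,
                         pos_factor = 0.4, seed = 43)
  pos <- eff$summaries$role == "pos_hp1a"
  expect_lt(median(eff$summaries$mean_hp1a[pos]),
            median(eff$summaries$mean_hp1a[!pos]))
  expect_lt(median(eff$summaries$relative_max_hp1a[pos]),
            median(eff$summaries$relative_max_hp1a[!pos]))
  expect_gt(median(eff$summaries$kurtosis_hp1a[pos]),
            median(eff$summaries$kurtosis_hp1a[!pos]))
})

test_that("coloc and eye generators are seed-deterministic", {
  a <- generate_coloc_pair("broad", seed = 3)
  b <- generate_coloc_pair("broad", seed = 3)
  expect_identical(a$field$channels, b$field$channels)
  expect_error(generate_coloc_pair("spiral", seed = 1))

  e1 <- generate_eye_image(0.4, seed = 5)
  e2 <- generate_eye_image(0.4, seed = 5)
  expect_identical(e1$image, e2$image)
  expect_error(generate_eye_image(1.2, seed = 1), "red_fraction")
  expect_error(generate_eye_image(-0.1, seed = 1), "red_fraction")
})
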