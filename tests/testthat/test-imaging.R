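# background subtraction, Crofton perimeter, segmentation, QC gating

test_that("background subtraction removes constants and keeps impulses", {
  flat <- matrix(500, 64, 64)
  expect_true(all(subtract_background(flat, sigma = 10) == 0))
  expect_error(subtract_background(flat, sigma = 0), "sigma")
  expect_error(subtract_background(flat, sigma = -3), "sigma")

  # impulse: output peak = impulse * (1 - Gaussian kernel center weight),
  # with the blur recomputed by direct dense convolution as the oracle
  img <- matrix(0, 101, 101); img[51, 51] <- 1000
  out <- subtract_background(img, sigma = 5)
  sz <- 2 * ceiling(3 * 5) + 1
  g1 <- dnorm(seq_len(sz) - (sz + 1) / 2, sd = 5)
  k <- outer(g1, g1); k <- k / sum(k)
  expect_equal(out[51, 51], 1000 * (1 - k[(sz + 1) / 2, (sz + 1) / 2]),
               tolerance = 1e-6)

  # segmentation is invariant to adding a constant to the DAPI channel
  g <- generate_nuclei_field(8, screen_sim_config(), seed = 11,
                             touching_fraction = 0)
  dapi <- g$field$channels$dapi
  thr <- plate_threshold(list(dapi), sigma = 25)
  m1 <- segment_nuclei(dapi, thr, sigma = 25)
  m2 <- segment_nuclei(pmin(dapi + 700, 65535), thr, sigma = 25)
  expect_identical(m1$labels, m2$labels)
})

test_that("off-nucleus residual after subtraction is small", {
  g <- generate_nuclei_field(10, screen_sim_config(), seed = 21,
                             touching_fraction = 0)
  bs <- subtract_background(g$field$channels$dapi, 25)
  off <- bs[g$truth$mask == 0]
  fe_mean <- mean(g$field$channels$dapi[g$truth$mask > 0])
  expect_lt(median(off), 0.01 * fe_mean)
})

test_that("Crofton roundness of disks converges to 4*pi, and matches the
          reference implementation", {
  # frozen oracle values from an independent implementation of the
  # 4-direction Crofton estimator (scikit-image perimeter_crofton)
  ref <- c(`10` = 65.197624164341, `20` = 127.71373126734748,
           `40` = 252.74594547336048)
  errs <- sapply(c(10, 20, 40), function(r) {
    m <- disk_mask(r)
    p <- crofton_perimeter(m)
    expect_equal(unname(p), unname(ref[as.character(r)]), tolerance = 1e-9)
    abs(p^2 / sum(m) - 4 * pi)
  })
  expect_true(all(diff(errs) < 0))           # error decreases with radius
  expect_lt(errs[2], 0.5)
  # isoperimetric bound (up to discretization tolerance)
  st <- mask_shape_stats(disk_mask(20))
  expect_gte(st$roundness, 4 * pi - 0.2)
})

test_that("segmentation recovers disks, blanks, and touching pairs", {
  blank <- matrix(200, 96, 96)
  expect_equal(nrow(segment_nuclei(blank, 1000, sigma = 20)$shape), 0L)

  # single above-threshold disk, radius 20: one label, area within 5%
  img <- matrix(0, 101, 101)
  img[disk_mask(20, pad = 30) > 0] <- 8000
  m <- segment_nuclei(img, 2000, sigma = 40)
  expect_equal(nrow(m$shape), 1L)
  expect_lt(abs(m$shape$area - pi * 400) / (pi * 400), 0.05)

  # two clean disks, centers 1.4 radii apart: split into 2 labels with the
  # boundary near the planted bisector
  r <- 12; n <- 96
  c1 <- c(40, 48); c2 <- c(40 + 1.4 * r, 48)
  xs <- matrix(rep(1:n, n), n, n); ys <- matrix(rep(1:n, each = n), n, n)
  d1 <- sqrt((xs - c1[1])^2 + (ys - c1[2])^2)
  d2 <- sqrt((xs - c2[1])^2 + (ys - c2[2])^2)
  img <- matrix(0, n, n); img[d1 <= r | d2 <= r] <- 8000
  m <- segment_nuclei(img, 2000, sigma = 40, min_area = 40)
  expect_equal(nrow(m$shape), 2L)
  # every pixel of the split should sit with its nearer planted center,
  # within a 2 px band around the bisector
  lab <- m$labels
  own1 <- lab[d1 < d2 - 2 & lab > 0]
  own2 <- lab[d2 < d1 - 2 & lab > 0]
  expect_length(unique(own1), 1L)
  expect_length(unique(own2), 1L)
  expect_false(unique(own1) == unique(own2))
})

test_that("QC gates flag low-intensity, saturated and non-round nuclei", {
  disk <- disk_mask(15)
  f <- flat_field(disk, list(gfp = 3500, mcherry = 5000))
  m <- qc_filter(new_nucleus_mask(disk), f,
                 min_mean = c(gfp = 4000, mcherry = 3000))
  expect_true(m$qc$low_intensity)
  expect_false(m$qc$pass)

  f2 <- flat_field(disk, list(gfp = 65535, mcherry = 5000))
  m2 <- qc_filter(new_nucleus_mask(disk), f2,
                  min_mean = c(gfp = 4000, mcherry = 3000))
  expect_true(m2$qc$saturated)

  # perfect disk retained; 5:1 ellipse of equal area flagged at 2 * 4pi
  a <- sqrt(400 * 5); b <- sqrt(400 / 5)
  ell <- ellipse_mask(a, b)
  fd <- flat_field(disk, list(gfp = 9000))
  fe <- flat_field(ell, list(gfp = 9000))
  md <- qc_filter(new_nucleus_mask(disk), fd, max_roundness = 8 * pi)
  me <- qc_filter(new_nucleus_mask(ell), fe, max_roundness = 8 * pi)
  expect_false(md$qc$non_round)
  expect_true(me$qc$non_round)

  # gate on a channel the field lacks fails
  expect_error(qc_filter(new_nucleus_mask(disk), fd,
                         min_mean = c(dapi = 100)), "absent")
})

test_that("image fields round-trip through multi-page 16-bit TIFF", {
  g <- generate_nuclei_field(5, screen_sim_config(field_size_px = 96L),
                             seed = 77, touching_fraction = 0)
  path <- tempfile(fileext = ".tif")
  write_field_tiff(g$field, path)
  back <- read_field_tiff(path)
  expect_identical(back$channel_names, g$field$channel_names)
  expect_equal(back$channels$dapi, g$field$channels$dapi, tolerance = 1e-9)
  expect_error(read_field_tiff(path, channel_names = c("a", "b")), "pages")
  unlink(path)
})
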