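# nuclear segmentation and quality gating

#' Gaussian-blur background subtraction
#'
#' Corrects background heterogeneity by subtracting the image blurred with a
#' wide Gaussian filter, clipping at zero. `sigma` should be much larger than
#' the nucleus radius so nuclei survive the subtraction; a flat image maps to
#' exactly zero. The image is edge-replicate padded before blurring so any
#' `sigma` is admissible.
#'
#' @param channel numeric intensity matrix
#' @param sigma Gaussian sd in pixels (> 0); default 50
#' @return background-subtracted matrix (>= 0)
#' @export
subtract_background <- function(channel, sigma = 50) {
  stopifnot(is.matrix(channel))
  if (!is.numeric(sigma) || length(sigma) != 1L || is.na(sigma) || sigma <= 0)
    stop("sigma must be a single positive number")
  p <- 2L * as.integer(ceiling(3 * sigma)) + 2L
  padded <- pad_replicate(channel, p)
  bl <- as.matrix(EBImage::gblur(padded, sigma = sigma))
  bl <- bl[(p + 1L):(p + nrow(channel)), (p + 1L):(p + ncol(channel))]
  out <- pmax(channel - bl, 0)
  # zap FFT roundoff so a flat input maps to exactly zero
  out[out <= 1e-7 * (abs(channel) + 1)] <- 0
  out
}

#' Crofton perimeter of labelled regions
#'
#' Four-direction Crofton estimate of each region's boundary length, the
#' integral-geometry estimator whose error on rasterized disks decreases
#' with radius (so the roundness metric P^2/A of a disk converges to 4*pi).
#'
#' @param labels integer label matrix (0 = background)
#' @return named numeric vector of perimeters, one per label
#' @export
crofton_perimeter <- function(labels) {
  labs <- sort(unique(labels[labels > 0]))
  if (!length(labs)) return(setNames(numeric(0), character(0)))
  s2 <- sqrt(2)
  lut <- c(0, pi / 4 * (1 + 1 / s2), pi / (4 * s2), pi / (2 * s2),
           0, pi / 4 * (1 + 1 / s2), 0, pi / (4 * s2),
           pi / 4, pi / 2, pi / (4 * s2), pi / (4 * s2),
           pi / 4, pi / 2, 0, 0)
  out <- setNames(numeric(length(labs)), labs)
  for (i in seq_along(labs)) {
    # crop to the label's bounding box for speed
    idx <- which(labels == labs[i], arr.ind = TRUE)
    r0 <- range(idx[, 1L]); c0 <- range(idx[, 2L])
    sub <- labels[r0[1L]:r0[2L], c0[1L]:c0[2L], drop = FALSE] == labs[i]
    p <- matrix(0L, nrow(sub) + 2L, ncol(sub) + 2L)
    p[2L:(nrow(sub) + 1L), 2L:(ncol(sub) + 1L)] <- sub
    n <- nrow(p); m <- ncol(p)
    # 2x2 configuration code over the padded image
    a <- p[-n, -m]; bq <- p[-n, -1L]; cq <- p[-1L, -m]; d <- p[-1L, -1L]
    code <- a + 4L * bq + 2L * cq + 8L * d
    out[i] <- sum(lut[code + 1L])
  }
  out
}

# per-label shape statistics: area, Crofton perimeter, centroid, roundness
# (P^2/A), eccentricity, solidity (convex-hull based), equivalent diameter,
# edge_touching flag
mask_shape_stats <- function(labels) {
  labs <- sort(unique(labels[labels > 0]))
  if (!length(labs))
    return(data.frame(label = integer(0), area = numeric(0),
                      perimeter = numeric(0), cx = numeric(0), cy = numeric(0),
                      roundness = numeric(0), eccentricity = numeric(0),
                      solidity = numeric(0), equiv_diameter = numeric(0),
                      edge_touching = logical(0)))
  per <- crofton_perimeter(labels)
  n <- nrow(labels); m <- ncol(labels)
  res <- lapply(labs, function(l) {
    idx <- which(labels == l, arr.ind = TRUE)
    A <- nrow(idx)
    cx <- mean(idx[, 1L]); cy <- mean(idx[, 2L])
    # central moments for eccentricity
    dx <- idx[, 1L] - cx; dy <- idx[, 2L] - cy
    mxx <- mean(dx^2) + 1 / 12; myy <- mean(dy^2) + 1 / 12
    mxy <- mean(dx * dy)
    tr <- mxx + myy
    det2 <- sqrt(pmax((mxx - myy)^2 + 4 * mxy^2, 0))
    l1 <- (tr + det2) / 2; l2 <- (tr - det2) / 2
    ecc <- if (l1 <= 0) 0 else sqrt(pmax(1 - l2 / l1, 0))
    # solidity via convex hull of pixel centers (shoelace area + A/2 rim)
    sol <- if (A >= 3L) {
      h <- grDevices::chull(idx[, 1L], idx[, 2L])
      hx <- idx[h, 1L]; hy <- idx[h, 2L]
      hull_area <- abs(sum(hx * c(hy[-1L], hy[1L]) -
                           c(hx[-1L], hx[1L]) * hy)) / 2
      # hull of centers misses the half-pixel rim; approximate with +P/2
      min(A / max(hull_area + unname(per[as.character(l)]) / 2, 1e-9), 1)
    } else 1
    edge <- any(idx[, 1L] %in% c(1L, n) | idx[, 2L] %in% c(1L, m))
    data.frame(label = l, area = A,
               perimeter = unname(per[as.character(l)]),
               cx = cx, cy = cy,
               roundness = unname(per[as.character(l)])^2 / A,
               eccentricity = ecc, solidity = sol,
               equiv_diameter = 2 * sqrt(A / pi), edge_touching = edge)
  })
  do.call(rbind, res)
}

#' Constant plate threshold from negative-control fields
#'
#' The screen uses one constant intensity threshold per plate, derived from
#' the pooled background-subtracted DAPI pixels of the given
#' (negative-control) fields and then held fixed for every well of the
#' plate: Otsu's split scaled by `factor`. On strongly bimodal fluorescence
#' the raw Otsu value sits far up the nuclear intensity class and clips the
#' soft rims of dim nuclei; scaling it toward the background mode (default
#' 0.65) keeps whole nuclei while staying far above background noise.
#'
#' @param dapi_list list of DAPI matrices (raw)
#' @param sigma background-blur sigma passed to [subtract_background()]
#' @param factor multiplier applied to the Otsu split
#' @return scalar threshold (AU)
#' @export
plate_threshold <- function(dapi_list, sigma = 50, factor = 0.65) {
  stopifnot(length(dapi_list) >= 1L, factor > 0)
  pooled <- unlist(lapply(dapi_list, function(x)
    as.numeric(subtract_background(x, sigma))))
  m <- matrix(pooled, ncol = 1L)
  factor *
    as.numeric(EBImage::otsu(m / 65535, range = c(0, 1), levels = 256L)) *
    65535
}

#' Background-statistics segmentation threshold
#'
#' Threshold set from the background pixel population of
#' background-subtracted images: median + `k` robust standard deviations
#' (1.4826 MAD). Appropriate when the marker has a bright subnuclear
#' compartment (e.g. mCherry-HP1a chromocenters) so that Otsu's bimodal
#' split would cut between nucleoplasm and compartment instead of between
#' background and nucleus.
#'
#' @param channel_list list of raw intensity matrices
#' @param sigma background-blur sigma ([subtract_background()])
#' @param k number of robust SDs above the background median
#' @return scalar threshold (AU)
#' @export
background_threshold <- function(channel_list, sigma = 25, k = 8) {
  stopifnot(length(channel_list) >= 1L, k > 0)
  pooled <- unlist(lapply(channel_list, function(x)
    as.numeric(subtract_background(x, sigma))))
  max(median(pooled) + k * mad(pooled), 1)
}

#' Segment nuclei in a DAPI channel
#'
#' Background-subtracts the DAPI raster, binarizes at a constant threshold,
#' removes components below `min_area`, and separates touching nuclei by
#' seeded watershed on the distance transform (regional maxima suppressed by
#' an h-maxima depth `h` to avoid spurious splits of noisy distance maps).
#'
#' @param dapi DAPI intensity matrix
#' @param threshold constant binarization threshold (AU, > 0) applied to the
#'   background-subtracted image; see [plate_threshold()]
#' @param min_area minimum component area (px)
#' @param sigma background-blur sigma (px)
#' @param h h-maxima depth (px) of the watershed seed suppression
#'   (default 0.3: the cleaned distance maps carry few spurious maxima, and
#'   deeper suppression merges genuinely touching pairs)
#' @return a `nucleus_mask`: list with `labels` (integer matrix) and `shape`
#'   (per-label shape statistics from [mask_shape_stats()])
#' @export
segment_nuclei <- function(dapi, threshold, min_area = 60, sigma = 50, h = 0.3) {
  stopifnot(is.matrix(dapi))
  if (threshold <= 0) stop("threshold must be > 0")
  bs <- subtract_background(dapi, sigma)
  bin <- bs > threshold
  if (!any(bin)) return(new_nucleus_mask(matrix(0L, nrow(dapi), ncol(dapi))))
  lab <- as.matrix(EBImage::bwlabel(bin))
  tab <- tabulate(lab[lab > 0])
  small <- which(tab < min_area)
  if (length(small)) {
    bin[lab %in% small] <- FALSE
    if (!any(bin))
      return(new_nucleus_mask(matrix(0L, nrow(dapi), ncol(dapi))))
  }
  dm <- EBImage::distmap(matrix(as.integer(bin), nrow(bin), ncol(bin)))
  ws <- as.matrix(EBImage::watershed(dm, tolerance = h))
  tab <- tabulate(ws[ws > 0])
  keep <- which(tab >= min_area)
  out <- matrix(0L, nrow(ws), ncol(ws))
  for (i in seq_along(keep)) out[ws == keep[i]] <- i
  new_nucleus_mask(out)
}

new_nucleus_mask <- function(labels, qc = NULL) {
  structure(list(labels = labels, shape = mask_shape_stats(labels), qc = qc),
            class = "nucleus_mask")
}

#' @export
print.nucleus_mask <- function(x, ...) {
  cat(sprintf("nucleus_mask: %d nuclei in %dx%d px\n",
              nrow(x$shape), nrow(x$labels), ncol(x$labels)))
  invisible(x)
}

#' Quality-gate segmented nuclei
#'
#' Flags nuclei failing any gate and removes them from the mask used for
#' feature aggregation. Gates: per-channel low-intensity floors (defaults as
#' used in the low-resolution colocalization screen: GFP < 4000 AU and
#' mCherry < 3000 AU are background), saturation (mean at the 16-bit
#' maximum), roundness (P^2/A above `max_roundness`; a perfect disk is
#' ~4*pi), and field-edge truncation.
#'
#' @param mask a `nucleus_mask` from [segment_nuclei()]
#' @param field an [image_field()] sharing the mask's dimensions
#' @param min_mean named numeric vector of per-channel intensity floors (AU);
#'   names must be channels of `field`
#' @param saturation mean-intensity ceiling (AU), default 16-bit max
#' @param max_roundness maximum admissible P^2/A (default `8 * pi`, twice
#'   the disk bound)
#' @param exclude_edge flag and drop nuclei touching the field edge
#' @return the mask with a `qc` data.frame (per-nucleus flags) and `labels`
#'   retaining only QC-passing nuclei
#' @export
qc_filter <- function(mask, field, min_mean = numeric(0),
                      saturation = 65535, max_roundness = 8 * pi,
                      exclude_edge = TRUE) {
  stopifnot(inherits(mask, "nucleus_mask"), inherits(field, "image_field"))
  if (length(min_mean) && !all(names(min_mean) %in% field$channel_names))
    stop("min_mean refers to channels absent from the field: ",
         paste(setdiff(names(min_mean), field$channel_names), collapse = ", "))
  sh <- mask$shape
  if (!nrow(sh)) { mask$qc <- data.frame(); return(mask) }
  lab_vec <- as.integer(mask$labels)
  means <- sapply(field$channel_names, function(ch) {
    v <- as.numeric(field$channels[[ch]])
    as.numeric(tapply(v[lab_vec > 0], lab_vec[lab_vec > 0], mean)[
      as.character(sh$label)])
  })
  if (is.null(dim(means))) means <- matrix(means, nrow = 1L,
                                           dimnames = list(NULL, field$channel_names))
  low <- rep(FALSE, nrow(sh))
  for (ch in names(min_mean)) low <- low | means[, ch] < min_mean[[ch]]
  sat <- apply(means, 1L, function(x) any(x >= saturation))
  nonround <- sh$roundness > max_roundness
  edge <- if (exclude_edge) sh$edge_touching else rep(FALSE, nrow(sh))
  qc <- data.frame(label = sh$label,
                   low_intensity = low, saturated = sat,
                   non_round = nonround, edge_touching = edge)
  qc$pass <- !(low | sat | nonround | edge)
  drop <- sh$label[!qc$pass]
  if (length(drop)) {
    lab <- mask$labels
    lab[lab %in% drop] <- 0L
    mask$labels <- lab
  }
  mask$qc <- qc
  mask
}

#' Match a segmentation against a ground-truth label mask
#'
#' Greedy one-to-one matching by overlap coefficient (intersection over the
#' smaller of the two areas, robust to the segmented nucleus being smaller
#' than its planted disk when it is dim): a planted nucleus is recovered if
#' some segmented label overlaps it with coefficient above `min_overlap`
#' and that label is not claimed by another planted nucleus. A merged pair
#' can therefore satisfy at most one of its members.
#'
#' @param truth_mask planted integer label matrix
#' @param seg a `nucleus_mask` or integer label matrix
#' @param min_overlap minimum overlap coefficient for a match
#' @return list with `n_truth`, `n_seg`, `matches` (data.frame truth label,
#'   seg label, overlap, iou), and `recall`
#' @export
segmentation_recovery <- function(truth_mask, seg, min_overlap = 0.5) {
  seg_lab <- if (inherits(seg, "nucleus_mask")) seg$labels else seg
  tl <- sort(unique(truth_mask[truth_mask > 0]))
  sl <- sort(unique(seg_lab[seg_lab > 0]))
  if (!length(tl) || !length(sl))
    return(list(n_truth = length(tl), n_seg = length(sl),
                matches = data.frame(), recall = if (length(tl)) 0 else NA))
  both <- truth_mask > 0 & seg_lab > 0
  tab <- table(truth = truth_mask[both], seg = seg_lab[both])
  t_area <- tabulate(truth_mask[truth_mask > 0])
  s_area <- tabulate(seg_lab[seg_lab > 0])
  cand <- which(tab > 0, arr.ind = TRUE)
  stats <- apply(cand, 1L, function(ij) {
    ti <- as.integer(rownames(tab)[ij[1L]])
    si <- as.integer(colnames(tab)[ij[2L]])
    inter <- tab[ij[1L], ij[2L]]
    c(overlap = inter / min(t_area[ti], s_area[si]),
      iou = inter / (t_area[ti] + s_area[si] - inter))
  })
  ord <- order(stats["overlap", ], stats["iou", ], decreasing = TRUE)
  used_t <- integer(0); used_s <- integer(0)
  rows <- list()
  for (i in ord) {
    if (stats["overlap", i] < min_overlap) break
    ti <- as.integer(rownames(tab)[cand[i, 1L]])
    si <- as.integer(colnames(tab)[cand[i, 2L]])
    if (ti %in% used_t || si %in% used_s) next
    used_t <- c(used_t, ti); used_s <- c(used_s, si)
    rows[[length(rows) + 1L]] <- data.frame(truth = ti, seg = si,
                                            overlap = stats["overlap", i],
                                            iou = stats["iou", i])
  }
  matches <- if (length(rows)) do.call(rbind, rows) else data.frame()
  list(n_truth = length(tl), n_seg = length(sl), matches = matches,
       recall = nrow(matches) / length(tl))
}
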