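# position-effect variegation quantification: red-pixel masking of eye
# images and the two group tests (white and yellow variegation)

#' Red-pixel mask of an 8-bit RGB eye image
#'
#' A pixel is "red" (loss of silencing) iff its stored 8-bit RGB values fall
#' inside the gate R 0-255, G 0-90, B 0-20 (bounds inclusive). The gate is
#' defined on raw stored RGB values, with no color-space transform, and is
#' applied identically to every image.
#'
#' @param image height x width x 3 array of 8-bit RGB values
#' @param gate named numeric vector `c(r_max, g_max, b_max)` upper bounds
#' @return logical matrix
#' @export
red_pixel_mask <- function(image, gate = c(r_max = 255, g_max = 90,
                                           b_max = 20)) {
  if (length(dim(image)) != 3L || dim(image)[3L] != 3L)
    stop("expected an RGB array (h x w x 3)")
  if (any(image < 0 | image > 255) || any(image != round(image)))
    stop("expected 8-bit RGB values in 0..255")
  red <- image[, , 1L] <= gate[["r_max"]] &
    image[, , 2L] <= gate[["g_max"]] &
    image[, , 3L] <= gate[["b_max"]]
  matrix(red, dim(image)[1L], dim(image)[2L])
}

#' Red area fraction of the eye
#'
#' Fraction of eye pixels that are red: `|red & eye| / |eye|`. Red pixels
#' outside the eye mask are ignored.
#'
#' @param red_mask logical matrix from [red_pixel_mask()]
#' @param eye_mask logical matrix delimiting the eye (non-empty)
#' @return proportion in `[0, 1]`
#' @export
red_area_fraction <- function(red_mask, eye_mask) {
  if (!identical(dim(red_mask), dim(eye_mask)))
    stop("masks must share dimensions")
  n_eye <- sum(eye_mask)
  if (n_eye == 0L) stop("eye mask is empty")
  sum(red_mask & eye_mask) / n_eye
}

#' Locate the eye region in a synthetic RGB image
#'
#' Default eye finder for images without a supplied mask: foreground =
#' pixels markedly redder than the neutral background (R - G above
#' `min_rg_gap`), then the largest connected component. Eye masks of real
#' photographs were drawn manually; supply them via the `eye_mask` arguments
#' instead when available.
#'
#' @param image h x w x 3 8-bit RGB array
#' @param min_rg_gap minimum R - G difference for foreground pixels
#' @return logical matrix
#' @export
find_eye_mask <- function(image, min_rg_gap = 30) {
  fg <- (image[, , 1L] - image[, , 2L]) > min_rg_gap
  if (!any(fg)) stop("no eye-like foreground found")
  lab <- as.matrix(EBImage::bwlabel(fg))
  biggest <- which.max(tabulate(lab[lab > 0]))
  # pale (white/orange) facets inside the eye fail the R-G gap; close them
  as.matrix(EBImage::fillHull(lab == biggest)) > 0
}

#' Compare white-variegation red fractions between two groups
#'
#' Two-tailed two-sample unequal-variance (Welch) t-test with
#' Welch-Satterthwaite degrees of freedom.
#'
#' @param group_a,group_b per-fly red area fractions (n >= 2 each)
#' @return `pev_result` list: `statistic`, `df`, `p`, `test = "welch_t"`
#' @export
compare_white <- function(group_a, group_b) {
  stopifnot(length(group_a) >= 2L, length(group_b) >= 2L)
  if (var(group_a) == 0 && var(group_b) == 0) {
    if (mean(group_a) == mean(group_b)) {
      warning("both groups constant and equal; p = 1")
      return(structure(list(statistic = 0, df = NA_real_, p = 1,
                            test = "welch_t"), class = "pev_result"))
    }
    stop("both groups have zero variance with different means")
  }
  tt <- t.test(group_a, group_b, var.equal = FALSE)
  structure(list(statistic = unname(tt$statistic),
                 df = unname(tt$parameter), p = tt$p.value,
                 test = "welch_t"), class = "pev_result")
}

#' Compare yellow-variegation spot counts between two groups
#'
#' Two-sample Kolmogorov-Smirnov test on per-fly dark-spot counts (the
#' counts themselves are manual inputs). Exact p for small tie-free
#' samples, asymptotic otherwise.
#'
#' @param spots_a,spots_b integer spot counts per fly (n >= 2 each)
#' @return `pev_result` list: `statistic` (D), `p`, `test = "ks"`
#' @export
compare_yellow <- function(spots_a, spots_b) {
  stopifnot(length(spots_a) >= 2L, length(spots_b) >= 2L)
  kt <- suppressWarnings(ks.test(spots_a, spots_b))
  structure(list(statistic = unname(kt$statistic), df = NA_real_,
                 p = kt$p.value, test = "ks"), class = "pev_result")
}

#' @export
print.pev_result <- function(x, ...) {
  cat(sprintf("%s: statistic=%.4g p=%.4g\n", x$test, x$statistic, x$p))
  invisible(x)
}
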