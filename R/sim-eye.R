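# synthetic RGB eye photographs with a known red-pigment area fraction

#' Generate a synthetic fly-eye RGB image with known red fraction
#'
#' Renders an elliptical eye on a grey background. Inside the eye, exactly
#' `round(red_fraction * n_eye_pixels)` pixels are drawn from a red-pigment
#' color distribution lying strictly inside the red gate used by
#' [red_pixel_mask()] (R 150-255, G 10-80, B 0-10), and the remainder from a
#' white/orange pigment distribution strictly outside it (G 100-200,
#' B 40-120). Both distributions stay >= 10 gray levels away from every gate
#' boundary so recovered fractions are tolerance-stable.
#'
#' @param red_fraction target red area fraction in `[0, 1]`
#' @param seed integer seed
#' @param width,height image size in pixels
#' @return list with `image` (height x width x 3 integer array, 8-bit RGB),
#'   `eye_mask` (logical matrix), and `truth` (list with `red_fraction` and
#'   the planted red pixel mask)
#' @export
generate_eye_image <- function(red_fraction, seed = 1L,
                               width = 200L, height = 160L) {
  if (!is.numeric(red_fraction) || length(red_fraction) != 1L ||
      is.na(red_fraction) || red_fraction < 0 || red_fraction > 1)
    stop("red_fraction must be a single value in [0, 1]")
  with_seed(seed, {
    xs <- matrix(rep(seq_len(height), width), height, width)
    ys <- matrix(rep(seq_len(width), each = height), height, width)
    cx <- height / 2; cy <- width / 2
    a <- height * 0.38; b <- width * 0.34
    th <- runif(1, -0.3, 0.3)
    xr <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
    yr <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
    eye <- (xr / a)^2 + (yr / b)^2 <= 1
    n_eye <- sum(eye)

    R <- matrix(0L, height, width); G <- R; B <- R
    # grey background, far from the red gate (B >> 20)
    R[] <- sample(55:85, height * width, TRUE)
    G[] <- sample(55:85, height * width, TRUE)
    B[] <- sample(55:85, height * width, TRUE)

    idx_eye <- which(eye)
    n_red <- round(red_fraction * n_eye)
    red_idx <- if (n_red > 0L) sample(idx_eye, n_red) else integer(0)
    white_idx <- setdiff(idx_eye, red_idx)
    if (length(red_idx)) {
      R[red_idx] <- sample(150:255, length(red_idx), TRUE)
      G[red_idx] <- sample(10:80, length(red_idx), TRUE)
      B[red_idx] <- sample(0:10, length(red_idx), TRUE)
    }
    if (length(white_idx)) {
      R[white_idx] <- sample(200:255, length(white_idx), TRUE)
      G[white_idx] <- sample(100:200, length(white_idx), TRUE)
      B[white_idx] <- sample(40:120, length(white_idx), TRUE)
    }
    img <- array(0L, dim = c(height, width, 3L))
    img[, , 1L] <- R; img[, , 2L] <- G; img[, , 3L] <- B
    red_mask <- matrix(FALSE, height, width)
    red_mask[red_idx] <- TRUE
    list(image = img, eye_mask = eye,
         truth = list(red_fraction = red_fraction, red_mask = red_mask))
  })
}
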