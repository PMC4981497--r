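# synthetic two-channel colocalization fields (mCherry-HP1a vs GFP-ORF)

coloc_patterns <- function()
  c("broad", "narrow", "focal", "boundary", "pan_nuclear", "independent")

#' Generate a synthetic two-channel colocalization field
#'
#' Channel 1 (`mcherry`, mCherry-HP1a) carries a compact heterochromatin
#' domain inside each nucleus; channel 2 (`gfp`, GFP-ORF) realizes the
#' requested geometric relationship to that domain:
#' \describe{
#'   \item{broad}{same support as the HP1a domain}
#'   \item{narrow}{eroded (smaller) domain, same center}
#'   \item{focal}{1-3 small spots inside/adjacent to the domain}
#'   \item{boundary}{rim at the domain edge}
#'   \item{pan_nuclear}{uniform over the whole nucleus}
#'   \item{independent}{a domain at an independent random position}
#' }
#'
#' @param pattern one of `coloc_patterns()`
#' @param seed integer seed
#' @param n_nuclei nuclei per field
#' @param config a [screen_sim_config()]; geometry/noise settings are reused
#' @param well provenance label
#' @return list with `field` (2-channel [image_field()]) and `truth`
#'   (label mask and the pattern class)
#' @export
generate_coloc_pair <- function(pattern, seed = 1L, n_nuclei = 12L,
                                config = screen_sim_config(),
                                well = NA_character_) {
  pattern <- match.arg(pattern, coloc_patterns())
  with_seed(seed, {
    fs <- config$field_size_px
    rr <- config$nucleus_radius_px
    radii <- runif(n_nuclei, rr[1L], rr[2L])
    margin <- max(rr[2L] + 4, 6)
    pl <- place_nuclei(n_nuclei, radii, fs, 0, margin)
    xs <- matrix(rep(seq_len(fs), fs), fs, fs)
    ys <- matrix(rep(seq_len(fs), each = fs), fs, fs)

    mask <- matrix(0L, fs, fs)
    best <- matrix(Inf, fs, fs)
    # diffuse (nucleoplasmic) and chromatin-bound signal are accumulated
    # separately: fine chromatin texture is shared between the two
    # reporters only where both are bound to the structure
    mch_dif <- matrix(0, fs, fs); mch_bnd <- matrix(0, fs, fs)
    gfp_dif <- matrix(0, fs, fs); gfp_bnd <- matrix(0, fs, fs)
    for (k in seq_len(n_nuclei)) {
      d <- sqrt((xs - pl$centers[k, 1L])^2 + (ys - pl$centers[k, 2L])^2)
      nd <- d / radii[k]
      upd <- nd <= 1 & nd < best
      mask[upd] <- k
      best[upd] <- nd[upd]
      # weak radial attenuation shared by both channels
      p <- soft_edge(radii[k] - d) * (1 - 0.15 * pmin(nd, 1)^2)
      off <- runif(2, -0.3, 0.3) * radii[k]
      dc <- sqrt((xs - pl$centers[k, 1L] - off[1L])^2 +
                 (ys - pl$centers[k, 2L] - off[2L])^2)
      rd <- 0.42 * radii[k]
      dom <- soft_edge(rd - dc)
      A_m <- max(rnorm(1, 9000, 1500), 3000)
      mch_dif <- pmax(mch_dif, 0.40 * A_m * p)
      mch_bnd <- pmax(mch_bnd, A_m * dom * p)
      A_g <- max(rnorm(1, 9000, 1500), 3000)
      bound <- switch(pattern,
        broad = dom,
        narrow = soft_edge(0.55 * rd - dc),
        focal = {
          spots <- matrix(0, fs, fs)
          for (s in seq_len(sample(1:3, 1L))) {
            ang <- runif(1, 0, 2 * pi)
            rad <- runif(1, 0, 0.9) * rd
            sc <- c(pl$centers[k, 1L] + off[1L] + rad * cos(ang),
                    pl$centers[k, 2L] + off[2L] + rad * sin(ang))
            ds <- sqrt((xs - sc[1L])^2 + (ys - sc[2L])^2)
            spots <- spots + soft_edge(2.2 - ds)
          }
          1.6 * pmin(spots, 1.5)
        },
        boundary = 1.2 * exp(-((dc - rd)^2) / (2 * 1.2^2)),
        pan_nuclear = matrix(0, fs, fs),
        independent = {
          off2 <- runif(2, -0.45, 0.45) * radii[k]
          d2 <- sqrt((xs - pl$centers[k, 1L] - off2[1L])^2 +
                     (ys - pl$centers[k, 2L] - off2[2L])^2)
          soft_edge(rd - d2)
        })
      dif_level <- if (pattern == "pan_nuclear") 0.85 else 0.50
      gfp_dif <- pmax(gfp_dif, dif_level * A_g * p)
      gfp_bnd <- pmax(gfp_bnd, A_g * bound * p)
    }
    # chromatin fine texture is a property of the decorated structure: the
    # heterochromatin texture is shared by both reporters only when the GFP
    # construct binds the same structure; an independent construct carries
    # its own texture
    shared <- matrix(exp(rnorm(fs * fs, 0, config$speckle_sdlog)), fs, fs)
    gfp_tex <- if (pattern == "independent")
      matrix(exp(rnorm(fs * fs, 0, config$speckle_sdlog)), fs, fs) else shared
    ispk <- function() matrix(exp(rnorm(fs * fs, 0, config$speckle_sdlog / 2)),
                              fs, fs)
    noise <- function(m) m + rnorm(fs * fs,
      sd = sqrt(config$read_noise_sd^2 + config$noise_gain * pmax(m, 0)))
    mch <- quantize16(noise(450 + mch_dif * ispk() + mch_bnd * shared * ispk()))
    gfp <- quantize16(noise(450 + gfp_dif * ispk() + gfp_bnd * gfp_tex * ispk()))
    list(field = image_field(list(mcherry = mch, gfp = gfp), well = well),
         truth = list(mask = mask, pattern = pattern, centers = pl$centers,
                      radii = radii))
  })
}
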