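# synthetic multi-channel fields of nuclei with known ground truth

# soft edge profile: ~1 inside, ~0 outside, 1-px transition
soft_edge <- function(signed_dist, width = 0.5) {
  1 / (1 + exp(-signed_dist / width))
}

# place nucleus centers: singles by rejection sampling, touching pairs at
# 1.2-1.6 mean radii. Returns list(centers = n x 2, radii). Errors out if
# placement is impossible.
place_nuclei <- function(n, radii, field, touching_fraction, margin,
                         max_iter = 4000L) {
  centers <- matrix(numeric(0), 0L, 2L)
  if (n == 0L) return(list(centers = centers, radii = numeric(0),
                           pair_id = integer(0)))
  n_pairs <- floor(touching_fraction * n / 2)
  pair_id <- integer(n)
  ok_sep <- function(c1, r1) {
    if (nrow(centers) == 0L) return(TRUE)
    d <- sqrt((centers[, 1L] - c1[1L])^2 + (centers[, 2L] - c1[2L])^2)
    all(d > (radii[seq_len(nrow(centers))] + r1) * 1.15)
  }
  draw <- function() c(runif(1, margin, field - margin),
                       runif(1, margin, field - margin))
  k <- 0L
  iter <- 0L
  while (k < n) {
    iter <- iter + 1L
    if (iter > max_iter)
      stop("cannot place ", n, " nuclei in a ", field, "-px field ",
           "without violating spacing constraints")
    is_pair <- (k %/% 2L) < n_pairs && (n - k) >= 2L
    c1 <- draw()
    if (!ok_sep(c1, radii[k + 1L])) next
    if (is_pair) {
      r1 <- radii[k + 1L]; r2 <- radii[k + 2L]
      sep <- runif(1, 1.2, 1.6) * (r1 + r2) / 2
      th <- runif(1, 0, 2 * pi)
      c2 <- c1 + sep * c(cos(th), sin(th))
      inside <- all(c2 > margin & c2 < field - margin)
      if (!inside) next
      # partner must not collide with previously placed nuclei
      if (nrow(centers) > 0L) {
        d <- sqrt((centers[, 1L] - c2[1L])^2 + (centers[, 2L] - c2[2L])^2)
        if (any(d <= (radii[seq_len(nrow(centers))] + r2) * 1.15)) next
      }
      centers <- rbind(centers, c1, c2)
      pair_id[k + 1L] <- pair_id[k + 2L] <- k %/% 2L + 1L
      k <- k + 2L
    } else {
      centers <- rbind(centers, c1)
      k <- k + 1L
    }
  }
  rownames(centers) <- NULL
  list(centers = centers, radii = radii, pair_id = pair_id)
}

#' Generate one synthetic 3-channel field of nuclei
#'
#' Renders a DAPI / HP1a / gamma-H2Av field of near-circular nuclei with
#' smooth interior texture over a low-frequency background gradient plus
#' signal-dependent noise, together with the ground-truth label mask. The
#' HP1a channel contains a bright chromocenter domain per nucleus whose
#' amplitude (together with the whole HP1a nuclear signal) is scaled by
#' `effect`, the planted multiplicative depletion/increase factor.
#'
#' @param n_nuclei number of nuclei to plant (>= 0)
#' @param config a [screen_sim_config()]
#' @param seed integer seed; identical (config, seed) gives identical output
#' @param effect multiplicative HP1a intensity factor (> 0)
#' @param touching_fraction override of `config$touching_fraction`
#' @param radius_factor multiplier on nucleus radii (cell-death morphology)
#' @param well,field_index provenance labels stored in the field
#' @return list with `field` (an [image_field()]) and `truth` (list with
#'   `mask` label matrix, `centers`, `radii`, `pair_id`, `effect`)
#' @export
generate_nuclei_field <- function(n_nuclei, config = screen_sim_config(),
                                  seed = config$seed, effect = 1,
                                  touching_fraction = config$touching_fraction,
                                  radius_factor = 1,
                                  well = NA_character_,
                                  field_index = NA_integer_) {
  stopifnot(n_nuclei >= 0, effect > 0)
  with_seed(seed, {
    fs <- config$field_size_px
    rr <- config$nucleus_radius_px * radius_factor
    radii <- runif(n_nuclei, rr[1L], rr[2L])
    margin <- max(rr[2L] + 4, 6)
    pl <- place_nuclei(n_nuclei, radii, fs, touching_fraction, margin)

    xs <- matrix(rep(seq_len(fs), fs), fs, fs)         # row coordinate
    ys <- matrix(rep(seq_len(fs), each = fs), fs, fs)  # col coordinate

    # ground-truth labels: nearest center in radius-normalized distance
    mask <- matrix(0L, fs, fs)
    best <- matrix(Inf, fs, fs)
    profiles <- vector("list", n_nuclei)
    for (k in seq_len(n_nuclei)) {
      d <- sqrt((xs - pl$centers[k, 1L])^2 + (ys - pl$centers[k, 2L])^2)
      nd <- d / radii[k]
      upd <- nd <= 1 & nd < best
      mask[upd] <- k
      best[upd] <- nd[upd]
      profiles[[k]] <- soft_edge(radii[k] - d) * (1 - 0.3 * pmin(nd, 1)^2)
    }

    chans <- list()
    for (nm in c("dapi", "hp1a", "gh2av")) {
      bl <- config$channel_baselines[[nm]]
      grad <- config$background_gradient_amplitude
      a <- runif(1, -1, 1); b <- runif(1, -1, 1)
      bg <- max(bl[1L] + rnorm(1, 0, bl[2L]), 0) +
        grad * ((a * xs / fs + b * ys / fs + 2) / 4)
      sig <- matrix(0, fs, fs)
      for (k in seq_len(n_nuclei)) {
        amp <- config$nucleus_amplitudes[[nm]]
        A <- max(rnorm(1, amp[1L], amp[2L]), amp[1L] * 0.2)
        p <- profiles[[k]]
        # nuclei are opaque: overlapping projections combine by max, not
        # sum, so touching pairs keep their figure-eight waist
        contrib <- if (nm == "hp1a") {
          # chromocenter domain offset inside the nucleus
          off <- runif(2, -0.35, 0.35) * radii[k]
          dc <- sqrt((xs - pl$centers[k, 1L] - off[1L])^2 +
                     (ys - pl$centers[k, 2L] - off[2L])^2)
          dom <- soft_edge(0.38 * radii[k] - dc)
          effect * A * (0.35 * p + 1.0 * dom * p)
        } else if (nm == "gh2av") {
          foci <- matrix(0, fs, fs)
          for (f in seq_len(sample(1:2, 1L))) {
            off <- runif(2, -0.5, 0.5) * radii[k]
            df <- sqrt((xs - pl$centers[k, 1L] - off[1L])^2 +
                       (ys - pl$centers[k, 2L] - off[2L])^2)
            foci <- foci + soft_edge(2 - df)
          }
          A * (0.6 * p + 1.2 * foci * p)
        } else {
          A * p
        }
        sig <- pmax(sig, contrib)
      }
      if (n_nuclei > 0L && config$speckle_sdlog > 0) {
        spk <- matrix(exp(rnorm(fs * fs, 0, config$speckle_sdlog)), fs, fs)
        sig <- sig * spk
      }
      img <- bg + sig
      img <- img + rnorm(fs * fs,
                         sd = sqrt(config$read_noise_sd^2 +
                                   config$noise_gain * pmax(img, 0)))
      chans[[nm]] <- quantize16(img)
    }

    list(field = image_field(chans, well = well, field = field_index),
         truth = list(mask = mask, centers = pl$centers, radii = radii,
                      pair_id = pl$pair_id, effect = effect))
  })
}

#' Generate a replicated synthetic screen plate of image fields
#'
#' Builds `n_replicates` plates sharing one layout. HP1a-RNAi wells (and any
#' wells named in `config$planted_wells`) carry a planted multiplicative
#' HP1a-intensity factor; cell-death wells get fewer, smaller nuclei.
#' Replicates share the layout and per-well factors but have independent
#' noise.
#'
#' @param config a [screen_sim_config()]
#' @param layout optional layout data.frame (`well`, `amplicon_id`, `role`);
#'   defaults to [plate_layout()]. Must contain at least one `pos_hp1a` and
#'   four negative-control wells.
#' @return list with `fields` (nested list `[[replicate]][[well]]` of
#'   [generate_nuclei_field()] results), `layout`, and `truth` (data.frame
#'   of per-well planted factor and cell-death status)
#' @export
generate_screen_plate <- function(config = screen_sim_config(),
                                  layout = plate_layout(config)) {
  stopifnot(all(c("well", "amplicon_id", "role") %in% names(layout)))
  if (sum(layout$role == "pos_hp1a") < 1L ||
      sum(layout$role %in% negative_roles()) < 4L)
    stop("layout must contain >= 1 positive-control and >= 4 ",
         "negative-control wells")
  eff <- rep(1, nrow(layout))
  pe <- config$planted_effects
  hit <- layout$role %in% names(pe)
  eff[hit] <- pe[layout$role[hit]]
  pw <- config$planted_wells
  if (length(pw)) {
    idx <- match(names(pw), layout$well)
    eff[idx[!is.na(idx)]] <- pw[!is.na(idx)]
  }
  dead <- layout$well %in% config$cell_death_wells
  truth <- data.frame(well = layout$well, role = layout$role,
                      effect = eff, cell_death = dead,
                      stringsAsFactors = FALSE)
  fields <- vector("list", config$n_replicates)
  for (r in seq_len(config$n_replicates)) {
    wells <- vector("list", nrow(layout))
    names(wells) <- layout$well
    for (w in seq_len(nrow(layout))) {
      nf <- config$n_fields_per_well
      wf <- vector("list", nf)
      for (f in seq_len(nf)) {
        s <- child_seed(config$seed, (r * 1000L + w) * 10L + f)
        n_nuc <- with_seed(s + 1L, rnbinom(
          1L, mu = config$nuclei_per_field$mean *
            if (dead[w]) config$cell_death_count_factor else 1,
          size = config$nuclei_per_field$dispersion))
        wf[[f]] <- generate_nuclei_field(
          n_nuc, config, seed = s, effect = eff[w],
          radius_factor = if (dead[w]) config$cell_death_radius_factor else 1,
          well = layout$well[w], field_index = f)
      }
      wells[[w]] <- wf
    }
    fields[[r]] <- wells
  }
  list(fields = fields, layout = layout, truth = truth)
}
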