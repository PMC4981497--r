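# well-aggregate-level synthetic screen generator
#
# Rendering and segmenting images for hundreds of wells is not needed to
# exercise the screen statistics: the unit entering Rank Product is the
# per-well aggregate feature vector. This generator draws those aggregates
# directly from the same statistical model the image generator realizes
# (replicate-consistent biological effects, heavy-tailed technical noise,
# multiplicative HP1a depletion factors), at full screen scale.

# features whose per-well aggregate responds to the planted HP1a factor,
# as (intercept, slope on log-factor, noise sd, log-scale?)
hp1a_response <- function() {
  list(
    mean_hp1a              = c(log(2500), 1.00, 0.020, 1),
    max_hp1a               = c(log(9500), 1.05, 0.030, 1),
    total_hp1a             = c(log(6e5),  1.00, 0.030, 1),
    sd_hp1a                = c(log(1600), 1.00, 0.030, 1),
    relative_max_hp1a      = c(log(3.2),  0.50, 0.020, 1),
    kurtosis_hp1a          = c(1.6,      -2.30, 0.120, 0),
    skew_hp1a              = c(0.9,      -0.80, 0.060, 0),
    edge_center_ratio_hp1a = c(0.75,     -0.10, 0.015, 0),
    pcc_hp1a_dapi          = c(0.55,      0.25, 0.025, 0)
  )
}

# baselines for features not driven by the HP1a factor: (level, well sd,
# replicate sd, log-scale?)
neutral_baselines <- function() {
  list(
    mean_dapi = c(log(4200), 0.03, 0.05, 1), max_dapi = c(log(14000), 0.03, 0.05, 1),
    total_dapi = c(log(1.0e6), 0.03, 0.05, 1), sd_dapi = c(log(2600), 0.03, 0.05, 1),
    relative_max_dapi = c(log(3.3), 0.02, 0.03, 1),
    kurtosis_dapi = c(0.4, 0.08, 0.12, 0), skew_dapi = c(0.5, 0.05, 0.08, 0),
    edge_center_ratio_dapi = c(0.8, 0.01, 0.02, 0),
    mean_gh2av = c(log(1400), 0.03, 0.05, 1), max_gh2av = c(log(5200), 0.03, 0.05, 1),
    total_gh2av = c(log(3.3e5), 0.03, 0.05, 1), sd_gh2av = c(log(900), 0.03, 0.05, 1),
    relative_max_gh2av = c(log(3.7), 0.02, 0.03, 1),
    kurtosis_gh2av = c(1.8, 0.10, 0.15, 0), skew_gh2av = c(1.1, 0.06, 0.09, 0),
    edge_center_ratio_gh2av = c(0.7, 0.01, 0.02, 0),
    area = c(log(240), 0.03, 0.04, 1), perimeter = c(log(56), 0.015, 0.02, 1),
    roundness = c(13.2, 0.10, 0.15, 0), eccentricity = c(0.45, 0.02, 0.03, 0),
    solidity = c(0.97, 0.004, 0.006, 0), equiv_diameter = c(log(17.5), 0.015, 0.02, 1),
    pcc_hp1a_gh2av = c(0.18, 0.02, 0.03, 0), pcc_dapi_gh2av = c(0.22, 0.02, 0.03, 0)
  )
}

#' Simulate per-well aggregate summaries for a full synthetic screen
#'
#' Draws replicate [aggregate_well()]-style summaries for `n_wells` wells
#' directly at the well level: each well carries a replicate-consistent
#' biological effect plus heavy-tailed (t, 3 df) per-replicate technical
#' noise, and wells with a planted multiplicative HP1a factor respond in the
#' HP1a intensity features (mean/max/total/sd down with depletion, relative
#' maximum down, kurtosis and skew up, HP1a-DAPI correlation down).
#'
#' @param n_wells total number of wells (controls included)
#' @param n_replicates replicates (plates) sharing the layout
#' @param n_pos number of HP1a-RNAi positive-control wells (factor
#'   `pos_factor`)
#' @param n_neg number of negative-control wells (split across mock / GFP /
#'   Rho1 / Thread roles)
#' @param n_planted number of sample wells carrying `planted_factor`
#' @param pos_factor,planted_factor multiplicative HP1a factors
#' @param n_cell_death sample wells with strongly reduced nucleus count and
#'   median nuclear area (cell-death phenotype)
#' @param nuclei_mean mean nucleus count per well and replicate
#' @param bio_sd replicate-consistent well effect sd (log scale)
#' @param tech_sd scale of the per-replicate t(3) technical noise
#' @param seed integer seed
#' @return list with `summaries` (data.frame: well, amplicon_id, role,
#'   replicate, n_nuclei and the 33 canonical features, one row per
#'   well x replicate) and `truth` (per-well role, factor, planted and
#'   cell-death flags)
#' @export
simulate_screen <- function(n_wells = 200L, n_replicates = 2L,
                            n_pos = 10L, n_neg = 8L,
                            n_planted = 0L, pos_factor = 0.4,
                            planted_factor = 0.5, n_cell_death = 0L,
                            nuclei_mean = 120, bio_sd = 0.05,
                            tech_sd = 0.06, seed = 1L) {
  stopifnot(n_wells >= n_pos + n_neg + n_planted + n_cell_death,
            n_replicates >= 1L, pos_factor > 0, planted_factor > 0)
  with_seed(seed, {
    wells <- sprintf("W%03d", seq_len(n_wells))
    roles <- rep("sample", n_wells)
    if (n_pos > 0L) roles[seq_len(n_pos)] <- "pos_hp1a"
    if (n_neg > 0L)
      roles[n_pos + seq_len(n_neg)] <-
        rep(negative_roles(), length.out = n_neg)
    idx_free <- which(roles == "sample")
    planted <- rep(FALSE, n_wells)
    if (n_planted > 0L) planted[idx_free[seq_len(n_planted)]] <- TRUE
    dead <- rep(FALSE, n_wells)
    if (n_cell_death > 0L)
      dead[idx_free[n_planted + seq_len(n_cell_death)]] <- TRUE

    fac <- rep(1, n_wells)
    fac[roles == "pos_hp1a"] <- pos_factor
    fac[planted] <- planted_factor

    count_factor <- rep(1, n_wells)
    count_factor[roles == "neg_rho1"] <- 0.8
    count_factor[roles == "neg_thread"] <- 0.5
    count_factor[dead] <- 0.35
    area_factor <- rep(1, n_wells)
    area_factor[roles == "neg_rho1"] <- 1.6
    area_factor[roles == "neg_thread"] <- 0.85
    area_factor[dead] <- 0.45

    resp <- hp1a_response()
    base <- neutral_baselines()
    feat_names <- canonical_features()
    # replicate-consistent well effects
    b_hp1a <- rnorm(n_wells, 0, bio_sd)
    b_neut <- sapply(base, function(p) rnorm(n_wells, 0, p[2L]))

    rows <- vector("list", n_replicates)
    for (r in seq_len(n_replicates)) {
      X <- matrix(NA_real_, n_wells, length(feat_names),
                  dimnames = list(NULL, feat_names))
      l_wr <- log(fac) + b_hp1a + tech_sd * rt(n_wells, df = 3)
      for (nm in names(resp)) {
        p <- resp[[nm]]
        val <- p[1L] + p[2L] * l_wr + p[3L] * rt(n_wells, df = 3)
        X[, nm] <- if (p[4L] == 1) exp(val) else val
      }
      for (nm in names(base)) {
        p <- base[[nm]]
        val <- p[1L] + b_neut[, nm] + p[3L] * rt(n_wells, df = 3)
        if (p[4L] == 1) {
          v <- exp(val)
          if (nm %in% c("area", "total_dapi", "total_gh2av"))
            v <- v * area_factor
          if (nm %in% c("perimeter", "equiv_diameter"))
            v <- v * sqrt(area_factor)
          X[, nm] <- v
        } else X[, nm] <- val
      }
      n_nuc <- rnbinom(n_wells, mu = nuclei_mean * count_factor, size = 30)
      rows[[r]] <- data.frame(
        well = wells,
        amplicon_id = ifelse(roles == "sample", paste0("AMP_", wells),
                             paste0("CTRL_", sub("^(pos|neg)_", "", roles))),
        role = roles, replicate = r, n_nuclei = n_nuc,
        X, stringsAsFactors = FALSE)
    }
    list(summaries = do.call(rbind, rows),
         truth = data.frame(well = wells, role = roles, effect = fac,
                            planted = planted, cell_death = dead,
                            stringsAsFactors = FALSE))
  })
}
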