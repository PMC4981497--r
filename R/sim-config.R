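#' Configuration for the synthetic screen generator
#'
#' Collects every tunable of the synthetic high-content screen: plate layout,
#' nucleus geometry and texture, per-channel intensity model, planted
#' multiplicative HP1a effects, and the camera noise model. All intensities
#' are arbitrary units (AU) on the 16-bit scale (0..65535).
#'
#' The rendered nucleus is a soft-edged disk with mild radial attenuation,
#' multiplied by per-pixel log-normal speckle; the HP1a channel additionally
#' carries a compact bright chromocenter domain inside the nucleus so that
#' maximum/relative-maximum/kurtosis features are non-degenerate. Noise is
#' Gaussian read noise plus Poisson-like signal-dependent noise, clipped to
#' the 16-bit range.
#'
#' @param n_wells_per_plate wells per plate (>= 6 so the default control
#'   layout fits)
#' @param n_replicates number of replicate plates sharing a layout
#' @param n_fields_per_well imaged fields per well
#' @param nuclei_per_field list with `mean` and `dispersion` (negative
#'   binomial size) of the per-field nucleus count
#' @param nucleus_radius_px two-element range of nucleus radii (pixels)
#' @param field_size_px square field edge length (pixels)
#' @param background_gradient_amplitude amplitude (AU) of the low-frequency
#'   background gradient
#' @param channel_baselines named list `channel -> c(mean, sd)` of background
#'   offsets (AU) for channels `dapi`, `hp1a`, `gh2av`
#' @param nucleus_amplitudes named list `channel -> c(mean, sd)` of nuclear
#'   signal amplitudes (AU)
#' @param planted_effects named numeric, well role -> multiplicative HP1a
#'   intensity factor (e.g. `c(pos_hp1a = 0.4)`); factors must be > 0
#' @param planted_wells named numeric, specific sample wells -> factor
#' @param touching_fraction proportion of nuclei placed as touching pairs
#'   (centers 1.2-1.6 mean radii apart)
#' @param cell_death_wells character vector of wells with reduced nucleus
#'   count and shrunken nuclei
#' @param cell_death_count_factor,cell_death_radius_factor multipliers applied
#'   to nucleus count / radius in cell-death wells
#' @param speckle_sdlog log-sd of the multiplicative nuclear speckle
#' @param read_noise_sd Gaussian read noise sd (AU)
#' @param noise_gain slope of the Poisson-like variance term (var = gain * AU)
#' @param seed integer seed giving bit-identical output for identical config
#' @return a `screen_sim_config` object (list)
#' @export
screen_sim_config <- function(n_wells_per_plate = 12L,
                              n_replicates = 2L,
                              n_fields_per_well = 2L,
                              nuclei_per_field = list(mean = 12, dispersion = 8),
                              nucleus_radius_px = c(7, 11),
                              field_size_px = 192L,
                              background_gradient_amplitude = 300,
                              channel_baselines = list(
                                dapi  = c(400, 40),
                                hp1a  = c(350, 35),
                                gh2av = c(300, 30)),
                              nucleus_amplitudes = list(
                                dapi  = c(12000, 2500),
                                hp1a  = c(9000, 2000),
                                gh2av = c(2500, 700)),
                              planted_effects = c(pos_hp1a = 0.4),
                              planted_wells = numeric(0),
                              touching_fraction = 0.15,
                              cell_death_wells = character(0),
                              cell_death_count_factor = 0.35,
                              cell_death_radius_factor = 0.7,
                              speckle_sdlog = 0.12,
                              read_noise_sd = 40,
                              noise_gain = 1.5,
                              seed = 1L) {
  stopifnot(n_wells_per_plate >= 6L, n_replicates >= 1L,
            n_fields_per_well >= 1L,
            nuclei_per_field$mean >= 0, nuclei_per_field$dispersion > 0,
            length(nucleus_radius_px) == 2L, all(nucleus_radius_px > 2),
            field_size_px >= 16L,
            background_gradient_amplitude >= 0,
            touching_fraction >= 0, touching_fraction <= 1,
            speckle_sdlog >= 0, read_noise_sd >= 0, noise_gain >= 0)
  for (nm in c("dapi", "hp1a", "gh2av")) {
    stopifnot(all(channel_baselines[[nm]] >= 0),
              all(nucleus_amplitudes[[nm]] >= 0))
  }
  if (length(planted_effects) && any(planted_effects <= 0))
    stop("planted effect factors must be > 0")
  if (length(planted_wells) && any(planted_wells <= 0))
    stop("planted well factors must be > 0")
  structure(as.list(environment()), class = "screen_sim_config")
}

#' Default plate layout for a synthetic screen
#'
#' Assigns one role per well: HP1a-RNAi positive controls (`pos_hp1a`),
#' negative controls (`neg_mock`, `neg_gfp`, `neg_rho1`, `neg_thread`, one
#' well each) and `sample` wells for the remainder. Replicate plates share
#' the layout.
#'
#' @param config a [screen_sim_config()]
#' @return data.frame with columns `well`, `amplicon_id`, `role`
#' @export
plate_layout <- function(config) {
  n <- config$n_wells_per_plate
  wells <- sprintf("W%03d", seq_len(n))
  roles <- rep("sample", n)
  roles[1:2] <- "pos_hp1a"
  roles[3:6] <- c("neg_mock", "neg_gfp", "neg_rho1", "neg_thread")
  amp <- ifelse(roles == "sample", paste0("AMP_", wells),
                paste0("CTRL_", sub("^(pos|neg)_", "", roles)))
  data.frame(well = wells, amplicon_id = amp, role = roles,
             stringsAsFactors = FALSE)
}

#' @export
print.screen_sim_config <- function(x, ...) {
  cat(sprintf(paste0("screen_sim_config: %d wells x %d replicates, ",
                     "%d fields/well, ~%g nuclei/field, field %d px\n"),
              x$n_wells_per_plate, x$n_replicates, x$n_fields_per_well,
              x$nuclei_per_field$mean, x$field_size_px))
  invisible(x)
}

negative_roles <- function() c("neg_mock", "neg_gfp", "neg_rho1", "neg_thread")
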