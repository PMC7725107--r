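#' Beam specification
#'
#' Describes one radiotherapy beam as delivered at the accelerator: modality,
#' nominal energy, dose rate, flattening-filter-free (FFF) mode, gantry angle
#' and field size. Photon fields support 6 and 10 MV (conventional 600 MU/min,
#' or FFF at 1200/2400 MU/min); electron fields support 4, 6, 8, 10, 12 and
#' 15 MeV at 600 MU/min. Gantry 0 deg is anterior-posterior (AP); 330 and 150
#' deg are the oblique tangential geometries (entry and exit side).
#'
#' @param modality `"photon"` or `"electron"`.
#' @param energy Nominal energy: MV for photons (6, 10), MeV for electrons
#'   (4, 6, 8, 10, 12, 15).
#' @param dose_rate Dose rate in MU/min: 600, 1200 or 2400. Rates above 600
#'   require `fff = TRUE`.
#' @param fff Logical; flattening-filter-free photon mode.
#' @param gantry_angle_deg Gantry angle: 0 (AP), 330 or 150 (oblique).
#' @param field_size_mm Length-2 numeric, field side lengths at isocenter (mm).
#' @param ssd_mm Source-to-surface distance (mm); metadata only.
#' @return An object of class `"beam_spec"`.
#' @export
beam_spec <- function(modality = c("photon", "electron"), energy,
                      dose_rate = 600, fff = FALSE, gantry_angle_deg = 0,
                      field_size_mm = c(50, 50), ssd_mm = 1017) {
  modality <- match.arg(modality)
  supported <- if (modality == "photon") c(6, 10) else c(4, 6, 8, 10, 12, 15)
  if (!is.numeric(energy) || length(energy) != 1L || !(energy %in% supported))
    stop(sprintf("unsupported %s energy %s; supported values: %s",
                 modality, format(energy), paste(supported, collapse = ", ")))
  if (!(dose_rate %in% c(600, 1200, 2400)))
    stop("dose_rate must be one of 600, 1200, 2400 MU/min")
  if (fff && modality != "photon")
    stop("fff mode applies to photon beams only")
  if (dose_rate > 600 && !fff)
    stop("dose_rate above 600 MU/min requires fff = TRUE")
  if (!(gantry_angle_deg %in% c(0, 330, 150)))
    stop("gantry_angle_deg must be 0 (AP), 330 or 150 (oblique)")
  stopifnot(length(field_size_mm) == 2L, all(field_size_mm > 0), ssd_mm > 0)
  structure(list(modality = modality, energy = energy, dose_rate = dose_rate,
                 fff = fff, gantry_angle_deg = gantry_angle_deg,
                 field_size_mm = as.numeric(field_size_mm), ssd_mm = ssd_mm),
            class = "beam_spec")
}

#' Tissue specification
#'
#' Optical description of the phantom surface. Cherenkov light emitted in
#' tissue is scattered and absorbed before reaching the surface; dark tissue
#' absorbs most of the visible-band emission, so its effective signal is a
#' small fraction of the light-tissue one. `absorption_factor` multiplies the
#' emitted signal; defaults are 1.0 for yellow and 0.05 for black tissue.
#'
#' @param color `"yellow"` or `"black"`.
#' @param absorption_factor Multiplier in (0, 1] on the emitted signal;
#'   defaults by color.
#' @param surface_roughness_mm Amplitude of a smooth random surface modulation
#'   (default 0: flat phantom).
#' @return An object of class `"tissue_spec"`.
#' @export
tissue_spec <- function(color = c("yellow", "black"), absorption_factor = NULL,
                        surface_roughness_mm = 0) {
  color <- match.arg(color)
  if (is.null(absorption_factor))
    absorption_factor <- if (color == "yellow") 1.0 else 0.05
  if (!(absorption_factor > 0 && absorption_factor <= 1))
    stop("absorption_factor must lie in (0, 1]")
  if (surface_roughness_mm < 0) stop("surface_roughness_mm must be >= 0")
  structure(list(color = color, absorption_factor = absorption_factor,
                 surface_roughness_mm = surface_roughness_mm),
            class = "tissue_spec")
}

#' Acquisition specification
#'
#' Camera and noise model for one CLI acquisition: CCD gain, integration time,
#' true pixel scale at the isocenter plane, Gaussian background (dark)
#' statistics, Poisson-like signal shot noise, sparkle impulse rate (direct
#' x-ray hits on the CCD) and frame count.
#'
#' Integration time defaults depend on modality and tissue and are resolved by
#' [default_integration_time()]: 1.0 s photon / 1.2 s electron for yellow
#' tissue, 2.0 s / 2.5 s for black. Signal and dark noise scale with
#' integration time relative to the yellow-tissue reference.
#'
#' @param gain_db CCD gain in dB (metadata; default 36, the camera maximum).
#' @param integration_time_s Integration time (s), or `NULL` to resolve per
#'   modality/tissue at simulation time.
#' @param pixel_scale_true True pixel scale (px/mm) at the isocenter plane;
#'   default 3.6 (36 px per 10 mm).
#' @param background_mean,background_sd Mean and SD of the Gaussian background
#'   offset (grayscale units at reference integration time).
#' @param sparkle_rate Expected number of sparkle impulse pixels per frame.
#' @param frames_per_condition Repeated frames per condition (>= 3).
#' @param bit_depth Image bit depth (default 16).
#' @param shot_noise_gain Variance of the signal shot noise per unit signal
#'   (grayscale units); 0 disables shot noise.
#' @return An object of class `"acquisition_spec"`.
#' @export
acquisition_spec <- function(gain_db = 36, integration_time_s = NULL,
                             pixel_scale_true = 3.6,
                             background_mean = 1200, background_sd = 120,
                             sparkle_rate = 50, frames_per_condition = 3,
                             bit_depth = 16, shot_noise_gain = 4) {
  if (!is.null(integration_time_s) && integration_time_s <= 0)
    stop("integration_time_s must be > 0")
  if (pixel_scale_true <= 0) stop("pixel_scale_true must be > 0")
  if (background_mean < 0 || background_sd < 0 || sparkle_rate < 0 ||
      shot_noise_gain < 0)
    stop("noise parameters must be >= 0")
  if (frames_per_condition < 3) stop("frames_per_condition must be >= 3")
  stopifnot(bit_depth %in% c(8, 16))
  structure(list(gain_db = gain_db, integration_time_s = integration_time_s,
                 pixel_scale_true = pixel_scale_true,
                 background_mean = background_mean,
                 background_sd = background_sd, sparkle_rate = sparkle_rate,
                 frames_per_condition = as.integer(frames_per_condition),
                 bit_depth = as.integer(bit_depth),
                 shot_noise_gain = shot_noise_gain),
            class = "acquisition_spec")
}

#' Default integration time
#'
#' Minimum integration time capturing the full Cherenkov signal: 1.0 s for
#' photon and 1.2 s for electron irradiation of light (yellow) tissue; black
#' tissue needs 2.0 s and 2.5 s respectively before a usable image forms.
#'
#' @param beam A [beam_spec()].
#' @param tissue A [tissue_spec()].
#' @return Integration time in seconds.
#' @export
default_integration_time <- function(beam, tissue) {
  if (tissue$color == "black") {
    if (beam$modality == "photon") 2.0 else 2.5
  } else {
    if (beam$modality == "photon") 1.0 else 1.2
  }
}

#' Introduced-shift specification
#'
#' A deliberate couch displacement along the superior-inferior (image X) axis,
#' used as ground truth for the matching measurement. Tested magnitudes in the
#' phantom study were 0, 2, 5 and 10 mm toward superior or inferior.
#'
#' @param magnitude_mm Nonnegative shift magnitude in mm.
#' @param direction `"superior"` or `"inferior"` (ignored when magnitude is 0).
#' @param shifted_field Which field carries the shift: `"photon"` or
#'   `"electron"`.
#' @return An object of class `"shift_spec"`.
#' @export
shift_spec <- function(magnitude_mm = 0,
                       direction = c("inferior", "superior"),
                       shifted_field = c("photon", "electron")) {
  direction <- match.arg(direction)
  shifted_field <- match.arg(shifted_field)
  if (magnitude_mm < 0) stop("magnitude_mm must be >= 0")
  structure(list(magnitude_mm = magnitude_mm, direction = direction,
                 shifted_field = shifted_field),
            class = "shift_spec")
}

#' Signed shift in mm (+ = inferior, i.e. +X)
#' @param shift A [shift_spec()] or `NULL` (treated as zero shift).
#' @return Signed displacement in mm along the image X axis.
#' @export
signed_shift_mm <- function(shift) {
  if (is.null(shift) || shift$magnitude_mm == 0) return(0)
  if (shift$direction == "inferior") shift$magnitude_mm else -shift$magnitude_mm
}
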