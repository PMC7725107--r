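#' Relative Cherenkov yield of a beam on a tissue
#'
#' Relative in-field surface intensity (arbitrary grayscale units at reference
#' integration time). The model encodes the orderings seen on light-tissue
#' phantoms: electron yield grows linearly with energy and exceeds
#' conventional-dose-rate photon yield; FFF photon yield scales with dose rate
#' relative to the conventional 600 MU/min; the exit-side oblique photon field
#' (gantry 150 deg) collects less light than the entry side (330 deg). All
#' yields are multiplied by the tissue absorption factor.
#'
#' @param beam A [beam_spec()].
#' @param tissue A [tissue_spec()].
#' @param fff_dose_rate_factor Multiplier applied to FFF photon yield; default
#'   `dose_rate / 600`.
#' @return Dimensionless relative intensity.
#' @export
cherenkov_yield <- function(beam, tissue, fff_dose_rate_factor = NULL) {
  stopifnot(inherits(beam, "beam_spec"), inherits(tissue, "tissue_spec"))
  if (beam$modality == "electron") {
    y <- 4500 + 250 * (beam$energy - 4)
  } else {
    y <- 3500
    if (beam$fff) {
      f <- if (is.null(fff_dose_rate_factor)) beam$dose_rate / 600 else
        fff_dose_rate_factor
      y <- y * f
    }
  }
  y <- y * switch(as.character(beam$gantry_angle_deg),
                  "0" = 1, "330" = 0.9, "150" = 0.65)
  y * tissue$absorption_factor
}

# default erf-edge widths (mm); see methods vignette for the calibration
default_sigma_edge <- function(beam) {
  if (beam$modality == "photon") 1.0 else 1.1
}

# obliquity angle (deg) implied by the gantry angle
beam_obliquity_deg <- function(beam) {
  if (beam$gantry_angle_deg %in% c(330, 150)) 30 else 0
}

# nominal field X interval (mm): photon field inferior of the junction at
# x = 0, electron field superior; oblique incidence stretches the photon
# field away from the junction by 1/cos(obliquity)
field_x_range <- function(beam) {
  len <- beam$field_size_mm[1]
  stretch <- 1 / cos(beam_obliquity_deg(beam) * pi / 180)
  if (beam$modality == "photon") c(0, len * stretch) else c(-len * stretch, 0)
}

#' Noiseless beam fluence map
#'
#' Renders the ideal (noiseless) CLI intensity of one field on the image
#' grid: yield times a separable 2-D profile whose edges are smoothed steps
#' (Gaussian-convolved, i.e. erf-shaped, with width `sigma_edge_mm`). Oblique
#' incidence broadens the X edges by `1/cos(obliquity)` and stretches the
#' in-field X extent by the same factor, away from the field junction. The
#' couch shift translates the field along X (positive toward inferior).
#'
#' @param beam A [beam_spec()].
#' @param tissue A [tissue_spec()].
#' @param shift A [shift_spec()] or `NULL` for no shift.
#' @param grid_shape Integer pair `(rows, cols)`; default `c(240, 580)`.
#' @param pixel_scale Pixels per mm (default 3.6).
#' @param sigma_edge_mm Edge width parameter (mm); default 1.0 mm photon,
#'   1.1 mm electron.
#' @param fff_dose_rate_factor Passed to [cherenkov_yield()].
#' @return A [field_image()] with the scenario recorded in its metadata.
#' @export
ideal_fluence_map <- function(beam, tissue, shift = NULL,
                              grid_shape = c(240, 580), pixel_scale = 3.6,
                              sigma_edge_mm = NULL,
                              fff_dose_rate_factor = NULL) {
  stopifnot(inherits(beam, "beam_spec"), inherits(tissue, "tissue_spec"))
  if (is.null(sigma_edge_mm)) sigma_edge_mm <- default_sigma_edge(beam)
  ny <- grid_shape[1]; nx <- grid_shape[2]
  cosang <- cos(beam_obliquity_deg(beam) * pi / 180)
  sx <- sigma_edge_mm / cosang
  sy <- sigma_edge_mm
  xr <- field_x_range(beam) + signed_shift_mm(shift)
  yr <- c(-0.5, 0.5) * beam$field_size_mm[2]

  x_mm <- px_coord_to_mm(0:(nx - 1), nx, pixel_scale)
  y_mm <- px_coord_to_mm(0:(ny - 1), ny, pixel_scale)
  margin <- 4 * sx
  over <- max(x_mm[1] - (xr[1] - margin), (xr[2] + margin) - x_mm[nx],
              y_mm[1] - (yr[1] - 4 * sy), (yr[2] + 4 * sy) - y_mm[ny])
  if (over > 0)
    stop(sprintf("field (plus penumbra) overflows the grid by %.2f mm", over))

  fx <- stats::pnorm((x_mm - xr[1]) / sx) * stats::pnorm((xr[2] - x_mm) / sx)
  fy <- stats::pnorm((y_mm - yr[1]) / sy) * stats::pnorm((yr[2] - y_mm) / sy)
  amp <- cherenkov_yield(beam, tissue, fff_dose_rate_factor)
  px <- amp * (fy %o% fx)
  field_image(px, pixel_scale = pixel_scale,
              meta = list(beam = beam, tissue = tissue, shift = shift,
                          sigma_edge_mm = sigma_edge_mm))
}

#' Add CCD acquisition noise to a noiseless frame
#'
#' Applies the camera noise model: (i) a per-pixel Gaussian background offset
#' (dark level), (ii) Poisson-like signal shot noise with variance
#' `shot_noise_gain` per unit signal, and (iii) sparkle impulses — a
#' Poisson-distributed number of pixels driven to near saturation by direct
#' x-ray hits on the CCD — then clips to the bit-depth range. Signal and dark
#' noise scale with integration time relative to the modality's light-tissue
#' reference (1.0 s photon, 1.2 s electron).
#'
#' Uses the current RNG state; seed control belongs to the caller (see
#' [simulate_condition()]).
#'
#' @param image A noiseless [field_image()].
#' @param acq An [acquisition_spec()].
#' @return A noisy [field_image()].
#' @export
add_noise <- function(image, acq) {
  stopifnot(inherits(image, "field_image"), inherits(acq, "acquisition_spec"))
  px <- image$pixels
  n <- length(px)
  maxv <- 2^acq$bit_depth - 1

  modality <- if (!is.null(image$meta$beam)) image$meta$beam$modality else "photon"
  t_ref <- if (modality == "photon") 1.0 else 1.2
  t <- acq$integration_time_s
  if (is.null(t)) {
    tis <- image$meta$tissue
    t <- if (!is.null(image$meta$beam) && !is.null(tis))
      default_integration_time(image$meta$beam, tis) else t_ref
  }
  tscale <- t / t_ref

  sig <- px * tscale
  if (acq$shot_noise_gain > 0) {
    g <- acq$shot_noise_gain
    sig <- g * stats::rpois(n, sig / g)
  }
  out <- sig + stats::rnorm(n, acq$background_mean * tscale,
                            acq$background_sd * tscale)
  if (acq$sparkle_rate > 0) {
    k <- stats::rpois(1, acq$sparkle_rate)
    if (k > 0) {
      idx <- sample.int(n, k)
      out[idx] <- stats::runif(k, 0.97, 1) * maxv
    }
  }
  out <- pmin(pmax(out, 0), maxv)
  dim(out) <- dim(px)
  field_image(out, pixel_scale = image$pixel_scale,
              meta = c(image$meta, list(acquisition = acq)),
              bit_depth = acq$bit_depth)
}

#' Simulate one acquisition condition
#'
#' Generates the full measured stack for one scenario: `frames_per_condition`
#' independent noisy realizations of the ideal fluence map, plus the same
#' number of background frames (radiation off, zero fluence) under identical
#' camera settings. Bit-identical for identical `(scenario, rng_seed)`.
#'
#' @param beam,tissue,shift Scenario specs (see [ideal_fluence_map()]).
#' @param acq An [acquisition_spec()].
#' @param rng_seed Integer seed for this condition.
#' @param ... Passed to [ideal_fluence_map()] (`grid_shape`, `sigma_edge_mm`,
#'   `fff_dose_rate_factor`).
#' @return An [image_stack()] with full scenario metadata.
#' @export
simulate_condition <- function(beam, tissue, acq = acquisition_spec(),
                               shift = NULL, rng_seed = 1L, ...) {
  ideal <- ideal_fluence_map(beam, tissue, shift,
                             pixel_scale = acq$pixel_scale_true, ...)
  dark <- field_image(array(0, dim(ideal$pixels)),
                      pixel_scale = ideal$pixel_scale, meta = ideal$meta)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(rng_seed %% .Machine$integer.max)
  frames <- lapply(seq_len(acq$frames_per_condition),
                   function(i) add_noise(ideal, acq))
  # radiation off: no beam, hence no direct x-ray hits (sparkles) on the CCD
  acq_bg <- acq; acq_bg$sparkle_rate <- 0
  bg <- lapply(seq_len(acq$frames_per_condition),
               function(i) add_noise(dark, acq_bg))
  image_stack(frames, bg,
              meta = list(beam = beam, tissue = tissue, shift = shift,
                          acquisition = acq, rng_seed = rng_seed))
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) return(invisible())
  assign(".Random.seed", old, envir = globalenv())
}

#' Synthetic ruler calibration image
#'
#' Renders the standard-scale ruler imaged at the accelerator isocenter plane:
#' bright tick marks along X at exact multiples of
#' `tick_spacing_mm * pixel_scale_true` pixels, with sub-pixel tick positions
#' rendered by area weighting so tick centroids are exact.
#'
#' @param pixel_scale_true True pixel scale (px/mm), default 3.6.
#' @param tick_spacing_mm Spacing between tick centers in mm (default 10).
#' @param grid_shape Image shape `(rows, cols)`.
#' @param tick_width_mm Width of each tick mark (mm).
#' @param amplitude Tick grayscale amplitude.
#' @param background Constant background level.
#' @return A [field_image()] whose metadata records the true scale.
#' @export
make_ruler_image <- function(pixel_scale_true = 3.6, tick_spacing_mm = 10,
                             grid_shape = c(60, 560), tick_width_mm = 1,
                             amplitude = 30000, background = 0) {
  if (tick_spacing_mm <= 0) stop("tick_spacing_mm must be > 0")
  ny <- grid_shape[1]; nx <- grid_shape[2]
  cx <- (nx - 1) / 2
  spacing_px <- tick_spacing_mm * pixel_scale_true
  half_w <- tick_width_mm * pixel_scale_true / 2
  kmax <- floor((cx - half_w - 1) / spacing_px)
  if (2 * kmax + 1 < 2)
    stop("fewer than 2 ruler ticks fit on the grid; enlarge it or reduce tick_spacing_mm")
  centers <- cx + (-kmax:kmax) * spacing_px
  # per-column coverage of [-0.5, +0.5] pixel cells by each tick interval
  row <- numeric(nx)
  edges <- 0:(nx - 1)
  for (p in centers) {
    lo <- pmax(edges - 0.5, p - half_w)
    hi <- pmin(edges + 0.5, p + half_w)
    row <- row + pmax(hi - lo, 0)
  }
  px <- background + amplitude * matrix(row, nrow = ny, ncol = nx, byrow = TRUE)
  field_image(pmin(px, 65535), pixel_scale = pixel_scale_true,
              meta = list(ruler = list(pixel_scale_true = pixel_scale_true,
                                       tick_spacing_mm = tick_spacing_mm,
                                       tick_width_mm = tick_width_mm)))
}
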