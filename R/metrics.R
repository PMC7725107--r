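#' Mean grayscale value over an ROI
#'
#' Arithmetic mean of all pixel values in the ROI — the MGV intensity
#' summary. Conventional defaults place a 100 x 50 mm ROI on the photon
#' field and a 75 x 50 mm ROI on the electron field (see [mgv_roi()]).
#'
#' @param image A [field_image()] (normally preprocessed).
#' @param roi A [rect_roi()].
#' @param scale Optional `"pixel_scale"` override.
#' @return The mean grayscale value.
#' @export
mean_grayscale <- function(image, roi, scale = NULL) {
  ix <- resolve_roi(roi, image, scale)
  mean(image$pixels[ix$rows, ix$cols])
}

#' Default MGV ROI for a beam
#'
#' A 100 x 50 mm (photon) or 75 x 50 mm (electron) rectangle centered on the
#' nominal field center.
#'
#' @param beam A [beam_spec()].
#' @return A [rect_roi()].
#' @export
mgv_roi <- function(beam) {
  w <- if (beam$modality == "photon") 100 else 75
  ctr <- mean(field_x_range(beam))
  rect_roi(ctr - w / 2, -25, w, 50)
}

#' Y-averaged grayscale profile of an ROI
#'
#' The GPVCI intensity summary: the ROI's per-column mean profile along the
#' X axis. Identical contract to [extract_profile()] (shared
#' implementation).
#'
#' @inheritParams mean_grayscale
#' @return An `"intensity_profile"`.
#' @export
grayscale_profile <- function(image, roi, scale = NULL) {
  extract_profile(image, roi, scale)
}

#' Intensity metrics of one preprocessed condition
#'
#' Computes the MGV and GPVCI of a preprocessed image over the beam's
#' default ROI.
#'
#' @param image A preprocessed [field_image()] whose metadata carries the
#'   beam spec (or supply `beam`).
#' @param beam A [beam_spec()]; default taken from the image metadata.
#' @param roi ROI override; default [mgv_roi()] of the beam.
#' @return A list with `mgv`, `gpvci` and the `roi` used.
#' @export
intensity_metrics <- function(image, beam = NULL, roi = NULL) {
  if (is.null(beam)) beam <- image$meta$beam
  if (is.null(beam)) stop("beam spec missing: supply `beam`")
  if (is.null(roi)) roi <- mgv_roi(beam)
  list(mgv = mean_grayscale(image, roi),
       gpvci = grayscale_profile(image, roi),
       roi = roi)
}
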