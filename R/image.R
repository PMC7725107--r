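#' CLI image frame
#'
#' A single 2-D grayscale frame with its pixel geometry and acquisition
#' metadata. Rows index the image Y axis, columns the X axis; X increases
#' toward the patient's inferior direction (the couch-shift axis). Pixel
#' centers sit at integer 0-based coordinates; millimeter coordinates place
#' the isocenter projection at the image center.
#'
#' @param pixels Numeric matrix of nonnegative grayscale values.
#' @param pixel_scale Pixels per millimeter (> 0).
#' @param meta Named list of provenance (beam/tissue/acquisition/shift specs).
#' @param bit_depth Bit depth bounding pixel values (default 16).
#' @return An object of class `"field_image"`.
#' @export
field_image <- function(pixels, pixel_scale = 3.6, meta = list(),
                        bit_depth = 16L) {
  pixels <- as.matrix(pixels)
  if (pixel_scale <= 0) stop("pixel_scale must be > 0")
  maxv <- 2^bit_depth - 1
  if (any(pixels < 0) || any(pixels > maxv))
    stop(sprintf("pixel values must lie in [0, %d]", maxv))
  structure(list(pixels = pixels, pixel_scale = pixel_scale, meta = meta,
                 bit_depth = as.integer(bit_depth)),
            class = "field_image")
}

#' @export
print.field_image <- function(x, ...) {
  cat(sprintf("<field_image> %d x %d px, %.3g px/mm, %d-bit, range [%.4g, %.4g]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_scale, x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' @export
dim.field_image <- function(x) dim(x$pixels)

#' Stack of repeated CLI frames plus matched background frames
#'
#' Bundles the repeated irradiation frames for one condition with the
#' background frames acquired under identical settings with the radiation
#' off. All frames share shape and pixel scale.
#'
#' @param frames List of [field_image()] irradiation frames.
#' @param background_frames List of [field_image()] radiation-off frames.
#' @param meta Named list of scenario provenance.
#' @return An object of class `"image_stack"`.
#' @export
image_stack <- function(frames, background_frames, meta = list()) {
  stopifnot(length(frames) >= 1L, length(background_frames) >= 1L)
  all_frames <- c(frames, background_frames)
  d <- dim(all_frames[[1]]$pixels)
  sc <- all_frames[[1]]$pixel_scale
  for (f in all_frames) {
    if (!identical(dim(f$pixels), d))
      stop(sprintf("all frames must share shape: found %s vs %s",
                   paste(dim(f$pixels), collapse = "x"),
                   paste(d, collapse = "x")))
    if (!isTRUE(all.equal(f$pixel_scale, sc)))
      stop("all frames must share pixel_scale")
  }
  structure(list(frames = frames, background_frames = background_frames,
                 pixel_scale = sc, meta = meta),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  cat(sprintf("<image_stack> %d frames + %d background, %d x %d px, %.3g px/mm\n",
              length(x$frames), length(x$background_frames),
              nrow(x$frames[[1]]$pixels), ncol(x$frames[[1]]$pixels),
              x$pixel_scale))
  invisible(x)
}

# mm -> fractional 0-based pixel coordinate along X / Y (center = isocenter)
mm_to_px_coord <- function(mm, n, pixel_scale) (n - 1) / 2 + mm * pixel_scale

# fractional pixel coordinate -> mm
px_coord_to_mm <- function(px, n, pixel_scale) (px - (n - 1) / 2) / pixel_scale
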