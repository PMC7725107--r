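#' Subtract the background from every frame of a stack
#'
#' The per-pixel median of the radiation-off background frames is subtracted
#' from each irradiation frame; negative results clamp to 0 (grayscale
#' contract). Background frames are retained on the result for later
#' signal-to-noise estimation.
#'
#' @param stack An [image_stack()] with background frames.
#' @return The stack with background-subtracted frames.
#' @export
subtract_background <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  d <- dim(stack$frames[[1]]$pixels)
  db <- dim(stack$background_frames[[1]]$pixels)
  if (!identical(d, db))
    stop(sprintf("frame shape %s does not match background shape %s",
                 paste(d, collapse = "x"), paste(db, collapse = "x")))
  bg <- pixelwise_median(stack$background_frames)
  stack$frames <- lapply(stack$frames, function(f) {
    f$pixels <- pmax(f$pixels - bg, 0)
    f
  })
  stack
}

# per-pixel median across a list of frames -> matrix
pixelwise_median <- function(frames) {
  m <- vapply(frames, function(f) as.numeric(f$pixels),
              numeric(length(frames[[1]]$pixels)))
  out <- row_median(m)
  dim(out) <- dim(frames[[1]]$pixels)
  out
}

#' Temporal median over the frame stack
#'
#' Per-pixel median across the repeated frames of one condition. With three
#' (or more) repeats this removes sparkle impulses present in only one frame.
#'
#' @param stack An [image_stack()] with at least 3 frames.
#' @return A single [field_image()].
#' @export
stack_median <- function(stack) {
  stopifnot(inherits(stack, "image_stack"))
  if (length(stack$frames) < 3)
    stop("stack_median needs at least 3 frames")
  px <- pixelwise_median(stack$frames)
  field_image(px, pixel_scale = stack$pixel_scale, meta = stack$meta)
}

#' Spatial median smoothing
#'
#' Running 2-D median with a rectangular kernel, default 10 x 10 pixels. The
#' even kernel is anchored so that the window covers offsets \[-5, +4\] along
#' each axis; image borders are handled by edge replication.
#'
#' @param image A [field_image()].
#' @param kernel Integer pair `(rows, cols)`, each >= 1 and <= the image size.
#' @return The smoothed [field_image()].
#' @export
median_smooth <- function(image, kernel = c(10, 10)) {
  stopifnot(inherits(image, "field_image"))
  image$pixels <- median_filter_rect(image$pixels, as.integer(kernel[1]),
                                     as.integer(kernel[2]))
  image
}

#' Full denoising chain for one condition
#'
#' Background subtraction, temporal median over the repeated frames, then
#' 10 x 10 spatial median smoothing — the standard CLI denoising sequence.
#'
#' @param stack An [image_stack()].
#' @param kernel Spatial median kernel (default `c(10, 10)`).
#' @return A denoised [field_image()].
#' @export
preprocess_stack <- function(stack, kernel = c(10, 10)) {
  median_smooth(stack_median(subtract_background(stack)), kernel = kernel)
}
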