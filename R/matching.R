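#' Rectangular region of interest in isocenter-plane millimeters
#'
#' Coordinates are millimeters at the isocenter plane with the origin at the
#' image center; X increases toward inferior, Y toward the image bottom.
#'
#' @param x_min_mm,y_min_mm Lower corner (mm).
#' @param width_mm,height_mm Extents along X and Y (mm, > 0).
#' @return An object of class `"rect_roi"`.
#' @export
rect_roi <- function(x_min_mm, y_min_mm, width_mm, height_mm) {
  if (width_mm <= 0 || height_mm <= 0)
    stop("ROI extents must be positive")
  structure(list(x_min_mm = x_min_mm, y_min_mm = y_min_mm,
                 width_mm = width_mm, height_mm = height_mm),
            class = "rect_roi")
}

#' Default matching ROI centered on the field junction
#'
#' A rectangle centered on the photon-electron junction (x = 0), wide enough
#' along X to contain the difference band of the largest tested shift plus
#' penumbra.
#'
#' @param width_mm,height_mm ROI extents (mm); defaults 30 x 30.
#' @return A [rect_roi()].
#' @export
junction_roi <- function(width_mm = 30, height_mm = 30) {
  rect_roi(-width_mm / 2, -height_mm / 2, width_mm, height_mm)
}

# resolve a rect_roi to 1-based pixel row/col index vectors
resolve_roi <- function(roi, image, scale = NULL) {
  stopifnot(inherits(roi, "rect_roi"), inherits(image, "field_image"))
  s <- if (is.null(scale)) image$pixel_scale else as_px_per_mm(scale)
  d <- dim(image$pixels)
  c0 <- round(mm_to_px_coord(roi$x_min_mm, d[2], s)) + 1
  c1 <- round(mm_to_px_coord(roi$x_min_mm + roi$width_mm, d[2], s)) + 1
  r0 <- round(mm_to_px_coord(roi$y_min_mm, d[1], s)) + 1
  r1 <- round(mm_to_px_coord(roi$y_min_mm + roi$height_mm, d[1], s)) + 1
  if (c0 < 1 || r0 < 1 || c1 > d[2] || r1 > d[1])
    stop(sprintf(paste0("ROI [%d:%d, %d:%d] px exceeds the %d x %d image; ",
                        "largest contained ROI is rows %d:%d, cols %d:%d"),
                 r0, r1, c0, c1, d[1], d[2],
                 max(r0, 1), min(r1, d[1]), max(c0, 1), min(c1, d[2])))
  list(rows = r0:r1, cols = c0:c1)
}

check_compatible <- function(a, b) {
  if (!identical(dim(a$pixels), dim(b$pixels)))
    stop(sprintf("image shapes differ: %s vs %s",
                 paste(dim(a$pixels), collapse = "x"),
                 paste(dim(b$pixels), collapse = "x")))
  if (!isTRUE(all.equal(a$pixel_scale, b$pixel_scale)))
    stop("pixel scales differ")
}

#' Compose the reference image
#'
#' Pixelwise sum of the zero-shift photon and electron CLI images, clipped to
#' the bit-depth maximum. The fraction of clipped pixels is recorded as the
#' `clip_fraction` attribute on the result's pixels.
#'
#' @param photon_ref,electron_ref Preprocessed zero-shift [field_image()]s.
#' @return The composite [field_image()].
#' @export
compose_reference <- function(photon_ref, electron_ref) {
  check_compatible(photon_ref, electron_ref)
  maxv <- 2^photon_ref$bit_depth - 1
  s <- photon_ref$pixels + electron_ref$pixels
  clip <- mean(s > maxv)
  out <- field_image(pmin(s, maxv), pixel_scale = photon_ref$pixel_scale,
                     meta = photon_ref$meta, bit_depth = photon_ref$bit_depth)
  attr(out$pixels, "clip_fraction") <- clip
  out
}

#' Compose a shifted composite image
#'
#' Adds the shifted field's CLI image to the other field's zero-shift image,
#' mirroring [compose_reference()]; which field carries the shift is recorded
#' in the composite metadata.
#'
#' @param shifted_img Preprocessed [field_image()] of the shifted field.
#' @param unshifted_other Preprocessed zero-shift [field_image()] of the
#'   other field.
#' @return The composite [field_image()].
#' @export
compose_shifted <- function(shifted_img, unshifted_other) {
  out <- compose_reference(shifted_img, unshifted_other)
  out$meta <- shifted_img$meta
  out$meta$shifted_field <-
    if (!is.null(shifted_img$meta$shift)) shifted_img$meta$shift$shifted_field
  out
}

#' Absolute difference image
#'
#' Pixelwise absolute difference between the shifted composite and the
#' reference, so both field gaps and overlaps produce a positive band whose
#' width encodes the shift.
#'
#' @param shifted_composite,reference Same-geometry [field_image()]s.
#' @return A [field_image()] of absolute differences.
#' @export
difference_image <- function(shifted_composite, reference) {
  check_compatible(shifted_composite, reference)
  out <- shifted_composite
  out$pixels <- abs(shifted_composite$pixels - reference$pixels)
  out
}

#' Extract the X intensity profile of an ROI
#'
#' Per-column mean over the ROI's rows: the Y-averaged intensity profile
#' along the superior-inferior (X) axis.
#'
#' @param image A [field_image()].
#' @param roi A [rect_roi()].
#' @param scale Optional `"pixel_scale"` overriding the image's own scale.
#' @return An object of class `"intensity_profile"` with `positions_px`
#'   (0-based pixel X coordinates) and `values`.
#' @export
extract_profile <- function(image, roi, scale = NULL) {
  ix <- resolve_roi(roi, image, scale)
  vals <- colMeans(image$pixels[ix$rows, ix$cols, drop = FALSE])
  structure(list(positions_px = ix$cols - 1, values = unname(vals),
                 roi = roi),
            class = "intensity_profile")
}

# baseline: median of the lowest quartile of profile values
profile_baseline <- function(values) {
  q <- sort(values)[seq_len(max(1, floor(length(values) / 4)))]
  stats::median(q)
}

#' Full width at half maximum of a profile
#'
#' The baseline is the median of the lowest quartile of profile values; the
#' half level sits midway between baseline and the global maximum. The width
#' is the distance between the outermost crossings of the half level on
#' either side of the global peak, with linear interpolation between the
#' adjacent samples at each crossing. If a side never drops below the half
#' level the width is truncated at the profile end.
#'
#' @param profile An [extract_profile()] result (or a numeric vector).
#' @return Width in pixels.
#' @export
profile_fwhm <- function(profile) {
  v <- if (inherits(profile, "intensity_profile")) profile$values else
    as.numeric(profile)
  pos <- if (inherits(profile, "intensity_profile")) profile$positions_px else
    seq_along(v) - 1
  base <- profile_baseline(v)
  ipk <- which.max(v)
  peak <- v[ipk]
  if (peak <= base)
    stop("no measurable band: profile peak does not rise above the baseline")
  half <- base + (peak - base) / 2

  # outermost upward crossing left of the peak
  xl <- pos[1]
  for (i in seq_len(ipk - 1)) {
    if (v[i] < half && v[i + 1] >= half) {
      xl <- pos[i] + (half - v[i]) / (v[i + 1] - v[i]) * (pos[i + 1] - pos[i])
      break
    }
  }
  # outermost downward crossing right of the peak
  n <- length(v)
  xr <- pos[n]
  if (ipk < n) {
    for (i in seq(n - 1, ipk)) {
      if (v[i] >= half && v[i + 1] < half) {
        xr <- pos[i] + (v[i] - half) / (v[i] - v[i + 1]) * (pos[i + 1] - pos[i])
        break
      }
    }
  }
  xr - xl
}

# pooled SD of background-frame residuals (about their pixelwise median)
# within the ROI: the noise floor entering the SNR gate
background_noise_sd <- function(stacks, roi, scale = NULL) {
  res <- unlist(lapply(stacks, function(st) {
    bg <- pixelwise_median(st$background_frames)
    img <- st$background_frames[[1]]
    ix <- resolve_roi(roi, img, scale)
    unlist(lapply(st$background_frames, function(f)
      (f$pixels - bg)[ix$rows, ix$cols]))
  }))
  stats::sd(res)
}
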