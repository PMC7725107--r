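#' Write an image stack to disk
#'
#' Saves the irradiation frames as a multi-page 16-bit grayscale TIFF, the
#' background frames as a second TIFF (`*_bg.tif`), and a JSON sidecar
#' recording the scenario metadata and pixel scale.
#'
#' @param stack An [image_stack()].
#' @param path Base path without extension; writes `<path>.tif`,
#'   `<path>_bg.tif` and `<path>.json`.
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "image_stack"))
  to01 <- function(f) f$pixels / 65535
  tiff::writeTIFF(lapply(stack$frames, to01), paste0(path, ".tif"),
                  bits.per.sample = 16L)
  tiff::writeTIFF(lapply(stack$background_frames, to01),
                  paste0(path, "_bg.tif"), bits.per.sample = 16L)
  meta <- stack$meta
  meta$pixel_scale <- stack$pixel_scale
  meta$n_frames <- length(stack$frames)
  jsonlite::write_json(strip_classes(meta), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

strip_classes <- function(x) {
  if (is.list(x)) lapply(unclass(x), strip_classes) else x
}

#' Read an image stack written by [write_stack()]
#'
#' Reads the multi-page TIFFs (8-bit input is promoted to the 16-bit range)
#' and the JSON sidecar.
#'
#' @param path Base path as given to [write_stack()].
#' @return An [image_stack()] (metadata as plain lists).
#' @export
read_stack <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  sc <- if (!is.null(meta$pixel_scale)) meta$pixel_scale else 3.6
  rd <- function(file) {
    pages <- tiff::readTIFF(file, all = TRUE, info = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    lapply(pages, function(m) {
      if (length(dim(m)) == 3L) m <- m[, , 1]  # collapse any channel axis
      field_image(round(m * 65535), pixel_scale = sc, meta = meta)
    })
  }
  image_stack(rd(paste0(path, ".tif")), rd(paste0(path, "_bg.tif")),
              meta = meta)
}

#' Read a scenario configuration from YAML
#'
#' Builds the spec objects from a YAML file with `beam`, `tissue`,
#' `acquisition` and `shift` blocks whose keys mirror the constructor
#' arguments of [beam_spec()], [tissue_spec()], [acquisition_spec()] and
#' [shift_spec()]. Missing blocks take the package defaults; a missing or
#' zero `shift` block means no introduced shift.
#'
#' @param path Path to the YAML file.
#' @return A list with elements `beam`, `tissue`, `acquisition`, `shift`.
#' @export
read_scenario_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  list(
    beam = do.call(beam_spec, cfg$beam),
    tissue = do.call(tissue_spec, as.list(cfg$tissue)),
    acquisition = do.call(acquisition_spec, as.list(cfg$acquisition)),
    shift = if (is.null(cfg$shift)) NULL else do.call(shift_spec, cfg$shift)
  )
}

#' Write an experiment result table to CSV
#'
#' One row per scenario-seed measurement, byte-identical across reruns with
#' the same configuration and seeds.
#'
#' @param x A `"cli_experiment"` from [run_experiment()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
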