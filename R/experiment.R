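#' Scenario grid for the AP photon + electron study
#'
#' One row per tested beam x shift x direction: photon 6/10 MV conventional
#' and 6/10 FFF (1200/2400 MU/min), electrons 4-15 MeV, all AP, with couch
#' shifts of 0, 2, 5 and 10 mm toward superior and inferior. The tested
#' beam's field carries the shift.
#'
#' @param shifts_mm Shift magnitudes (default `c(0, 2, 5, 10)`).
#' @param directions Shift directions (default both).
#' @return A data frame of scenarios for [run_experiment()].
#' @export
scenario_grid_ap <- function(shifts_mm = c(0, 2, 5, 10),
                             directions = c("superior", "inferior")) {
  beams <- rbind(
    data.frame(modality = "photon", energy = c(6, 10, 6, 10),
               dose_rate = c(600, 600, 1200, 2400),
               fff = c(FALSE, FALSE, TRUE, TRUE), gantry = 0),
    data.frame(modality = "electron", energy = c(4, 6, 8, 10, 12, 15),
               dose_rate = 600, fff = FALSE, gantry = 0))
  expand_scenarios(beams, shifts_mm, directions)
}

#' Scenario grid for the oblique tangential photon study
#'
#' Photon 6/10 MV and 6/10 FFF fields at gantry 330 and 150 deg (entry and
#' exit side), with the same shift grid as the AP study. The partner electron
#' field stays AP.
#'
#' @inheritParams scenario_grid_ap
#' @param gantry_angles Oblique gantry angles (default `c(330, 150)`).
#' @return A data frame of scenarios for [run_experiment()].
#' @export
scenario_grid_oblique <- function(shifts_mm = c(0, 2, 5, 10),
                                  directions = c("superior", "inferior"),
                                  gantry_angles = c(330, 150)) {
  beams <- do.call(rbind, lapply(gantry_angles, function(g)
    data.frame(modality = "photon", energy = c(6, 10, 6, 10),
               dose_rate = c(600, 600, 1200, 2400),
               fff = c(FALSE, FALSE, TRUE, TRUE), gantry = g)))
  expand_scenarios(beams, shifts_mm, directions)
}

expand_scenarios <- function(beams, shifts_mm, directions) {
  grid <- merge(beams,
                expand.grid(shift_mm = shifts_mm, direction = directions,
                            stringsAsFactors = FALSE))
  grid <- grid[order(grid$modality, grid$gantry, grid$energy, grid$dose_rate,
                     grid$shift_mm, grid$direction), ]
  grid$scenario_id <- sprintf("%s%g%s_g%03d_s%g%s",
                              substr(grid$modality, 1, 1), grid$energy,
                              ifelse(grid$fff, "FFF", ""), grid$gantry,
                              grid$shift_mm, substr(grid$direction, 1, 3))
  rownames(grid) <- NULL
  grid
}

# deterministic 31-bit sub-seed from a base seed and a key string
derive_seed <- function(base_seed, key) {
  h <- as.double(base_seed %% 2147483647)
  for (k in utf8ToInt(key)) h <- (h * 131 + k) %% 2147483647
  as.integer(h)
}

scenario_beam <- function(row) {
  beam_spec(row$modality, row$energy, dose_rate = row$dose_rate,
            fff = row$fff, gantry_angle_deg = row$gantry)
}

#' Run the full matching experiment grid
#'
#' For every scenario and seed: simulate the tested beam's zero-shift and
#' shifted stacks and the partner field's zero-shift stack, denoise, compose
#' reference and shifted composites, measure the matching value, and compute
#' the tested field's MGV. Zero-shift stacks are simulated once per
#' (beam, seed) and reused across the shift series. Per-scenario failures are
#' recorded in the `status` column without aborting the grid.
#'
#' @param scenarios A scenario data frame ([scenario_grid_ap()] or
#'   [scenario_grid_oblique()]).
#' @param seeds Integer vector of replicate seeds (>= 1 values).
#' @param tissue A [tissue_spec()] (default yellow).
#' @param acq An [acquisition_spec()].
#' @param partner_photon_energy,partner_electron_energy Energy of the fixed
#'   partner field paired with a tested electron / photon beam.
#' @param roi Matching ROI (default [junction_roi()]).
#' @param detect_threshold,apply_correction,correction_mm Passed to
#'   [cli_match()].
#' @param verbose Print per-scenario progress.
#' @return A data frame of class `"cli_experiment"`, one row per
#'   scenario-seed, with a `summary` attribute of per-group statistics
#'   (mean and SD of |discrepancy|, fraction within 1 mm, maximum).
#' @export
run_experiment <- function(scenarios, seeds = 1:3,
                           tissue = tissue_spec("yellow"),
                           acq = acquisition_spec(),
                           partner_photon_energy = 6,
                           partner_electron_energy = 8,
                           roi = junction_roi(), detect_threshold = 2,
                           apply_correction = FALSE, correction_mm = 0.55,
                           verbose = FALSE) {
  stopifnot(length(seeds) >= 1)
  cache <- new.env(parent = emptyenv())
  zero_stack <- function(beam, seed) {
    key <- paste(beam$modality, beam$energy, beam$dose_rate,
                 beam$gantry_angle_deg, seed, sep = "_")
    if (!exists(key, envir = cache)) {
      st <- simulate_condition(beam, tissue, acq, shift = NULL,
                               rng_seed = derive_seed(seed, key))
      assign(key, prepare_stack(st), envir = cache)
    }
    get(key, envir = cache)
  }

  if (nrow(scenarios) == 0) {
    out <- data.frame()
    class(out) <- c("cli_experiment", "data.frame")
    attr(out, "summary") <- data.frame()
    return(out)
  }
  rows <- vector("list", nrow(scenarios) * length(seeds))
  k <- 0
  for (i in seq_len(nrow(scenarios))) {
    row <- scenarios[i, ]
    beam <- scenario_beam(row)
    partner <- if (row$modality == "photon")
      beam_spec("electron", partner_electron_energy)
    else beam_spec("photon", partner_photon_energy)
    for (seed in seeds) {
      k <- k + 1
      rec <- data.frame(row, seed = seed, introduced_mm = NA_real_,
                        measured_mm = NA_real_, discrepancy_mm = NA_real_,
                        abs_discrepancy_mm = NA_real_, detectable = NA,
                        snr = NA_real_, mgv = NA_real_, status = "ok",
                        stringsAsFactors = FALSE)
      res <- tryCatch({
        tested0 <- zero_stack(beam, seed)
        partner0 <- zero_stack(partner, seed)
        sh <- shift_spec(row$shift_mm, row$direction,
                         shifted_field = row$modality)
        shifted <- prepare_stack(simulate_condition(
          beam, tissue, acq, shift = sh,
          rng_seed = derive_seed(seed, paste0(row$scenario_id, "_shift"))))
        photon0 <- if (row$modality == "photon") tested0 else partner0
        electron0 <- if (row$modality == "photon") partner0 else tested0
        m <- cli_match(photon0, electron0,
                       photon_shifted = if (row$modality == "photon") shifted,
                       electron_shifted = if (row$modality == "electron") shifted,
                       roi = roi, detect_threshold = detect_threshold,
                       apply_correction = apply_correction,
                       correction_mm = correction_mm, preprocessed = TRUE)
        rec$introduced_mm <- m$introduced_shift_mm
        rec$measured_mm <- m$measured_matching_mm
        rec$discrepancy_mm <- m$discrepancy_mm
        rec$abs_discrepancy_mm <- abs(m$discrepancy_mm)
        rec$detectable <- m$detectable
        rec$snr <- m$snr
        rec$mgv <- mean_grayscale(tested0$processed, mgv_roi(beam))
        rec
      }, error = function(e) {
        rec$status <- paste("error:", conditionMessage(e))
        rec
      })
      rows[[k]] <- res
      if (verbose)
        message(sprintf("%s seed %d: measured %.2f mm (introduced %+g)",
                        row$scenario_id, seed, res$measured_mm,
                        res$introduced_mm))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cli_experiment", "data.frame")
  attr(out, "summary") <- summarize_experiment(out)
  out
}

summarize_experiment <- function(x) {
  ok <- x[x$status == "ok" & !is.na(x$abs_discrepancy_mm), ]
  if (nrow(ok) == 0) return(data.frame())
  grp <- interaction(ok$modality, ok$gantry, drop = TRUE)
  do.call(rbind, lapply(split(ok, grp), function(g) {
    data.frame(modality = g$modality[1], gantry = g$gantry[1],
               n = nrow(g),
               mean_abs_mm = mean(g$abs_discrepancy_mm),
               sd_abs_mm = stats::sd(g$abs_discrepancy_mm),
               frac_within_1mm = mean(g$abs_discrepancy_mm <= 1),
               max_abs_mm = max(g$abs_discrepancy_mm))
  }))
}

#' @export
print.cli_experiment <- function(x, ...) {
  cat(sprintf("<cli_experiment> %d measurements (%d scenarios)\n",
              nrow(x), length(unique(x$scenario_id))))
  s <- attr(x, "summary")
  if (!is.null(s) && nrow(s) > 0) {
    cat("Group summary (|discrepancy|, mm):\n")
    print(format(s, digits = 3), row.names = FALSE)
  }
  invisible(x)
}

#' @export
summary.cli_experiment <- function(object, ...) attr(object, "summary")
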