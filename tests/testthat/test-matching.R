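yellow <- tissue_spec("yellow")

test_that("reference composition is additive, clipped, and clip-flagged", {
  p <- field_image(matrix(c(rep(500, 50), rep(0, 50)), 10, 10))
  e <- field_image(matrix(c(rep(0, 50), rep(300, 50)), 10, 10))
  zero <- field_image(matrix(0, 10, 10))
  # additive identity
  expect_equal(compose_reference(p, zero)$pixels, p$pixels, ignore_attr = TRUE)
  # spatially disjoint fields: union, max unchanged
  u <- compose_reference(p, e)
  expect_equal(max(u$pixels), 500)
  expect_equal(u$pixels, p$pixels + e$pixels, ignore_attr = TRUE)
  expect_equal(attr(u$pixels, "clip_fraction"), 0)
  # 8-bit clipping
  a8 <- field_image(matrix(200, 4, 4), bit_depth = 8)
  s8 <- compose_reference(a8, a8)
  expect_true(all(s8$pixels == 255))
  expect_equal(attr(s8$pixels, "clip_fraction"), 1)
  expect_error(compose_reference(p, field_image(matrix(0, 4, 4))), "shapes")
})

test_that("shifted composite matches the reference at zero shift and keeps provenance", {
  acq <- acquisition_spec(background_mean = 0, background_sd = 0,
                          sparkle_rate = 0, shot_noise_gain = 0)
  ph <- beam_spec("photon", 6)
  p0 <- preprocess_stack(simulate_condition(ph, yellow, acq, NULL, 1))
  e0 <- preprocess_stack(simulate_condition(beam_spec("electron", 8), yellow,
                                            acq, NULL, 1))
  sh <- shift_spec(0, "superior", "photon")
  ps <- preprocess_stack(simulate_condition(ph, yellow, acq, sh, 1))
  expect_equal(compose_shifted(ps, e0)$pixels,
               compose_reference(p0, e0)$pixels, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(compose_shifted(ps, e0)$meta$shifted_field, "photon")
})

test_that("the difference of composites is supported only at the moved edges", {
  acq <- acquisition_spec(background_mean = 0, background_sd = 0,
                          sparkle_rate = 0, shot_noise_gain = 0)
  ph <- beam_spec("photon", 6)
  p0 <- preprocess_stack(simulate_condition(ph, yellow, acq, NULL, 1))
  e0 <- preprocess_stack(simulate_condition(beam_spec("electron", 8), yellow,
                                            acq, NULL, 1))
  sh <- shift_spec(10, "superior", "photon")
  ps <- preprocess_stack(simulate_condition(ph, yellow, acq, sh, 1))
  d <- difference_image(compose_shifted(ps, e0), compose_reference(p0, e0))
  nx <- ncol(d$pixels)
  x_mm <- (0:(nx - 1) - (nx - 1) / 2) / d$pixel_scale
  colmax <- apply(d$pixels, 2, max)
  band <- x_mm > -14 & x_mm < 4         # junction band (shift 10 superior)
  far <- x_mm > 36 & x_mm < 54          # far photon edge band
  outside <- !(band | far)
  expect_gt(max(colmax[band]), 0.9 * max(colmax))
  expect_gt(max(colmax[far]), 0.9 * max(colmax))
  expect_lt(max(colmax[outside]), 0.02 * max(colmax))
  # identical inputs give the zero image
  r <- compose_reference(p0, e0)
  expect_true(all(difference_image(r, r)$pixels == 0))
})

test_that("a sharp field stepped by k px leaves bands exactly k px wide", {
  for (k in c(2, 5)) {
    a <- matrix(0, 20, 300); a[, 100:199] <- 1000
    b <- matrix(0, 20, 300); b[, (100 + k):(199 + k)] <- 1000
    d <- difference_image(field_image(b), field_image(a))
    runs <- rle(apply(d$pixels, 2, max) > 0)
    expect_equal(runs$lengths[runs$values], c(k, k))
  }
})

test_that("erf-edged difference bands have FWHM equal to the shift", {
  # oracle: FWHM of pnorm((x+k)/s) - pnorm(x/s) by bisection on the 1-D form
  oracle_band_fwhm <- function(k_px, s_px) {
    g <- function(x) pnorm((x + k_px) / s_px) - pnorm(x / s_px)
    peak <- g(-k_px / 2)
    lo <- -k_px / 2; hi <- 100          # right half-level crossing
    for (i in 1:100) {
      m <- (lo + hi) / 2
      if (g(m) > peak / 2) lo <- m else hi <- m
    }
    2 * ((lo + hi) / 2 + k_px / 2)      # symmetric about -k/2
  }
  ph <- beam_spec("photon", 6)
  for (k_mm in c(5, 10)) {
    i0 <- ideal_fluence_map(ph, yellow)
    i1 <- ideal_fluence_map(ph, yellow, shift_spec(k_mm, "superior", "photon"))
    d <- difference_image(i1, i0)
    prof <- extract_profile(d, junction_roi())
    k_px <- k_mm * 3.6; s_px <- 1.0 * 3.6
    expect_equal(profile_fwhm(prof), oracle_band_fwhm(k_px, s_px),
                 tolerance = 1 / (k_px))
  }
})

test_that("ROI profiles are per-column means over the ROI rows", {
  cst <- field_image(matrix(3.5, 72, 72), pixel_scale = 1)
  roi <- rect_roi(-10, -10, 20, 20)
  expect_true(all(extract_profile(cst, roi)$values == 3.5))
  # single bright column: peak value = bright rows / total rows
  m <- matrix(0, 72, 72); m[30:39, 40] <- 1
  prof <- extract_profile(field_image(m, pixel_scale = 1), roi)
  expect_equal(max(prof$values), 10 / 21)  # 10 bright rows / 21 ROI rows
  expect_equal(prof$positions_px[which.max(prof$values)], 39)
  # random ROI against the double-loop oracle
  set.seed(31)
  rnd <- matrix(runif(72 * 72), 72, 72)
  img <- field_image(rnd, pixel_scale = 1)
  roi2 <- rect_roi(-7, -13, 19, 11)
  prof2 <- extract_profile(img, roi2)
  ix_rows <- (round(35.5 + -13) + 1):(round(35.5 + -2) + 1)
  ix_cols <- (round(35.5 + -7) + 1):(round(35.5 + 12) + 1)
  expect_identical(prof2$values, oracle_profile(rnd, ix_rows, ix_cols))
  # out-of-bounds ROI errors with a clipped suggestion
  expect_error(extract_profile(img, rect_roi(-50, -10, 120, 20)),
               "largest contained ROI")
})

test_that("FWHM follows its defining geometry on canonical pulses", {
  rect <- c(rep(0, 30), rep(100, 36), rep(0, 30))
  expect_equal(profile_fwhm(rect), 36)
  expect_equal(px_to_mm(profile_fwhm(rect), pixel_scale(3.6)), 10)
  tri <- c(rep(0, 20), 10 - abs(-10:10), rep(0, 20))
  expect_equal(profile_fwhm(tri), 10)
  expect_error(profile_fwhm(rep(5, 40)), "no measurable band")
})

test_that("interpolated FWHM tracks the threshold-count oracle on noisy bands", {
  set.seed(32)
  x <- seq(-54, 54)
  worst <- 0
  for (i in 1:100) {
    s <- runif(1, 7, 36); sd_px <- runif(1, 2, 5)
    v <- pnorm((x + s / 2) / sd_px) - pnorm((x - s / 2) / sd_px) +
      rnorm(length(x), 0, 0.01)
    worst <- max(worst, abs(profile_fwhm(v) - oracle_fwhm_count(v)))
  }
  expect_lte(worst, 1)
})

test_that("noiseless shifts are recovered with the expected small-shift bias", {
  m5 <- noiseless_match(5, "superior", "electron")
  expect_equal(m5$measured_matching_mm, 5, tolerance = 0.3 / 5)
  expect_equal(m5$introduced_shift_mm, -5)
  # zero-shift null: no band, measured 0 via the declared-zero path
  m0 <- noiseless_match(0, "superior", "photon")
  expect_true(m0$detectable)
  expect_equal(m0$measured_matching_mm, 0)
  expect_equal(m0$discrepancy_mm, 0)
  # monotone in shift magnitude
  meas <- vapply(c(0, 2, 5, 10), function(s)
    noiseless_match(s, "inferior", "photon")$measured_matching_mm, numeric(1))
  expect_true(all(diff(meas) > 0))
  # direction symmetry
  a <- noiseless_match(5, "superior", "photon")$measured_matching_mm
  b <- noiseless_match(5, "inferior", "photon")$measured_matching_mm
  expect_equal(a, b, tolerance = 0.05 / 5)
})

test_that("matching on black tissue is flagged not detectable", {
  black <- tissue_spec("black")
  p <- prepare_stack(simulate_condition(beam_spec("photon", 6), black,
                                        rng_seed = 41))
  e <- prepare_stack(simulate_condition(beam_spec("electron", 8), black,
                                        rng_seed = 42))
  sh <- prepare_stack(simulate_condition(
    beam_spec("photon", 6), black,
    shift = shift_spec(5, "inferior", "photon"), rng_seed = 43))
  m <- cli_match(p, e, photon_shifted = sh, preprocessed = TRUE)
  expect_false(m$detectable)
  expect_true(is.na(m$measured_matching_mm))
  expect_true(is.na(m$discrepancy_mm))
  expect_lt(m$snr, 2)
})

test_that("exactly one shifted stack may be supplied", {
  p <- simulate_condition(beam_spec("photon", 6), yellow, rng_seed = 1)
  e <- simulate_condition(beam_spec("electron", 8), yellow, rng_seed = 2)
  expect_error(cli_match(p, e, photon_shifted = p, electron_shifted = e),
               "at most one")
})

test_that("high-dose-rate oblique fields give no larger matching-error spread", {
  conv <- beam_spec("photon", 6, gantry_angle_deg = 330)
  fff <- beam_spec("photon", 6, dose_rate = 1200, fff = TRUE,
                   gantry_angle_deg = 330)
  acq <- acquisition_spec(integration_time_s = 1.0)
  d_conv <- vapply(1:12, function(k)
    noisy_match(conv, 2, "inferior", k, acq = acq)$discrepancy_mm, numeric(1))
  d_fff <- vapply(1:12, function(k)
    noisy_match(fff, 2, "inferior", 100 + k, acq = acq)$discrepancy_mm,
    numeric(1))
  expect_lte(var(d_fff), var(d_conv))
})
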