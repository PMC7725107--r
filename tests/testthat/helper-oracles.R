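# Independent brute-force oracles used across the suite. These deliberately
# re-derive each operation with plain loops so they share no code with the
# implementation under test.

# rectangular running median, anchor offsets [-k%/%2, k-1-k%/%2], replicate
# borders -- straight double loop with sort-based medians
oracle_median_filter <- function(m, kh, kw) {
  nr <- nrow(m); nc <- ncol(m)
  rlo <- -(kh %/% 2); rhi <- kh - 1 - kh %/% 2
  clo <- -(kw %/% 2); chi <- kw - 1 - kw %/% 2
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ii <- pmin(pmax(i + rlo:rhi, 1), nr)
      jj <- pmin(pmax(j + clo:chi, 1), nc)
      out[i, j] <- median(m[ii, jj])
    }
  }
  out
}

# per-pixel median across a list of matrices, elementwise loop
oracle_stack_median <- function(mats) {
  nr <- nrow(mats[[1]]); nc <- ncol(mats[[1]])
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr))
    for (j in seq_len(nc))
      out[i, j] <- median(vapply(mats, function(m) m[i, j], numeric(1)))
  out
}

# ROI column-mean profile by explicit double loop
oracle_profile <- function(m, rows, cols) {
  vapply(cols, function(j) {
    s <- 0
    for (i in rows) s <- s + m[i, j]
    s / length(rows)
  }, numeric(1))
}

# FWHM as the count of samples at or above the half level (same baseline
# rule as the implementation: median of the lowest quartile)
oracle_fwhm_count <- function(v) {
  base <- median(sort(v)[seq_len(max(1, floor(length(v) / 4)))])
  half <- base + (max(v) - base) / 2
  sum(v >= half)
}

# 20-80% edge width of a 1-D erf edge, located numerically by bisection on a
# dense numerical rendering of the edge (no closed-form constant)
oracle_edge_width_2080 <- function(sigma, lo = -50, hi = 50) {
  f <- function(x) pnorm(x / sigma)
  solve_level <- function(level) {
    a <- lo; b <- hi
    for (i in 1:200) {
      m <- (a + b) / 2
      if (f(m) < level) a <- m else b <- m
    }
    (a + b) / 2
  }
  solve_level(0.8) - solve_level(0.2)
}

# noiseless measurement helper: simulate a photon/electron pair with one
# shifted field and run the full matching chain without acquisition noise
noiseless_match <- function(shift_mm, direction, shifted_field,
                            gantry = 0, sigma_edge_mm = NULL,
                            tissue = tissue_spec("yellow")) {
  acq <- acquisition_spec(background_mean = 0, background_sd = 0,
                          sparkle_rate = 0, shot_noise_gain = 0)
  photon <- beam_spec("photon", 6, gantry_angle_deg = gantry)
  electron <- beam_spec("electron", 8)
  sim <- function(beam, shift) prepare_stack(simulate_condition(
    beam, tissue, acq, shift = shift, rng_seed = 1,
    sigma_edge_mm = sigma_edge_mm))
  p0 <- sim(photon, NULL); e0 <- sim(electron, NULL)
  sh <- if (shift_mm > 0)
    shift_spec(shift_mm, direction, shifted_field = shifted_field)
  shifted <- if (!is.null(sh))
    sim(if (shifted_field == "photon") photon else electron, sh)
  cli_match(p0, e0,
            photon_shifted = if (shifted_field == "photon") shifted,
            electron_shifted = if (shifted_field == "electron") shifted,
            preprocessed = TRUE)
}

# small noisy matching run for one scenario/seed (shared by variance tests)
noisy_match <- function(beam, shift_mm, direction, seed,
                        tissue = tissue_spec("yellow"),
                        acq = acquisition_spec()) {
  partner <- if (beam$modality == "photon") beam_spec("electron", 8) else
    beam_spec("photon", 6)
  photon <- if (beam$modality == "photon") beam else partner
  electron <- if (beam$modality == "photon") partner else beam
  p0 <- prepare_stack(simulate_condition(photon, tissue, acq, NULL,
                                         rng_seed = 1000 + seed))
  e0 <- prepare_stack(simulate_condition(electron, tissue, acq, NULL,
                                         rng_seed = 2000 + seed))
  sh <- shift_spec(shift_mm, direction, shifted_field = beam$modality)
  shifted <- prepare_stack(simulate_condition(beam, tissue, acq, sh,
                                              rng_seed = 3000 + seed))
  cli_match(p0, e0,
            photon_shifted = if (beam$modality == "photon") shifted,
            electron_shifted = if (beam$modality == "electron") shifted,
            preprocessed = TRUE)
}
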