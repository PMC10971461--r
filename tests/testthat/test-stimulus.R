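test_that("block profile is binary, symmetric and block-constant", {
  spec <- stimulus_spec(aperture_deg = 0.96, pixel_pitch_deg = 0.06,
                        seed = 11)
  pat <- generate_line_profile(spec)
  expect_length(pat$values, 16)
  expect_setequal(unique(pat$values), c(-0.3, 0.3))
  # constant within each 2-row block
  m <- matrix(pat$values, nrow = 2)
  expect_true(all(m[1, ] == m[2, ]))
})

test_that("profiles are unbiased and independent across seeds", {
  spec <- stimulus_spec()
  set.seed(101)
  grand <- replicate(300, mean(generate_line_profile(spec)$values))
  # E[mean] = 0; SE of the grand mean over the replicate means
  se <- sd(grand) / sqrt(length(grand))
  expect_lt(abs(mean(grand)), 3 * se + 1e-12)
  r <- replicate(100, {
    a <- generate_line_profile(spec)$values
    b <- generate_line_profile(spec)$values
    cor(a, b)
  })
  expect_lt(abs(mean(r)), 3 * sd(r) / sqrt(length(r)))
})

test_that("raised-cosine filter has the specified band structure", {
  spec <- stimulus_spec()
  n <- spec$n_px
  x <- (seq_len(n) - 1) * spec$pixel_pitch_deg
  gain_of <- function(f_target) {
    k <- round(f_target * n * spec$pixel_pitch_deg)
    f <- k / (n * spec$pixel_pitch_deg)   # nearest DFT frequency
    s <- ofrkit:::new_line_pattern(sin(2 * pi * f * x), spec$pixel_pitch_deg)
    out <- lowpass_raised_cosine(s, spec)
    c(f = f, gain = sqrt(mean(out$values^2)) / sqrt(mean(s$values^2)))
  }
  g_pass <- gain_of(0.2)
  expect_equal(unname(g_pass["gain"]), 1, tolerance = 1e-9)
  g_stop <- gain_of(1.0)
  expect_lt(unname(g_stop["gain"]), 1e-9)
  g_mid <- gain_of(0.5625)
  expect_equal(unname(g_mid["gain"]),
               raised_cosine_gain(unname(g_mid["f"])), tolerance = 1e-9)
  # the transition-band formula itself at the exact midpoint
  expect_identical(raised_cosine_gain(0.5625), 0.5)
  # spectral purity of a full generated pattern
  pat <- make_stimulus_pattern(stimulus_spec(seed = 5))
  sp <- abs(fft(pat$values))
  f <- pmin(0:(n - 1), n - (0:(n - 1))) / (n * spec$pixel_pitch_deg)
  expect_lt(max(sp[f >= spec$stopband_cpd]) / max(sp), 1e-6)
  raw <- lowpass_raised_cosine(generate_line_profile(stimulus_spec(seed = 5)),
                               spec)
  sp0 <- abs(fft(generate_line_profile(stimulus_spec(seed = 5))$values))
  sp1 <- abs(fft(raw$values))
  low <- f <= spec$passband_cpd & sp0 > 1e-9
  expect_lt(max(abs(sp1[low] / sp0[low] - 1)), 1e-6)
})

test_that("RMS normalization is exact, linear and idempotent", {
  p <- ofrkit:::new_line_pattern(rep(c(0.1, -0.1), 50), 0.03)
  out <- normalize_rms_contrast(p, 0.30)
  expect_equal(out$values, rep(c(0.3, -0.3), 50))
  pat <- make_stimulus_pattern(stimulus_spec(seed = 9))
  expect_equal(rms_contrast(pat), 0.30, tolerance = 1e-9)
  expect_equal(normalize_rms_contrast(pat, 0.30)$values, pat$values)
  expect_error(normalize_rms_contrast(
    ofrkit:::new_line_pattern(rep(0, 10), 0.03)), "all-zero")
})

test_that("dichoptic pairs have exact interocular correlation", {
  pat <- make_stimulus_pattern(stimulus_spec(seed = 3))
  pc <- make_dichoptic_pair(pat, 1)
  expect_identical(pc$eye_b$values, pc$eye_a$values)
  expect_equal(cor(pc$eye_a$values, pc$eye_b$values), 1)
  pa <- make_dichoptic_pair(pat, -1)
  expect_identical(pa$eye_b$values, -pa$eye_a$values)
  expect_equal(cor(pa$eye_a$values, pa$eye_b$values), -1)
  # contrast reversal is an involution
  back <- make_dichoptic_pair(pa$eye_b, -1)
  expect_identical(back$eye_b$values, pat$values)
  # both conditions share power spectrum and contrast
  expect_equal(abs(fft(pa$eye_b$values)), abs(fft(pc$eye_b$values)))
  expect_equal(rms_contrast(pa$eye_b), rms_contrast(pc$eye_b))
  expect_error(make_dichoptic_pair(pat, 0), "correlation")
})

test_that("rendered sequences have the stated frame count, drift and zero green", {
  spec <- stimulus_spec(seed = 21)
  pair <- make_dichoptic_pair(make_stimulus_pattern(spec), -1)
  up <- render_frame_sequence(pair, "up", spec)
  expect_length(up$frames, round(0.200 * 144))   # 29
  expect_true(all(vapply(up$frames, function(f) all(f[, 2] == 0),
                         logical(1))))
  expect_equal(diff(up$timestamps_ms)[1], 1000 / 144, tolerance = 1e-9)
  v_up <- estimate_drift_speed(up)
  expect_equal(v_up, 50, tolerance = 0.01 * 50)
  down <- render_frame_sequence(pair, "down", spec)
  expect_equal(estimate_drift_speed(down), -v_up, tolerance = 1e-9)
  # red carries eye A, blue carries eye B (anticorrelated here)
  f1 <- up$frames[[1]]
  expect_equal(cor(f1[, 1], f1[, 3]), -1, tolerance = 1e-9)
})

test_that("frame sequences round-trip through PNG with metadata", {
  spec <- stimulus_spec(aperture_deg = 3, seed = 2, duration_ms = 21)
  pair <- make_dichoptic_pair(make_stimulus_pattern(spec), 1)
  fs <- render_frame_sequence(pair, "up", spec)
  dir <- tempfile("fseq")
  on.exit(unlink(dir, recursive = TRUE), add = TRUE)
  paths <- write_frame_sequence(fs, dir, width_px = 8)
  pngs <- grep("png$", paths, value = TRUE)
  expect_length(pngs, length(fs$frames))
  img <- png::readPNG(pngs[1])
  expect_equal(dim(img), c(spec$n_px, 8, 3))
  expect_true(all(img[, , 2] == 0))
  meta <- yaml::read_yaml(file.path(dir, "sequence_meta.yaml"))
  expect_identical(meta$direction, "up")
})

test_that("invalid stimulus specs are rejected", {
  expect_error(stimulus_spec(passband_cpd = 0.8), "passband")
  expect_error(stimulus_spec(rms_contrast = 1.2), "rms_contrast")
  expect_error(stimulus_spec(aperture_deg = -1), "positive")
  spec <- stimulus_spec(drift_speed_deg_s = 50, refresh_hz = 1)
  pair <- make_dichoptic_pair(make_stimulus_pattern(stimulus_spec(
    aperture_deg = 1.2, seed = 1)), 1)
  sp2 <- stimulus_spec(aperture_deg = 1.2, refresh_hz = 1)
  expect_error(render_frame_sequence(pair, "up", sp2), "drift")
})
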