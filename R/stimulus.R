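#' Stimulus specification for dichoptic random-line patterns
#'
#' Describes the 1D random-line stimulus used to evoke ocular-following
#' responses: a vertical luminance profile built from two-pixel-row blocks,
#' low-pass filtered with a raised-cosine transition, normalized to a target
#' RMS contrast, and drifted vertically behind a static square aperture.
#'
#' The aperture height in pixels is `aperture_deg / pixel_pitch_deg` rounded
#' to the nearest whole number of blocks (so the block structure tiles the
#' cyclic pattern exactly); with the defaults this gives 934 rows (28.02 deg).
#'
#' @param aperture_deg Side of the static square aperture, degrees.
#' @param pixel_pitch_deg Visual angle of one pixel row, degrees (a
#'   two-row block spans `2 * pixel_pitch_deg`).
#' @param block_rows_px Pixel rows per luminance block.
#' @param passband_cpd Spatial frequency below which the low-pass filter has
#'   unit gain, cycles/deg.
#' @param stopband_cpd Spatial frequency above which the filter has zero
#'   gain, cycles/deg.
#' @param rms_contrast Target root-mean-square contrast as a fraction of the
#'   mean luminance.
#' @param mean_luminance Mean/background luminance, cd/m2 (informational;
#'   rendered frames store normalized luminance with the mean at 0.5).
#' @param drift_speed_deg_s Drift speed of the pattern, deg/s.
#' @param refresh_hz Display refresh rate, Hz.
#' @param duration_ms Motion duration, ms.
#' @param seed Optional RNG seed used when a profile is generated from this
#'   spec.
#' @return An object of class `stimulus_spec`.
#' @export
stimulus_spec <- function(aperture_deg = 28, pixel_pitch_deg = 0.03,
                          block_rows_px = 2, passband_cpd = 0.375,
                          stopband_cpd = 0.75, rms_contrast = 0.30,
                          mean_luminance = 7.0, drift_speed_deg_s = 50,
                          refresh_hz = 144, duration_ms = 200, seed = NULL) {
  if (aperture_deg <= 0 || pixel_pitch_deg <= 0 || block_rows_px < 1)
    stop("stimulus dimensions must be positive", call. = FALSE)
  if (!(passband_cpd > 0 && passband_cpd < stopband_cpd))
    stop("need 0 < passband_cpd < stopband_cpd", call. = FALSE)
  if (!(rms_contrast > 0 && rms_contrast < 1))
    stop("rms_contrast must be in (0, 1)", call. = FALSE)
  if (drift_speed_deg_s <= 0 || refresh_hz <= 0 || duration_ms <= 0)
    stop("drift speed, refresh rate and duration must be positive",
         call. = FALSE)
  block_deg <- pixel_pitch_deg * block_rows_px
  n_blocks <- round(aperture_deg / block_deg)
  if (n_blocks < 2)
    stop("aperture too small for the block size", call. = FALSE)
  spec <- list(
    aperture_deg = aperture_deg, pixel_pitch_deg = pixel_pitch_deg,
    block_rows_px = as.integer(block_rows_px),
    passband_cpd = passband_cpd, stopband_cpd = stopband_cpd,
    rms_contrast = rms_contrast, mean_luminance = mean_luminance,
    drift_speed_deg_s = drift_speed_deg_s, refresh_hz = refresh_hz,
    duration_ms = duration_ms, seed = seed,
    n_blocks = as.integer(n_blocks),
    n_px = as.integer(n_blocks * block_rows_px))
  class(spec) <- "stimulus_spec"
  spec
}

new_line_pattern <- function(values, pitch_deg, correlation_tag = NA_character_,
                             pattern_id = NA_character_) {
  structure(list(values = as.numeric(values), pitch_deg = pitch_deg,
                 correlation_tag = correlation_tag, pattern_id = pattern_id),
            class = "line_pattern")
}

#' Generate a binary random-line luminance profile
#'
#' Assigns a high or low value (symmetric about the mean, i.e. +c or -c in
#' mean-relative units) independently to each block of consecutive pixel
#' rows. The profile is the raw, unfiltered stimulus; apply
#' [lowpass_raised_cosine()] and [normalize_rms_contrast()] to obtain the
#' displayed pattern.
#'
#' @param spec A [stimulus_spec()].
#' @return A `line_pattern` with mean-relative values in `{-c, +c}` where
#'   `c = spec$rms_contrast`.
#' @export
generate_line_profile <- function(spec) {
  stopifnot(inherits(spec, "stimulus_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  signs <- sample(c(-1, 1), spec$n_blocks, replace = TRUE)
  values <- rep(signs * spec$rms_contrast, each = spec$block_rows_px)
  new_line_pattern(values, spec$pixel_pitch_deg,
                   pattern_id = sprintf("p%08x",
                                        sample.int(.Machine$integer.max, 1L)))
}

#' Raised-cosine low-pass gain
#'
#' Unit gain at and below the passband edge, zero at and above the stopband
#' edge, half-cosine transition in between:
#' `G(f) = (1 + cos(pi * (f - f_pass) / (f_stop - f_pass))) / 2`.
#'
#' @param f Spatial frequency, cycles/deg (vectorized).
#' @param passband_cpd,stopband_cpd Transition band edges, cycles/deg.
#' @return Gain values in `[0, 1]`.
#' @export
raised_cosine_gain <- function(f, passband_cpd = 0.375, stopband_cpd = 0.75) {
  f <- abs(f)
  g <- 0.5 * (1 + cos(pi * (f - passband_cpd) / (stopband_cpd - passband_cpd)))
  g[f <= passband_cpd] <- 1
  g[f >= stopband_cpd] <- 0
  g
}

#' Low-pass filter a line pattern in the frequency domain
#'
#' Applies the raised-cosine gain to the discrete spectrum of the cyclic
#' profile (circular convolution). The pattern wraps behind the aperture
#' during drift, so cyclic filtering has no edge artifacts and commutes with
#' cyclic shifts.
#'
#' @param pattern A `line_pattern` sampled at `spec$pixel_pitch_deg`.
#' @param spec A [stimulus_spec()] supplying the band edges.
#' @return The filtered `line_pattern`.
#' @export
lowpass_raised_cosine <- function(pattern, spec) {
  stopifnot(inherits(pattern, "line_pattern"), inherits(spec, "stimulus_spec"))
  n <- length(pattern$values)
  if (n < 4) stop("pattern shorter than filter support", call. = FALSE)
  # two-sided frequency axis of the length-n DFT, cycles/deg
  k <- seq_len(n) - 1L
  f <- pmin(k, n - k) / (n * pattern$pitch_deg)
  g <- raised_cosine_gain(f, spec$passband_cpd, spec$stopband_cpd)
  out <- Re(stats::fft(stats::fft(pattern$values) * g, inverse = TRUE)) / n
  pattern$values <- out
  pattern
}

#' Root-mean-square contrast of a line pattern
#'
#' RMS of the mean-relative luminance values (the convention for
#' non-periodic noise stimuli, where contrast is expressed relative to the
#' mean luminance).
#'
#' @param pattern A `line_pattern`.
#' @return RMS contrast as a fraction.
#' @export
rms_contrast <- function(pattern) {
  stopifnot(inherits(pattern, "line_pattern"))
  sqrt(mean(pattern$values^2))
}

#' Scale a line pattern to a target RMS contrast
#'
#' @param pattern A non-constant `line_pattern`.
#' @param target Target RMS contrast (fraction of mean luminance).
#' @return The linearly rescaled `line_pattern`; idempotent.
#' @export
normalize_rms_contrast <- function(pattern, target = 0.30) {
  stopifnot(inherits(pattern, "line_pattern"))
  r <- rms_contrast(pattern)
  if (r == 0) stop("cannot normalize an all-zero pattern", call. = FALSE)
  pattern$values <- pattern$values * (target / r)
  pattern
}

#' Build a dichoptic pair with a given interocular correlation
#'
#' The correlated condition (+1) shows the identical pattern to both eyes;
#' the anticorrelated condition (-1) shows one eye the contrast-reversed
#' (negated) pattern. Both members share the same power spectrum and RMS
#' contrast and differ only in interocular correlation.
#'
#' @param pattern A normalized `line_pattern` (shown to eye A).
#' @param correlation `+1` or `-1`.
#' @return A `dichoptic_pair` with fields `eye_a`, `eye_b`,
#'   `interocular_correlation`.
#' @export
make_dichoptic_pair <- function(pattern, correlation) {
  stopifnot(inherits(pattern, "line_pattern"))
  if (!(identical(correlation, 1) || identical(correlation, -1) ||
        identical(correlation, 1L) || identical(correlation, -1L)))
    stop("interocular correlation must be +1 or -1", call. = FALSE)
  eye_a <- pattern
  eye_a$correlation_tag <- "left_eye"
  eye_b <- pattern
  eye_b$values <- pattern$values * as.numeric(correlation)
  eye_b$correlation_tag <- "right_eye"
  structure(list(eye_a = eye_a, eye_b = eye_b,
                 interocular_correlation = as.numeric(correlation)),
            class = "dichoptic_pair")
}

# cyclic linear interpolation of v at fractional sample positions pos (0-based)
cyclic_interp <- function(v, pos) {
  n <- length(v)
  pos <- pos %% n
  i0 <- floor(pos)
  w <- pos - i0
  (1 - w) * v[(i0 %% n) + 1L] + w * v[((i0 + 1L) %% n) + 1L]
}

#' Render a drifting dichoptic frame sequence
#'
#' Renders `round(duration_ms / 1000 * refresh_hz)` frames in which the 1D
#' pattern drifts vertically behind the static aperture. The stimulus is
#' constant along the horizontal axis, so each frame is stored as its
#' vertical luminance profile per color channel (`n_px x 3` matrix,
#' columns red/green/blue, green identically zero); [write_frame_sequence()]
#' expands profiles to full 2D images on demand. The red channel carries
#' `pair$eye_a`, the blue channel `pair$eye_b`; values are normalized
#' luminance `0.5 * (1 + contrast)`.
#'
#' Drift is rendered by cyclically shifting a supersampled copy of the
#' profile by an integer number of supersamples per frame, with the
#' fractional residual accumulated across frames so the mean speed is exact
#' to within one part in `supersample * n_px`.
#'
#' @param pair A [make_dichoptic_pair()] result.
#' @param direction `"up"` or `"down"`.
#' @param spec A [stimulus_spec()].
#' @param supersample Integer supersampling factor for subpixel drift.
#' @return A `frame_sequence` with fields `frames` (list of profile
#'   matrices), `direction`, `timestamps_ms`, `spec`.
#' @export
render_frame_sequence <- function(pair, direction = c("up", "down"), spec,
                                  supersample = 8L) {
  direction <- match.arg(direction)
  stopifnot(inherits(pair, "dichoptic_pair"), inherits(spec, "stimulus_spec"))
  n <- length(pair$eye_a$values)
  n_frames <- round(spec$duration_ms / 1000 * spec$refresh_hz)
  shift_px <- spec$drift_speed_deg_s / spec$refresh_hz / spec$pixel_pitch_deg
  if (shift_px >= n)
    stop("per-frame drift exceeds the pattern height", call. = FALSE)
  s <- as.integer(supersample)
  # supersampled profiles (cyclic linear interpolation of the filtered,
  # band-limited pattern)
  pos <- (seq_len(n * s) - 1L) / s
  a_ss <- cyclic_interp(pair$eye_a$values, pos)
  b_ss <- cyclic_interp(pair$eye_b$values, pos)
  # frame k shows pattern sample (row + shift): a positive shift moves
  # content toward smaller row indices, i.e. upward on the display
  sgn <- if (direction == "up") 1 else -1
  frames <- vector("list", n_frames)
  cols <- seq(1L, n * s, by = s)
  for (k in seq_len(n_frames)) {
    sh <- sgn * round((k - 1L) * shift_px * s)
    idx <- ((cols - 1L + sh) %% (n * s)) + 1L
    red <- pmin(pmax(0.5 * (1 + a_ss[idx]), 0), 1)
    blue <- pmin(pmax(0.5 * (1 + b_ss[idx]), 0), 1)
    frames[[k]] <- cbind(red = red, green = rep(0, n), blue = blue)
  }
  structure(list(frames = frames, direction = direction,
                 timestamps_ms = (seq_len(n_frames) - 1L) / spec$refresh_hz * 1000,
                 spec = spec),
            class = "frame_sequence")
}

# signed circular shift (in samples) of b relative to a, by FFT
# cross-correlation with parabolic sub-sample peak interpolation
circular_shift_estimate <- function(a, b) {
  n <- length(a)
  a <- a - mean(a); b <- b - mean(b)
  cc <- Re(stats::fft(stats::fft(a) * Conj(stats::fft(b)), inverse = TRUE)) / n
  i <- which.max(cc)
  ip <- if (i == n) 1L else i + 1L
  im <- if (i == 1L) n else i - 1L
  denom <- cc[im] - 2 * cc[i] + cc[ip]
  frac <- if (denom == 0) 0 else 0.5 * (cc[im] - cc[ip]) / denom
  lag <- (i - 1L) + frac
  if (lag > n / 2) lag <- lag - n
  lag
}

#' Estimate the drift speed of a rendered frame sequence
#'
#' Measures the cyclic vertical shift between consecutive frames by circular
#' cross-correlation (with parabolic sub-sample interpolation), averages the
#' per-frame shifts, and converts to deg/s via the pixel pitch and refresh
#' rate. Positive speeds indicate upward drift.
#'
#' @param fseq A [render_frame_sequence()] result.
#' @param channel `"red"` or `"blue"`.
#' @return Signed drift speed, deg/s.
#' @export
estimate_drift_speed <- function(fseq, channel = c("red", "blue")) {
  channel <- match.arg(channel)
  stopifnot(inherits(fseq, "frame_sequence"))
  ch <- if (channel == "red") 1L else 3L
  nf <- length(fseq$frames)
  if (nf < 2) stop("need at least two frames", call. = FALSE)
  shifts <- vapply(seq_len(nf - 1L), function(k) {
    # cross-correlation peaks at the pattern-sample shift between frames;
    # positive = content moved up
    circular_shift_estimate(fseq$frames[[k]][, ch],
                            fseq$frames[[k + 1L]][, ch])
  }, numeric(1))
  mean(shifts) * fseq$spec$pixel_pitch_deg * fseq$spec$refresh_hz
}

#' Generate a complete displayed pattern from a spec
#'
#' Convenience wrapper: random block profile, raised-cosine low-pass, RMS
#' normalization.
#'
#' @param spec A [stimulus_spec()].
#' @return A normalized, filtered `line_pattern`.
#' @export
make_stimulus_pattern <- function(spec) {
  normalize_rms_contrast(
    lowpass_raised_cosine(generate_line_profile(spec), spec),
    spec$rms_contrast)
}

#' Write a frame sequence as PNG images plus a metadata sidecar
#'
#' Expands each stored profile to a `n_px x width_px` RGB image (green
#' channel zero) and writes `frame_000.png`, ... along with
#' `sequence_meta.yaml` recording the spec, direction and seed.
#'
#' @param fseq A `frame_sequence`.
#' @param dir Output directory (created if needed).
#' @param width_px Image width; defaults to the pattern height.
#' @return Invisibly, the written file paths.
#' @export
write_frame_sequence <- function(fseq, dir, width_px = NULL) {
  stopifnot(inherits(fseq, "frame_sequence"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  n <- nrow(fseq$frames[[1]])
  if (is.null(width_px)) width_px <- n
  paths <- character(0)
  for (k in seq_along(fseq$frames)) {
    prof <- fseq$frames[[k]]
    img <- array(0, dim = c(n, width_px, 3))
    for (ch in 1:3) img[, , ch] <- matrix(prof[, ch], n, width_px)
    p <- file.path(dir, sprintf("frame_%03d.png", k - 1L))
    png::writePNG(img, p)
    paths <- c(paths, p)
  }
  meta <- file.path(dir, "sequence_meta.yaml")
  yaml::write_yaml(list(direction = fseq$direction,
                        timestamps_ms = as.numeric(fseq$timestamps_ms),
                        spec = unclass(fseq$spec)), meta)
  invisible(c(paths, meta))
}
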