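# Independent oracles and small fixtures shared across the test files.
# These are deliberately written as brute-force references, separate from
# the package's implementation paths.

# Step-by-step reference for the iterative robust-MAD exclusion: works on a
# shrinking vector of values (not a mask) with medians computed by explicit
# sorting, and returns the sorted multiset of kept values.
oracle_mad_filter <- function(x, k = 3, degenerate_keep_median = TRUE) {
  med_by_sort <- function(v) {
    v <- sort(v)
    n <- length(v)
    if (n %% 2 == 1) v[(n + 1) / 2] else (v[n / 2] + v[n / 2 + 1]) / 2
  }
  v <- x[is.finite(x)]
  repeat {
    m <- med_by_sort(v)
    s <- 1.4826 * med_by_sort(abs(v - m))
    keep <- if (s == 0) v == m else abs(v - m) <= k * s
    if (all(keep)) return(sort(v))
    v <- v[keep]
  }
}

# Exact two-sided Mann-Whitney p by full enumeration of rank assignments.
oracle_exact_mw_p <- function(x, y) {
  nx <- length(x)
  r <- rank(c(x, y))
  u_obs <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  combos <- utils::combn(length(r), nx)
  us <- apply(combos, 2, function(idx) sum(r[idx]) - nx * (nx + 1) / 2)
  mu <- nx * length(y) / 2
  mean(abs(us - mu) >= abs(u_obs - mu))
}

# Textbook pooled-variance two-sided t-test p.
oracle_pooled_t_p <- function(x, y) {
  nx <- length(x); ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  tt <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / nx + 1 / ny))
  2 * pt(-abs(tt), nx + ny - 2)
}

# Compact camera geometry used throughout the frame-tier tests; small
# frames keep rendering and labelling fast without changing the tracker's
# accuracy regime (features stay tens of pixels wide).
test_camera <- function(noise_sd = 0) {
  camera_model(frame_size_px = c(320, 280), pupil_radius_px = 18,
               iris_radius_px = 45, marker_radius_px = 7,
               px_per_deg = 40, noise_sd = noise_sd,
               pupil_center = c(200, 150), marker_center = c(70, 70))
}

test_tracker <- function() {
  list(pupil_min_area = 400, pupil_max_area = 1e4,
       marker_min_area = 40, marker_max_area = 600,
       exclude_radius = 80)
}

# Render a bare eye frame via the package's internal renderer.
render_test_frame <- function(cam, pupil_xy, marker_xy, blink = FALSE) {
  ofrkit:::render_eye_frame(cam, pupil_xy, marker_xy, blink = blink)
}
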