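test_that("eye-in-head subtraction and unit conversion are exact", {
  tab <- simulate_trial_table(subject_model(n_trials_per_cell = 2, seed = 4,
                                            saccade_rate = 0,
                                            head_jump_rate = 0,
                                            blink_rate = 0))$trials
  tab$dy_pupil_mov[1] <- 12.0
  tab$dy_marker_mov[1] <- 0
  et <- compute_eye_in_head(tab, px_per_deg = 40)
  expect_equal(et$eye_mov[1], 0.30)
  # pure head motion: pupil follows the marker, eye-in-head is zero
  tab2 <- tab
  for (ep in c("fix", "mov")) {
    tab2[[paste0("dy_pupil_", ep)]] <- tab2[[paste0("dy_marker_", ep)]]
    tab2[[paste0("dx_pupil_", ep)]] <- tab2[[paste0("dx_marker_", ep)]]
  }
  et2 <- compute_eye_in_head(tab2, 40)
  expect_true(all(abs(c(et2$eye_fix, et2$eye_mov)) < 1e-12))
  # schema errors
  expect_error(compute_eye_in_head(tab[, c("trial_id", "dy_marker_fix")], 40),
               "columns")
  expect_error(compute_eye_in_head(tab, -1))
})

test_that("iterative robust filter matches hand-computed and oracle results", {
  cfg <- qc_config()
  x <- c(0.1, 0.12, 0.11, 0.09, 5.0)
  keep <- robust_outlier_filter(x, cfg)
  expect_identical(keep, c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # all identical: degenerate rule keeps everything
  expect_true(all(robust_outlier_filter(rep(2, 5), cfg)))
  # degenerate rule: zero MAD keeps only values at the median
  expect_identical(robust_outlier_filter(c(1, 1, 1, 1, 3), cfg),
                   c(TRUE, TRUE, TRUE, TRUE, FALSE))
  # two-cluster pathological input against the brute-force oracle
  y <- c(rep(0, 6), rep(10, 4), 100)
  expect_identical(sort(y[robust_outlier_filter(y, cfg)]),
                   oracle_mad_filter(y))
  expect_error(robust_outlier_filter(c(1, 2), cfg), "3 finite")
})

test_that("robust filter agrees with the step-by-step oracle on random input", {
  cfg <- qc_config()
  set.seed(12)
  for (i in 1:200) {
    n <- sample(3:15, 1)
    x <- rnorm(n)
    if (runif(1) < 0.5) x <- c(x, rnorm(sample(1:3, 1), 0, 20))
    if (runif(1) < 0.2) x <- round(x)   # induce ties / zero-MAD cases
    expect_identical(sort(x[robust_outlier_filter(x, cfg)]),
                     oracle_mad_filter(x))
  }
})

test_that("QC excludes exactly the injected fixation saccades", {
  # clean fixation noise drawn from a bounded (uniform) distribution: for
  # Uniform(-a, a) the robust SD is 1.4826 * a / 2 = 0.74 a, so 3 robust
  # SDs exceed the support and no clean trial can be flagged; the injected
  # offsets are far outside. This makes the expected exclusion set exact.
  set.seed(9)
  n <- 120
  cond <- rep(c("correlated", "anticorrelated"), each = n / 2)
  dirn <- rep(c("up", "down"), n / 2)
  a <- 0.05
  et <- data.frame(
    trial_id = sprintf("T%03d", 1:n), condition = cond, direction = dirn,
    eye_fix = runif(n, -a, a), eye_mov = runif(n, -0.3, 0.3),
    eye_fix_x = runif(n, -a, a), eye_mov_x = runif(n, -a, a),
    head_fix = runif(n, -0.4, 0.4), head_mov = runif(n, -0.4, 0.4),
    head_fix_x = runif(n, -0.4, 0.4), head_mov_x = runif(n, -0.4, 0.4),
    excluded_reason = "none", stringsAsFactors = FALSE)
  injected <- sample(n, n / 5)
  et$eye_fix[injected] <- et$eye_fix[injected] +
    sample(c(-1, 1), length(injected), TRUE) * 10 * a
  res <- apply_qc(et, qc_config(px_per_deg = 40))
  expect_setequal(which(res$trials$excluded_reason == "fix_eye"), injected)
  expect_equal(res$report$exclusion_fraction, length(injected) / n)
  # idempotence: re-running on the kept set excludes nothing
  res2 <- apply_qc(res$kept, qc_config(px_per_deg = 40))
  expect_equal(res2$report$n_excluded, 0)
  expect_identical(res2$kept$trial_id, res$kept$trial_id)
})

test_that("QC is order-invariant and scale-equivariant", {
  s <- simulate_trial_table(subject_model(seed = 19, saccade_rate = 0.15,
                                          head_jump_rate = 0.1,
                                          blink_rate = 0.05))
  et <- compute_eye_in_head(s$trials, 40)
  cfg <- qc_config(px_per_deg = 40)
  res <- apply_qc(et, cfg)
  perm <- sample(nrow(et))
  res_p <- apply_qc(et[perm, ], cfg)
  expect_setequal(res_p$kept$trial_id, res$kept$trial_id)
  et_s <- et
  for (col in c("eye_fix", "eye_fix_x", "head_fix", "head_fix_x",
                "head_mov", "head_mov_x"))
    et_s[[col]] <- et_s[[col]] * 7
  res_s <- apply_qc(et_s, cfg)
  expect_identical(res_s$kept$trial_id, res$kept$trial_id)
  # accounting identity and blink propagation
  expect_equal(res$report$exclusion_fraction,
               1 - res$report$n_kept / res$report$n_total)
  expect_equal(res$report$reason_counts$blink, sum(s$trials$blink_flag))
  expect_error(apply_qc(et[0, ], cfg), "empty")
})

test_that("contaminated sessions land in a plausible exclusion range", {
  # with blink + saccade + head-jump rates like the clinical recordings,
  # total exclusions should fall in a 5-45% band
  s <- simulate_trial_table(subject_model(seed = 33, saccade_rate = 0.1,
                                          head_jump_rate = 0.05,
                                          blink_rate = 0.1))
  et <- compute_eye_in_head(s$trials, 40)
  res <- apply_qc(et, qc_config(px_per_deg = 40))
  expect_gt(res$report$exclusion_fraction, 0.05)
  expect_lt(res$report$exclusion_fraction, 0.45)
})
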