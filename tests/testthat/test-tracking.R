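test_that("pupil and marker centers are recovered to subpixel accuracy", {
  cam <- test_camera()
  f <- render_test_frame(cam, c(200.25, 150.75), c(70.5, 70.5))
  p <- detect_pupil(f, min_area = 400, max_area = 1e4)
  expect_true(p$valid)
  expect_lt(abs(p$x - 200.25), 0.05)
  expect_lt(abs(p$y - 150.75), 0.05)
  m <- detect_marker(f, min_area = 40, max_area = 600, pupil = p,
                     exclude_radius = 80)
  expect_true(m$valid)
  expect_lt(abs(m$x - 70.5), 0.05)
  expect_lt(abs(m$y - 70.5), 0.05)
  expect_true(p$quality >= 0 && p$quality <= 1)
})

test_that("detection failures are reported, never raised", {
  cam <- test_camera()
  blank <- matrix(cam$background_intensity, 280, 320)
  expect_false(detect_pupil(blank, min_area = 400, max_area = 1e4)$valid)
  fb <- render_test_frame(cam, cam$pupil_center, cam$marker_center,
                          blink = TRUE)
  expect_false(detect_pupil(fb, min_area = 400, max_area = 1e4)$valid)
  # marker absent
  f <- render_test_frame(cam, cam$pupil_center, c(-100, -100))
  p <- detect_pupil(f, min_area = 400, max_area = 1e4)
  expect_false(detect_marker(f, min_area = 40, max_area = 600, pupil = p,
                             exclude_radius = 80)$valid)
  # marker partially out of frame
  f2 <- render_test_frame(cam, cam$pupil_center, c(3, 70))
  p2 <- detect_pupil(f2, min_area = 400, max_area = 1e4)
  expect_false(detect_marker(f2, min_area = 40, max_area = 600, pupil = p2,
                             exclude_radius = 80)$valid)
})

test_that("equal dark blobs are tie-broken deterministically with a penalty", {
  img <- matrix(0.8, 120, 120)
  img <- ofrkit:::add_disc(img, 30, 30, 10, 0.05, soft = 0)
  img <- ofrkit:::add_disc(img, 90, 80, 10, 0.05, soft = 0)
  one <- matrix(0.8, 120, 120)
  one <- ofrkit:::add_disc(one, 30, 30, 10, 0.05, soft = 0)
  single <- detect_pupil(one, min_area = 100, max_area = 1e4)
  p <- detect_pupil(img, min_area = 100, max_area = 1e4)
  expect_true(p$valid)
  # lower centroid y wins (the blob at y = 30)
  expect_lt(abs(p$y - 30), 0.5)
  expect_lt(abs(p$x - 30), 0.5)
  expect_lt(p$quality, single$quality)
})

test_that("measured displacements are translation-equivariant", {
  cam <- test_camera()
  shift_img <- function(img, a, b) {
    # integer roll: +a cols right, +b rows down
    h <- nrow(img); w <- ncol(img)
    img[((seq_len(h) - 1 - b) %% h) + 1, ((seq_len(w) - 1 - a) %% w) + 1]
  }
  f0 <- render_test_frame(cam, c(200.3, 150.6), c(70.2, 70.8))
  f1 <- shift_img(f0, 4, -3)
  p0 <- detect_pupil(f0, min_area = 400, max_area = 1e4)
  p1 <- detect_pupil(f1, min_area = 400, max_area = 1e4)
  expect_lt(abs((p1$x - p0$x) - 4), 0.02)
  expect_lt(abs((p1$y - p0$y) - (-3)), 0.02)
})

test_that("trial measurement recovers known shifts and flags discards", {
  cam <- test_camera()
  tpl <- function(frames, id = "T1")
    structure(list(frames = frames, trial_id = id, condition = "correlated",
                   direction = "up", timestamps_ms = c(0, 80, 160)),
              class = "frame_triplet")
  base <- render_test_frame(cam, cam$pupil_center, cam$marker_center)
  # static triplet: all displacements zero
  m0 <- measure_trial(tpl(list(base, base, base)), test_tracker())
  expect_false(m0$blink_flag || m0$oof_flag)
  expect_equal(unlist(m0[grep("^d[xy]_", names(m0))]),
               setNames(rep(0, 8), names(m0)[grep("^d[xy]_", names(m0))]))
  # known subpixel shifts per epoch (image y down = negative analysis dy)
  f1 <- render_test_frame(cam, cam$pupil_center + c(0.4, 1.3),
                          cam$marker_center + c(0.4, 1.3))
  f2 <- render_test_frame(cam, cam$pupil_center + c(0.4 - 0.7, 1.3 - 5.2),
                          cam$marker_center + c(0.4, 1.3))
  m1 <- measure_trial(tpl(list(base, f1, f2)), test_tracker())
  expect_equal(m1$dy_pupil_fix, -1.3, tolerance = 0.05)
  expect_equal(m1$dx_pupil_fix, 0.4, tolerance = 0.05)
  expect_equal(m1$dy_pupil_mov, 5.2, tolerance = 0.05)
  expect_equal(m1$dx_pupil_mov, -0.7, tolerance = 0.05)
  expect_equal(m1$dy_marker_mov, 0, tolerance = 0.05)
  # blink at t2
  fb <- render_test_frame(cam, cam$pupil_center, cam$marker_center,
                          blink = TRUE)
  mb <- measure_trial(tpl(list(base, f1, fb)), test_tracker())
  expect_true(mb$blink_flag)
  expect_true(is.na(mb$dy_pupil_mov))
  # marker out of frame at t1
  fo <- render_test_frame(cam, cam$pupil_center, c(2, 70))
  mo <- measure_trial(tpl(list(base, fo, base)), test_tracker())
  expect_true(mo$oof_flag)
  expect_false(mo$blink_flag)
  # mismatched frame sizes
  small <- base[1:100, 1:100]
  expect_error(measure_trial(tpl(list(base, base, small))), "dimensions")
})

test_that("subpixel accuracy degrades gracefully with pixel noise", {
  cam <- test_camera()
  set.seed(31)
  rmse_at <- function(noise_sd, n = 20) {
    camn <- cam; camn$noise_sd <- noise_sd
    e <- replicate(n, {
      sh <- runif(2, -2, 2)
      f0 <- render_test_frame(camn, camn$pupil_center, camn$marker_center)
      f1 <- render_test_frame(camn, camn$pupil_center + sh,
                              camn$marker_center)
      p0 <- detect_pupil(f0, min_area = 400, max_area = 1e4)
      p1 <- detect_pupil(f1, min_area = 400, max_area = 1e4)
      c(p1$x - p0$x - sh[1], p1$y - p0$y - sh[2])
    })
    sqrt(mean(e^2))
  }
  r <- vapply(c(0, 0.01, 0.03), rmse_at, numeric(1))
  expect_lt(r[1], 0.05)
  expect_true(all(diff(r) > 0))   # monotone degradation
})

test_that("discard accounting matches the generated contamination exactly", {
  cam <- test_camera()
  m <- subject_model(saccade_rate = 0, head_jump_rate = 0, blink_rate = 0.3,
                     movement_noise_sd_deg = 0.05,
                     fixation_noise_sd_deg = 0.02, head_noise_sd_px = 0.3,
                     n_trials_per_cell = 3, seed = 77)
  s <- simulate_trial_table(m)
  tab <- track_session(render_session_frames(s, cam), test_tracker())
  expect_identical(tab$blink_flag, s$trials$blink_flag)
  expect_equal(mean(tab$blink_flag | tab$oof_flag),
               mean(s$truth$contaminated == "blink"))
})
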