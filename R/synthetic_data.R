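#' Subject model for synthetic OFR sessions
#'
#' Parameters of a simulated observer. The movement-epoch vertical eye
#' displacement for an upward-drifting stimulus is drawn from
#' `Normal(+A/2, sigma)` and for downward from `Normal(-A/2, sigma)`, where
#' `A` is the condition's true OFR amplitude, so the expected
#' up-minus-down difference equals `A`. Fixation-epoch displacements are
#' zero-mean noise. A stereo-deficient observer is modelled by setting the
#' anticorrelated amplitude equal to the correlated one.
#'
#' @param ofr_correlated_deg True OFR amplitude for correlated stimuli, deg.
#' @param ofr_anticorrelated_deg True amplitude for anticorrelated stimuli,
#'   deg (equal to `ofr_correlated_deg` for a stereo-deficient subject).
#' @param movement_noise_sd_deg SD of the movement-epoch vertical eye
#'   displacement about its condition mean, deg.
#' @param fixation_noise_sd_deg SD of fixation-epoch eye displacement, deg.
#' @param head_noise_sd_px SD of head-marker displacement per epoch, px.
#' @param saccade_rate Fraction of trials contaminated by a large
#'   fixation-epoch eye movement (offset 10 x fixation noise SD).
#' @param head_jump_rate Fraction of trials with a large head movement
#'   (offset 10 x head noise SD, in a random epoch).
#' @param blink_rate Fraction of trials with an occluded/missing pupil.
#' @param n_trials_per_cell Trials per condition x direction cell.
#' @param px_per_deg Camera scale factor: pupil-image translation per degree
#'   of eye rotation.
#' @param seed Optional RNG seed.
#' @return An object of class `subject_model`.
#' @export
subject_model <- function(ofr_correlated_deg = 0.4,
                          ofr_anticorrelated_deg = 0.15,
                          movement_noise_sd_deg = 0.15,
                          fixation_noise_sd_deg = 0.05,
                          head_noise_sd_px = 0.5,
                          saccade_rate = 0.1, head_jump_rate = 0.05,
                          blink_rate = 0.1, n_trials_per_cell = 30,
                          px_per_deg = 40, seed = NULL) {
  stopifnot(ofr_correlated_deg >= 0, ofr_anticorrelated_deg >= 0,
            movement_noise_sd_deg >= 0, fixation_noise_sd_deg >= 0,
            head_noise_sd_px >= 0, px_per_deg > 0)
  rates <- c(saccade_rate, head_jump_rate, blink_rate)
  if (any(rates < 0 | rates > 1))
    stop("contamination rates must be in [0, 1]", call. = FALSE)
  if (sum(rates) > 1)
    stop("contamination rates must sum to at most 1", call. = FALSE)
  structure(list(ofr_correlated_deg = ofr_correlated_deg,
                 ofr_anticorrelated_deg = ofr_anticorrelated_deg,
                 movement_noise_sd_deg = movement_noise_sd_deg,
                 fixation_noise_sd_deg = fixation_noise_sd_deg,
                 head_noise_sd_px = head_noise_sd_px,
                 saccade_rate = saccade_rate,
                 head_jump_rate = head_jump_rate,
                 blink_rate = blink_rate,
                 n_trials_per_cell = as.integer(n_trials_per_cell),
                 px_per_deg = px_per_deg, seed = seed),
            class = "subject_model")
}

#' Camera model for synthetic near-IR frame rendering
#'
#' Geometry and photometry of the simulated eye-tracking camera. Intensities
#' are normalized luminance in `[0, 1]`; the pupil must be darker than the
#' iris and the head marker darker than the background (dark-pupil,
#' dark-marker imaging).
#'
#' @param frame_size_px `c(width, height)` of the camera frame, px.
#' @param pupil_radius_px Pupil radius, px.
#' @param pupil_intensity,iris_intensity,marker_intensity,background_intensity
#'   Normalized intensities.
#' @param iris_radius_px Iris radius, px.
#' @param marker_radius_px Head-marker radius, px.
#' @param px_per_deg Pupil-image translation per degree of eye rotation.
#' @param noise_sd Additive Gaussian pixel noise SD.
#' @param pupil_center,marker_center Base `c(x, y)` image positions
#'   (0-based, continuous px); defaults place the pupil right of center and
#'   the marker in the upper-left region.
#' @return An object of class `camera_model`.
#' @export
camera_model <- function(frame_size_px = c(2448, 2048),
                         pupil_radius_px = 60, iris_radius_px = 150,
                         pupil_intensity = 0.05, iris_intensity = 0.35,
                         marker_radius_px = 20, marker_intensity = 0.05,
                         background_intensity = 0.7,
                         px_per_deg = 40, noise_sd = 0,
                         pupil_center = NULL, marker_center = NULL) {
  stopifnot(length(frame_size_px) == 2, all(frame_size_px > 0),
            px_per_deg > 0, pupil_radius_px > 0, marker_radius_px > 0)
  if (pupil_intensity >= iris_intensity)
    stop("pupil must be darker than iris", call. = FALSE)
  if (marker_intensity >= background_intensity)
    stop("marker must be darker than background", call. = FALSE)
  if (is.null(pupil_center))
    pupil_center <- c(0.62 * frame_size_px[1], 0.55 * frame_size_px[2])
  if (is.null(marker_center))
    marker_center <- c(0.22 * frame_size_px[1], 0.28 * frame_size_px[2])
  structure(list(frame_size_px = as.integer(frame_size_px),
                 pupil_radius_px = pupil_radius_px,
                 iris_radius_px = iris_radius_px,
                 pupil_intensity = pupil_intensity,
                 iris_intensity = iris_intensity,
                 marker_radius_px = marker_radius_px,
                 marker_intensity = marker_intensity,
                 background_intensity = background_intensity,
                 px_per_deg = px_per_deg, noise_sd = noise_sd,
                 pupil_center = pupil_center, marker_center = marker_center),
            class = "camera_model")
}

trial_table_columns <- c("trial_id", "condition", "direction",
                         "dy_pupil_fix", "dy_pupil_mov",
                         "dy_marker_fix", "dy_marker_mov",
                         "dx_pupil_fix", "dx_pupil_mov",
                         "dx_marker_fix", "dx_marker_mov",
                         "blink_flag", "oof_flag")

#' Simulate a trial table of per-trial displacements
#'
#' Generates one session: 2 conditions x 2 directions x
#' `n_trials_per_cell` trials in randomized order, as pupil and head-marker
#' displacements per epoch (camera pixels, analysis convention: positive
#' vertical = upward). Pupil displacement is marker displacement plus eye
#' rotation scaled by `px_per_deg`. Contaminated trials get either an added
#' fixation-epoch eye offset of 10 x the fixation noise SD (saccade), an
#' added head offset of 10 x the head noise SD in a random epoch (head
#' jump), or a missing-pupil flag (blink). Ground truth is returned
#' alongside.
#'
#' @param model A [subject_model()].
#' @return A list of class `ofr_session`: `trials` (data frame with columns
#'   `trial_id, condition, direction, dy_pupil_fix, dy_pupil_mov,
#'   dy_marker_fix, dy_marker_mov, dx_*, blink_flag, oof_flag`) and `truth`
#'   (per-trial true displacements and contamination labels).
#' @export
simulate_trial_table <- function(model) {
  stopifnot(inherits(model, "subject_model"))
  if (model$n_trials_per_cell < 2)
    stop("need at least 2 trials per cell", call. = FALSE)
  if (!is.null(model$seed)) set.seed(model$seed)
  n <- model$n_trials_per_cell
  cells <- expand.grid(condition = c("correlated", "anticorrelated"),
                       direction = c("up", "down"),
                       rep = seq_len(n), stringsAsFactors = FALSE)
  nt <- nrow(cells)
  ord <- sample.int(nt)
  cells <- cells[ord, , drop = FALSE]
  amp <- ifelse(cells$condition == "correlated",
                model$ofr_correlated_deg, model$ofr_anticorrelated_deg)
  dir_sign <- ifelse(cells$direction == "up", 1, -1)

  eye_mov <- stats::rnorm(nt, dir_sign * amp / 2, model$movement_noise_sd_deg)
  eye_fix <- stats::rnorm(nt, 0, model$fixation_noise_sd_deg)
  eye_mov_x <- stats::rnorm(nt, 0, model$fixation_noise_sd_deg)
  eye_fix_x <- stats::rnorm(nt, 0, model$fixation_noise_sd_deg)
  head <- matrix(stats::rnorm(4 * nt, 0, model$head_noise_sd_px), nt, 4)
  colnames(head) <- c("fix_y", "mov_y", "fix_x", "mov_x")

  # at most one contamination type per trial
  u <- stats::runif(nt)
  contaminated <- rep("none", nt)
  contaminated[u < model$saccade_rate] <- "saccade"
  contaminated[u >= model$saccade_rate &
                 u < model$saccade_rate + model$head_jump_rate] <- "headjump"
  contaminated[u >= model$saccade_rate + model$head_jump_rate &
                 u < model$saccade_rate + model$head_jump_rate +
                 model$blink_rate] <- "blink"

  sac_off <- 10 * max(model$fixation_noise_sd_deg, 0.05)
  jump_off <- 10 * max(model$head_noise_sd_px, 0.5)
  is_sac <- contaminated == "saccade"
  eye_fix[is_sac] <- eye_fix[is_sac] +
    sample(c(-1, 1), sum(is_sac), replace = TRUE) * sac_off
  is_jump <- contaminated == "headjump"
  if (any(is_jump)) {
    epoch <- sample(c("fix_y", "mov_y"), sum(is_jump), replace = TRUE)
    sgn <- sample(c(-1, 1), sum(is_jump), replace = TRUE)
    idx <- which(is_jump)
    for (j in seq_along(idx))
      head[idx[j], epoch[j]] <- head[idx[j], epoch[j]] + sgn[j] * jump_off
  }
  blink <- contaminated == "blink"

  ppd <- model$px_per_deg
  trials <- data.frame(
    trial_id = sprintf("T%03d", seq_len(nt)),
    condition = cells$condition, direction = cells$direction,
    dy_pupil_fix = head[, "fix_y"] + eye_fix * ppd,
    dy_pupil_mov = head[, "mov_y"] + eye_mov * ppd,
    dy_marker_fix = head[, "fix_y"], dy_marker_mov = head[, "mov_y"],
    dx_pupil_fix = head[, "fix_x"] + eye_fix_x * ppd,
    dx_pupil_mov = head[, "mov_x"] + eye_mov_x * ppd,
    dx_marker_fix = head[, "fix_x"], dx_marker_mov = head[, "mov_x"],
    blink_flag = blink, oof_flag = FALSE,
    stringsAsFactors = FALSE)
  num <- setdiff(trial_table_columns, c("trial_id", "condition", "direction",
                                        "blink_flag", "oof_flag"))
  trials[blink, num] <- NA_real_

  truth <- data.frame(
    trial_id = trials$trial_id,
    condition = cells$condition, direction = cells$direction,
    true_eye_disp_fix = eye_fix, true_eye_disp_mov = eye_mov,
    true_head_disp_fix = head[, "fix_y"], true_head_disp_mov = head[, "mov_y"],
    contaminated = contaminated, stringsAsFactors = FALSE)
  rownames(trials) <- rownames(truth) <- NULL
  structure(list(trials = trials, truth = truth, model = model),
            class = "ofr_session")
}

# anti-aliased dark disc added into an image region: intensity blends from
# the background (or current content) to `intensity` with a 1-px soft edge
add_disc <- function(img, cx, cy, radius, intensity, soft = 1) {
  h <- nrow(img); w <- ncol(img)
  x0 <- max(1L, floor(cx + 1 - radius - 2)); x1 <- min(w, ceiling(cx + 1 + radius + 2))
  y0 <- max(1L, floor(cy + 1 - radius - 2)); y1 <- min(h, ceiling(cy + 1 + radius + 2))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(rep(1, length(ys)), xs - 1 - cx)
  dy <- outer(ys - 1 - cy, rep(1, length(xs)))
  d <- sqrt(dx^2 + dy^2)
  cov <- if (soft > 0) pmin(pmax((radius + soft / 2 - d) / soft, 0), 1)
         else as.numeric(d <= radius)
  img[ys, xs] <- img[ys, xs] * (1 - cov) + intensity * cov
  img
}

render_eye_frame <- function(cam, pupil_xy, marker_xy, blink = FALSE) {
  w <- cam$frame_size_px[1]; h <- cam$frame_size_px[2]
  img <- matrix(cam$background_intensity, h, w)
  if (!blink) {
    # a blink occludes iris and pupil alike (closed eyelid)
    img <- add_disc(img, pupil_xy[1], pupil_xy[2], cam$iris_radius_px,
                    cam$iris_intensity)
    img <- add_disc(img, pupil_xy[1], pupil_xy[2], cam$pupil_radius_px,
                    cam$pupil_intensity)
  }
  img <- add_disc(img, marker_xy[1], marker_xy[2], cam$marker_radius_px,
                  cam$marker_intensity)
  if (cam$noise_sd > 0)
    img <- pmin(pmax(img + stats::rnorm(length(img), 0, cam$noise_sd), 0), 1)
  img
}

#' Render camera-frame triplets for a simulated session
#'
#' Produces, for each trial, three grayscale frames at t0/t1/t2. Feature
#' positions follow the trial table: the pupil at t1 is the base position
#' plus the fixation-epoch pupil displacement, at t2 plus the movement-epoch
#' displacement on top; the marker moves by the head components only.
#' Analysis-space vertical displacements (positive = up) are converted to
#' image rows (y down) with a sign flip here; the tracker applies the
#' inverse flip once when reporting displacements. Blink trials render the
#' pupil absent at t1. Features pushed outside the frame are rendered
#' (clipped) anyway; the tracker is responsible for discarding them.
#'
#' @param session An `ofr_session` from [simulate_trial_table()], or its
#'   `trials` data frame.
#' @param cam A [camera_model()].
#' @return A list of `frame_triplet` objects (fields `frames` = list of
#'   three matrices, `trial_id`, `condition`, `direction`,
#'   `timestamps_ms = c(0, 80, 160)`).
#' @export
render_session_frames <- function(session, cam) {
  trials <- if (inherits(session, "ofr_session")) session$trials else session
  stopifnot(inherits(cam, "camera_model"))
  missing_cols <- setdiff(trial_table_columns, names(trials))
  if (length(missing_cols))
    stop("trial table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  lapply(seq_len(nrow(trials)), function(i) {
    tr <- trials[i, ]
    blink <- isTRUE(tr$blink_flag)
    d <- function(v) if (blink || is.na(v)) 0 else v
    # analysis dy (up positive) -> image dy (down positive)
    p0 <- cam$pupil_center
    p1 <- p0 + c(d(tr$dx_pupil_fix), -d(tr$dy_pupil_fix))
    p2 <- p1 + c(d(tr$dx_pupil_mov), -d(tr$dy_pupil_mov))
    m0 <- cam$marker_center
    m1 <- m0 + c(d(tr$dx_marker_fix), -d(tr$dy_marker_fix))
    m2 <- m1 + c(d(tr$dx_marker_mov), -d(tr$dy_marker_mov))
    structure(list(
      frames = list(t0 = render_eye_frame(cam, p0, m0),
                    t1 = render_eye_frame(cam, p1, m1, blink = blink),
                    t2 = render_eye_frame(cam, p2, m2)),
      trial_id = tr$trial_id, condition = tr$condition,
      direction = tr$direction, timestamps_ms = c(0, 80, 160)),
      class = "frame_triplet")
  })
}

#' Write a session's trial and ground-truth tables as CSV
#'
#' @param session An `ofr_session`.
#' @param dir Output directory.
#' @return Invisibly, the written paths.
#' @export
write_session_csv <- function(session, dir) {
  stopifnot(inherits(session, "ofr_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  pt <- file.path(dir, "trials.csv")
  pg <- file.path(dir, "ground_truth.csv")
  utils::write.csv(session$trials, pt, row.names = FALSE)
  utils::write.csv(session$truth, pg, row.names = FALSE)
  invisible(c(pt, pg))
}
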