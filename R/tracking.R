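#' @importFrom EBImage bwlabel
NULL

# dark-blob detector shared by pupil and marker localization.
# Thresholds dark pixels (Otsu within an intensity window unless a fixed
# threshold is given), labels connected components, keeps those inside the
# area bounds, and returns the subpixel, darkness-weighted centroid of the
# selected component. Coordinates are 0-based continuous pixels, origin at
# the top-left, x rightward, y downward.
detect_dark_blob <- function(frame, min_area, max_area,
                             min_circularity = 0.5,
                             intensity_window = c(0, 1),
                             exclude_center = NULL, exclude_radius = 0,
                             reject_border = FALSE, threshold = NULL) {
  stopifnot(is.matrix(frame))
  invalid <- list(x = NA_real_, y = NA_real_, quality = 0, valid = FALSE,
                  on_border = FALSE)
  roi <- frame
  roi[roi < intensity_window[1]] <- intensity_window[1]
  roi[roi > intensity_window[2]] <- intensity_window[2]
  if (is.null(threshold)) {
    rng <- range(roi)
    if (diff(rng) < 1e-6) return(invalid)
    threshold <- EBImage::otsu(roi, range = rng)
  }
  mask <- frame < threshold
  if (!is.null(exclude_center) && exclude_radius > 0) {
    xs <- outer(rep(1, nrow(frame)), seq_len(ncol(frame)) - 1)
    ys <- outer(seq_len(nrow(frame)) - 1, rep(1, ncol(frame)))
    mask[(xs - exclude_center[1])^2 + (ys - exclude_center[2])^2 <=
           exclude_radius^2] <- FALSE
  }
  if (!any(mask)) return(invalid)
  lab <- EBImage::bwlabel(mask)
  lab <- matrix(as.integer(lab), nrow(frame), ncol(frame))
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area & areas <= max_area)
  if (!length(keep)) return(invalid)
  # per-component stats; circularity proxy = area / (pi * r_max^2), 1 for a
  # perfect disc, small for elongated or ragged components
  stats_of <- function(id) {
    px <- which(lab == id, arr.ind = TRUE)
    cy <- mean(px[, 1] - 1); cx <- mean(px[, 2] - 1)
    r2 <- (px[, 1] - 1 - cy)^2 + (px[, 2] - 1 - cx)^2
    circ <- min(1, areas[id] / (pi * max(max(r2), 0.25)))
    border <- any(px[, 1] == 1L | px[, 1] == nrow(frame) |
                    px[, 2] == 1L | px[, 2] == ncol(frame))
    list(id = id, area = areas[id], cx = cx, cy = cy, circ = circ,
         border = border)
  }
  comps <- lapply(keep, stats_of)
  comps <- Filter(function(s) s$circ >= min_circularity, comps)
  if (!length(comps)) return(invalid)
  a <- vapply(comps, `[[`, numeric(1), "area")
  best_area <- max(a)
  cand <- comps[a == best_area]
  tie <- length(cand) > 1
  if (tie) {
    # deterministic tie-break: lowest centroid y, then lowest x
    ord <- order(vapply(cand, `[[`, numeric(1), "cy"),
                 vapply(cand, `[[`, numeric(1), "cx"))
    cand <- cand[ord]
  }
  sel <- cand[[1]]
  px <- which(lab == sel$id, arr.ind = TRUE)
  w <- threshold - frame[px]
  w[w < 0] <- 0
  if (sum(w) == 0) w <- rep(1, nrow(px))
  x <- sum(w * (px[, 2] - 1)) / sum(w)
  y <- sum(w * (px[, 1] - 1)) / sum(w)
  quality <- sel$circ * if (tie) 0.5 else 1
  list(x = x, y = y, quality = quality, valid = TRUE,
       on_border = sel$border)
}

#' Locate the pupil in a near-IR eye frame
#'
#' Dark-pupil detection: the frame is thresholded (Otsu's method within an
#' intensity window), connected components within the area bounds and above
#' a circularity floor are found, and the largest is taken as the pupil
#' (ties broken deterministically by lower centroid y, then lower x, with a
#' quality penalty). The reported center is the darkness-weighted subpixel
#' centroid of the component. Detection failure is reported via
#' `valid = FALSE`, never as an error.
#'
#' @param frame Grayscale image matrix (rows = y, values in `[0, 1]`).
#' @param min_area,max_area Component area bounds, px^2.
#' @param min_circularity Minimum circularity (area over circumscribed-disc
#'   area) for a component to count as a pupil.
#' @param intensity_window Intensities are clamped to this range before
#'   Otsu thresholding.
#' @param threshold Optional fixed threshold overriding Otsu.
#' @return A `feature_location`: list with `x`, `y` (0-based subpixel px),
#'   `quality` in `[0, 1]`, `valid`, `on_border`.
#' @export
detect_pupil <- function(frame, min_area = 2000, max_area = 2e5,
                         min_circularity = 0.5, intensity_window = c(0, 1),
                         threshold = NULL) {
  loc <- detect_dark_blob(frame, min_area, max_area, min_circularity,
                          intensity_window, threshold = threshold)
  loc$feature <- "pupil"
  structure(loc, class = "feature_location")
}

#' Locate the head marker in a near-IR frame
#'
#' As [detect_pupil()] but with marker-sized area bounds and an exclusion
#' zone around the detected pupil so the (equally dark) pupil cannot be
#' picked up. A marker component touching the image border (partially out
#' of frame) is reported as `valid = FALSE`.
#'
#' @inheritParams detect_pupil
#' @param pupil A `feature_location` from [detect_pupil()]; its
#'   neighbourhood is excluded from the search.
#' @param exclude_radius Radius of the exclusion zone around the pupil, px.
#' @return A `feature_location`.
#' @export
detect_marker <- function(frame, min_area = 50, max_area = 5e3,
                          min_circularity = 0.5, intensity_window = c(0, 1),
                          pupil = NULL, exclude_radius = 250,
                          threshold = NULL) {
  center <- if (!is.null(pupil) && isTRUE(pupil$valid))
    c(pupil$x, pupil$y) else NULL
  loc <- detect_dark_blob(frame, min_area, max_area, min_circularity,
                          intensity_window, exclude_center = center,
                          exclude_radius = exclude_radius,
                          threshold = threshold)
  if (isTRUE(loc$on_border)) loc$valid <- FALSE
  loc$feature <- "marker"
  structure(loc, class = "feature_location")
}

#' Measure per-epoch pupil and marker displacements for one trial
#'
#' Detects the pupil and head marker in each of the three frames and forms
#' displacements over the fixation epoch (t1 - t0) and the movement epoch
#' (t2 - t1) as differences of the per-frame absolute centers. Vertical
#' displacements are reported in the analysis convention (positive = up),
#' i.e. the image-row axis is sign-flipped here, once. Trials where the
#' pupil is undetected in any frame are discarded as blinks; trials where
#' the pupil touches the frame border or the marker is undetected or
#' border-touching are discarded as out-of-frame.
#'
#' @param triplet A `frame_triplet` (see [render_session_frames()]).
#' @param tracker Optional list of detector settings:
#'   `pupil_min_area`, `pupil_max_area`, `marker_min_area`,
#'   `marker_max_area`, `min_circularity`, `exclude_radius`.
#' @return One-row data frame in the session trial-table schema (`dy_*`,
#'   `dx_*`, `blink_flag`, `oof_flag`), displacements in px.
#' @export
measure_trial <- function(triplet, tracker = list()) {
  stopifnot(inherits(triplet, "frame_triplet"), length(triplet$frames) == 3)
  dims <- vapply(triplet$frames, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("frames in a triplet must share dimensions", call. = FALSE)
  tk <- utils::modifyList(list(pupil_min_area = 2000, pupil_max_area = 2e5,
                               marker_min_area = 50, marker_max_area = 5e3,
                               min_circularity = 0.5, exclude_radius = 250),
                          tracker)
  pupils <- lapply(triplet$frames, detect_pupil,
                   min_area = tk$pupil_min_area, max_area = tk$pupil_max_area,
                   min_circularity = tk$min_circularity)
  markers <- mapply(function(fr, pu)
    detect_marker(fr, min_area = tk$marker_min_area,
                  max_area = tk$marker_max_area,
                  min_circularity = tk$min_circularity,
                  pupil = pu, exclude_radius = tk$exclude_radius),
    triplet$frames, pupils, SIMPLIFY = FALSE)

  pupil_ok <- vapply(pupils, `[[`, logical(1), "valid")
  pupil_border <- vapply(pupils, function(p) isTRUE(p$on_border), logical(1))
  marker_ok <- vapply(markers, `[[`, logical(1), "valid")

  blink <- any(!pupil_ok)
  oof <- !blink && (any(pupil_border) || any(!marker_ok))
  out <- data.frame(trial_id = triplet$trial_id,
                    condition = triplet$condition %||% NA_character_,
                    direction = triplet$direction %||% NA_character_,
                    dy_pupil_fix = NA_real_, dy_pupil_mov = NA_real_,
                    dy_marker_fix = NA_real_, dy_marker_mov = NA_real_,
                    dx_pupil_fix = NA_real_, dx_pupil_mov = NA_real_,
                    dx_marker_fix = NA_real_, dx_marker_mov = NA_real_,
                    blink_flag = blink, oof_flag = oof,
                    stringsAsFactors = FALSE)
  if (blink || oof) return(out)
  # image y grows downward; analysis dy is positive upward
  dy <- function(locs, i, j) -(locs[[j]]$y - locs[[i]]$y)
  dx <- function(locs, i, j) locs[[j]]$x - locs[[i]]$x
  out$dy_pupil_fix <- dy(pupils, 1, 2); out$dy_pupil_mov <- dy(pupils, 2, 3)
  out$dx_pupil_fix <- dx(pupils, 1, 2); out$dx_pupil_mov <- dx(pupils, 2, 3)
  out$dy_marker_fix <- dy(markers, 1, 2); out$dy_marker_mov <- dy(markers, 2, 3)
  out$dx_marker_fix <- dx(markers, 1, 2); out$dx_marker_mov <- dx(markers, 2, 3)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Track a whole session of frame triplets
#'
#' Applies [measure_trial()] to each triplet and binds the rows into a
#' trial table with the same schema as the table tier of the synthetic
#' generator, so downstream QC and statistics run identically on tracked
#' frames and on simulated tables.
#'
#' @param triplets List of `frame_triplet` objects.
#' @param tracker Detector settings passed to [measure_trial()].
#' @return Trial-table data frame.
#' @export
track_session <- function(triplets, tracker = list()) {
  do.call(rbind, lapply(triplets, measure_trial, tracker = tracker))
}
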