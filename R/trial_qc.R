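#' QC configuration for robust trial screening
#'
#' Settings for the iterative outlier exclusion applied to each screened
#' channel. A channel is an (epoch, signal) pair; the defaults screen
#' fixation-epoch eye, fixation-epoch head, and movement-epoch head — the
#' movement-epoch eye signal is deliberately never screened, since that is
#' the response being measured.
#'
#' @param k_mad Multiplier on the robust SD (scaled MAD) beyond which a
#'   value counts as an outlier.
#' @param max_iterations Safety cap on filter iterations.
#' @param channels Data frame with columns `epoch` (`"fix"`/`"mov"`) and
#'   `signal` (`"eye"`/`"head"`).
#' @param screen_axes Axes screened per channel; a saccade in x is still
#'   poor fixation, so both axes are screened by default.
#' @param px_per_deg Camera scale factor used when converting pixel
#'   displacements to degrees.
#' @return An object of class `qc_config`.
#' @export
qc_config <- function(k_mad = 3, max_iterations = 50,
                      channels = data.frame(
                        epoch = c("fix", "fix", "mov"),
                        signal = c("eye", "head", "head"),
                        stringsAsFactors = FALSE),
                      screen_axes = c("y", "x"), px_per_deg = 40) {
  stopifnot(k_mad > 0, max_iterations >= 1, nrow(channels) >= 1,
            all(channels$epoch %in% c("fix", "mov")),
            all(channels$signal %in% c("eye", "head")),
            all(screen_axes %in% c("x", "y")), px_per_deg > 0)
  structure(list(k_mad = k_mad, robust_sd_method = "scaled_mad",
                 max_iterations = as.integer(max_iterations),
                 channels = channels, screen_axes = screen_axes,
                 px_per_deg = px_per_deg),
            class = "qc_config")
}

#' Convert raw pupil/marker displacements to eye-in-head trials
#'
#' Eye-in-head displacement is pupil displacement (eye-in-space) minus
#' head-marker displacement (head-in-space), per epoch and axis, converted
#' to degrees with the camera scale factor. Head-marker displacements are
#' kept in pixels. Blink and out-of-frame discards propagate into
#' `excluded_reason`.
#'
#' @param measurements Trial table (schema of [simulate_trial_table()] /
#'   [track_session()]).
#' @param px_per_deg Camera scale factor, px per degree.
#' @return Data frame of eye trials: `trial_id`, `condition`, `direction`,
#'   `eye_fix`, `eye_mov`, `eye_fix_x`, `eye_mov_x` (deg), `head_fix`,
#'   `head_mov`, `head_fix_x`, `head_mov_x` (px), `excluded_reason`.
#' @export
compute_eye_in_head <- function(measurements, px_per_deg) {
  stopifnot(px_per_deg > 0)
  missing_cols <- setdiff(trial_table_columns, names(measurements))
  if (length(missing_cols))
    stop("trial table lacks columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  m <- measurements
  out <- data.frame(
    trial_id = m$trial_id, condition = m$condition, direction = m$direction,
    eye_fix = (m$dy_pupil_fix - m$dy_marker_fix) / px_per_deg,
    eye_mov = (m$dy_pupil_mov - m$dy_marker_mov) / px_per_deg,
    eye_fix_x = (m$dx_pupil_fix - m$dx_marker_fix) / px_per_deg,
    eye_mov_x = (m$dx_pupil_mov - m$dx_marker_mov) / px_per_deg,
    head_fix = m$dy_marker_fix, head_mov = m$dy_marker_mov,
    head_fix_x = m$dx_marker_fix, head_mov_x = m$dx_marker_mov,
    excluded_reason = ifelse(m$blink_flag, "blink",
                             ifelse(m$oof_flag, "out_of_frame", "none")),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Iterative robust outlier filter
#'
#' Repeatedly computes the median and the robust SD (1.4826 x the median
#' absolute deviation) of the currently kept values and drops values
#' deviating from the median by more than `k_mad` robust SDs, until a pass
#' drops nothing (or `max_iterations` is reached). When the robust SD is
#' zero (at least half the kept values identical), only values exactly
#' equal to the median are kept — the documented degenerate rule.
#'
#' @param values Numeric vector (at least 3 finite values).
#' @param cfg A [qc_config()] (only `k_mad` and `max_iterations` are used).
#' @return Logical keep-mask the same length as `values`.
#' @export
robust_outlier_filter <- function(values, cfg = qc_config()) {
  stopifnot(inherits(cfg, "qc_config"))
  if (sum(is.finite(values)) < 3)
    stop("need at least 3 finite values", call. = FALSE)
  keep <- is.finite(values)
  for (it in seq_len(cfg$max_iterations)) {
    m <- stats::median(values[keep])
    s <- 1.4826 * stats::median(abs(values[keep] - m))
    drop <- if (s == 0) keep & (values != m)
            else keep & (abs(values - m) > cfg$k_mad * s)
    if (!any(drop)) break
    keep <- keep & !drop
  }
  keep
}

qc_channel_column <- function(epoch, signal, axis) {
  base <- paste0(signal, "_", epoch)
  if (axis == "x") paste0(base, "_x") else base
}

#' Apply robust QC screening to a session of eye trials
#'
#' Runs [robust_outlier_filter()] on each configured channel (and axis)
#' over all non-discarded trials of the session pooled across the four
#' condition x direction cells — fixation drift and head motion are
#' condition-agnostic, and pooling avoids biasing the per-cell response
#' means. A trial is excluded if it is flagged on any screened channel;
#' reasons are prioritized blink > out_of_frame > fix_eye > fix_head >
#' mov_head.
#'
#' The whole multi-channel screening is itself repeated until a full pass
#' over every channel drops no further trial, so the procedure is
#' idempotent: re-running it on its own kept set excludes nothing.
#'
#' @param trials Eye-trial table from [compute_eye_in_head()] (one
#'   subject-session).
#' @param cfg A [qc_config()].
#' @return List with `kept` (trials surviving QC), `trials` (all trials
#'   with final `excluded_reason`), and `report` (per-channel and total
#'   exclusion fractions and counts).
#' @export
apply_qc <- function(trials, cfg = qc_config()) {
  stopifnot(inherits(cfg, "qc_config"))
  if (nrow(trials) == 0) stop("empty session", call. = FALSE)
  reason <- trials$excluded_reason
  n_screenable <- sum(reason == "none")
  ch_names <- paste0(cfg$channels$epoch, "_", cfg$channels$signal)
  ch_excluded <- stats::setNames(rep(0L, length(ch_names)), ch_names)
  # channel priority for the reported primary reason follows the
  # configured order (default fix_eye > fix_head > mov_head)
  for (pass in seq_len(cfg$max_iterations)) {
    screenable <- reason == "none"
    flags <- matrix(FALSE, nrow(trials), length(ch_names),
                    dimnames = list(NULL, ch_names))
    for (i in seq_len(nrow(cfg$channels))) {
      for (axis in cfg$screen_axes) {
        col <- qc_channel_column(cfg$channels$epoch[i],
                                 cfg$channels$signal[i], axis)
        if (!col %in% names(trials))
          stop("missing channel column: ", col, call. = FALSE)
        keep <- robust_outlier_filter(trials[[col]][screenable], cfg)
        flags[which(screenable)[!keep], i] <- TRUE
      }
    }
    if (!any(flags)) break
    for (i in seq_along(ch_names)) {
      newly <- screenable & flags[, i] & reason == "none"
      ch_excluded[i] <- ch_excluded[i] + sum(newly)
      reason[newly] <- ch_names[i]
    }
  }
  channel_frac <- as.list(ch_excluded / max(n_screenable, 1L))
  trials$excluded_reason <- reason
  kept <- trials[reason == "none", , drop = FALSE]
  rownames(kept) <- NULL
  n_total <- nrow(trials)
  report <- list(
    n_total = n_total, n_kept = nrow(kept),
    n_excluded = n_total - nrow(kept),
    exclusion_fraction = 1 - nrow(kept) / n_total,
    per_channel_fraction = channel_frac,
    reason_counts = as.list(table(reason)))
  list(kept = kept, trials = trials, report = report)
}
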