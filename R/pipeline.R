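#' Pipeline configuration
#'
#' Bundles all stage configurations and the top-level seed into one
#' serializable object. The top-level seed fans out deterministically into
#' stage-specific child seeds (simulation, rendering, bootstrap), each
#' recorded in the run report, so a run is reproducible bit-for-bit from
#' its config alone.
#'
#' @param subject A [subject_model()].
#' @param camera A [camera_model()] (used only by the frame tier).
#' @param qc A [qc_config()].
#' @param stimulus A [stimulus_spec()] (recorded for provenance; the
#'   table tier does not render stimuli).
#' @param tier `"table"` (simulate -> qc -> stats) or `"frames"`
#'   (simulate -> render -> track -> qc -> stats).
#' @param n_bootstrap Bootstrap replicates for the condition comparison.
#' @param alpha Significance level.
#' @param seed Top-level RNG seed.
#' @param tracker Detector settings for the frame tier (see
#'   [measure_trial()]).
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(subject = subject_model(),
                            camera = camera_model(),
                            qc = qc_config(px_per_deg = subject$px_per_deg),
                            stimulus = stimulus_spec(),
                            tier = c("table", "frames"),
                            n_bootstrap = 10000, alpha = 0.05,
                            seed = 1L, tracker = list()) {
  tier <- match.arg(tier)
  structure(list(subject = subject, camera = camera, qc = qc,
                 stimulus = stimulus, tier = tier,
                 n_bootstrap = as.integer(n_bootstrap), alpha = alpha,
                 seed = as.integer(seed), tracker = tracker),
            class = "pipeline_config")
}

# deterministic fan-out of the top-level seed into stage seeds
stage_seeds <- function(seed) {
  list(simulate = (seed * 7L + 1L) %% 2000000000L,
       render = (seed * 7L + 2L) %% 2000000000L,
       bootstrap = (seed * 7L + 3L) %% 2000000000L)
}

#' Run the full OFR analysis pipeline on a simulated session
#'
#' Executes the stages for one subject-session: simulate a trial table
#' (and, on the frame tier, render camera-frame triplets and track them),
#' convert to eye-in-head displacements, apply robust QC, summarize both
#' conditions and run the bootstrap correlated-versus-anticorrelated
#' comparison. When `out_dir` is given, writes `trials.csv`,
#' `ground_truth.csv`, `kept.csv`, `summary.csv`, `report.json` and a
#' `manifest.csv` with MD5 checksums of every written file.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory.
#' @return List of class `pipeline_run`: `session`, `eye_trials`, `qc`
#'   (kept table + report), `summaries` (both conditions), `comparison`
#'   ([bootstrap_condition_comparison()] result), `seeds`, `config`.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seeds <- stage_seeds(config$seed)
  subject <- config$subject
  subject$seed <- seeds$simulate
  session <- simulate_trial_table(subject)
  measurements <- session$trials
  if (config$tier == "frames") {
    set.seed(seeds$render)
    triplets <- render_session_frames(session, config$camera)
    measurements <- track_session(triplets, tracker = config$tracker)
  }
  eye_trials <- compute_eye_in_head(measurements, config$qc$px_per_deg)
  qc <- apply_qc(eye_trials, config$qc)
  kept <- qc$kept
  split_cond <- split(kept, kept$condition)
  if (is.null(split_cond$correlated) || is.null(split_cond$anticorrelated))
    stop("stats stage: a condition lost all trials in QC", call. = FALSE)
  comparison <- bootstrap_condition_comparison(
    split_cond$correlated, split_cond$anticorrelated,
    n_bootstrap = config$n_bootstrap, seed = seeds$bootstrap,
    alpha = config$alpha)
  summaries <- rbind(comparison$ofr_correlated, comparison$ofr_anticorrelated)
  run <- structure(list(session = session, eye_trials = eye_trials, qc = qc,
                        summaries = summaries, comparison = comparison,
                        seeds = seeds, config = config),
                   class = "pipeline_run")
  if (!is.null(out_dir)) write_pipeline_run(run, out_dir)
  run
}

write_pipeline_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(write_session_csv(run$session, out_dir))
  kept_path <- file.path(out_dir, "kept.csv")
  utils::write.csv(run$qc$kept, kept_path, row.names = FALSE)
  sum_path <- file.path(out_dir, "summary.csv")
  utils::write.csv(run$summaries, sum_path, row.names = FALSE)
  report <- list(
    tier = run$config$tier, seed = run$config$seed, seeds = run$seeds,
    n_bootstrap = run$comparison$n_bootstrap, alpha = run$comparison$alpha,
    qc = run$qc$report,
    delta = run$comparison$delta,
    p_bootstrap = run$comparison$p_bootstrap,
    sensitive_flag = run$comparison$sensitive_flag)
  report_path <- file.path(out_dir, "report.json")
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  paths <- c(paths, kept_path, sum_path, report_path)
  manifest <- data.frame(file = basename(paths),
                         md5 = unname(tools::md5sum(paths)),
                         stringsAsFactors = FALSE)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(paths)
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("OFR pipeline run (", x$config$tier, " tier)\n", sep = "")
  cat(sprintf("  trials: %d total, %d kept (%.0f%% excluded)\n",
              x$qc$report$n_total, x$qc$report$n_kept,
              100 * x$qc$report$exclusion_fraction))
  s <- x$summaries
  for (i in seq_len(nrow(s)))
    cat(sprintf("  OFR %-14s %.3f +/- %.3f deg (SEM %.3f)\n",
                s$condition[i], s$ofr[i], s$ofr_sd[i], s$ofr_sem[i]))
  cat(sprintf("  delta = %.3f deg, bootstrap p = %.4g -> %s\n",
              x$comparison$delta, x$comparison$p_bootstrap,
              if (x$comparison$sensitive_flag)
                "sensitive to interocular correlation"
              else "not sensitive"))
  invisible(x)
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("OFR comparison: delta = %.3f deg, p = %.4g (B = %d)%s\n",
              x$delta, x$p_bootstrap, x$n_bootstrap,
              if (x$sensitive_flag) " *" else ""))
  invisible(x)
}
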