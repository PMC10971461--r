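#' Direction-difference tests for one condition
#'
#' Two-sided unpaired tests of vertical eye displacement for up- versus
#' down-drifting stimuli: a pooled-variance Student t-test and a
#' Mann-Whitney U test (exact when both groups have at most 8 observations
#' and no ties occur; otherwise the normal approximation with tie and
#' continuity correction). With zero variance in both groups and equal
#' means, both p-values are 1 by convention.
#'
#' @param up,dw Numeric vectors of movement-epoch vertical eye
#'   displacements (deg), at least 2 each.
#' @param var_equal Use the pooled-variance t statistic (default); set
#'   `FALSE` for Welch.
#' @return List with `p_t` and `p_np`.
#' @export
direction_test <- function(up, dw, var_equal = TRUE) {
  if (length(up) < 2 || length(dw) < 2)
    stop("need at least 2 values per direction", call. = FALSE)
  degenerate <- stats::sd(up) == 0 && stats::sd(dw) == 0
  if (degenerate && mean(up) == mean(dw)) return(list(p_t = 1, p_np = 1))
  if (degenerate) return(list(p_t = 0, p_np = 0))
  p_t <- stats::t.test(up, dw, var.equal = var_equal)$p.value
  use_exact <- max(length(up), length(dw)) <= 8 &&
    !any(duplicated(c(up, dw)))
  p_np <- suppressWarnings(
    stats::wilcox.test(up, dw, exact = use_exact, correct = TRUE)$p.value)
  list(p_t = p_t, p_np = p_np)
}

#' Derived OFR columns from per-direction summary statistics
#'
#' The OFR is the difference of the mean vertical eye displacements to
#' upward- and downward-drifting stimuli in the open-loop movement window;
#' its SD and SEM combine the per-direction dispersions:
#' `ofr = mean_up - mean_dw`, `ofr_sd = sqrt(sd_up^2 + sd_dw^2)`,
#' `ofr_sem = sqrt(sd_up^2 / n_up + sd_dw^2 / n_dw)`.
#'
#' @param mean_up,sd_up,n_up,mean_dw,sd_dw,n_dw Per-direction sample
#'   statistics (vectorized).
#' @return Data frame with columns `ofr`, `ofr_sd`, `ofr_sem`.
#' @export
ofr_from_direction_stats <- function(mean_up, sd_up, n_up,
                                     mean_dw, sd_dw, n_dw) {
  data.frame(ofr = mean_up - mean_dw,
             ofr_sd = sqrt(sd_up^2 + sd_dw^2),
             ofr_sem = sqrt(sd_up^2 / n_up + sd_dw^2 / n_dw))
}

#' Summarize one condition's OFR from kept trials
#'
#' Computes per-direction sample means and SDs (n - 1 denominator) of the
#' movement-epoch vertical eye-in-head displacement, the derived OFR
#' columns, and the direction-difference p-values.
#'
#' @param trials Kept eye-trial table of a single condition (columns
#'   `direction`, `eye_mov`).
#' @param condition Optional condition label; taken from the table when
#'   absent.
#' @param var_equal Passed to [direction_test()].
#' @return One-row data frame: `condition`, `mean_up`, `sd_up`, `n_up`,
#'   `mean_dw`, `sd_dw`, `n_dw`, `ofr`, `ofr_sd`, `ofr_sem`, `p_t`, `p_np`.
#' @export
summarize_condition <- function(trials, condition = NULL, var_equal = TRUE) {
  if (is.null(condition)) {
    condition <- unique(trials$condition)
    if (length(condition) != 1)
      stop("trials must come from a single condition", call. = FALSE)
  }
  up <- trials$eye_mov[trials$direction == "up"]
  dw <- trials$eye_mov[trials$direction == "down"]
  if (length(up) < 2)
    stop(sprintf("condition %s, direction up: fewer than 2 trials",
                 condition), call. = FALSE)
  if (length(dw) < 2)
    stop(sprintf("condition %s, direction down: fewer than 2 trials",
                 condition), call. = FALSE)
  p <- direction_test(up, dw, var_equal = var_equal)
  cbind(data.frame(condition = condition,
                   mean_up = mean(up), sd_up = stats::sd(up),
                   n_up = length(up),
                   mean_dw = mean(dw), sd_dw = stats::sd(dw),
                   n_dw = length(dw), stringsAsFactors = FALSE),
        ofr_from_direction_stats(mean(up), stats::sd(up), length(up),
                                 mean(dw), stats::sd(dw), length(dw)),
        data.frame(p_t = p$p_t, p_np = p$p_np))
}

#' Bootstrap comparison of correlated versus anticorrelated OFRs
#'
#' For each bootstrap replicate, each of the four condition x direction
#' cells is resampled with replacement at its own size and the replicate
#' statistic is the difference of the two resampled OFRs,
#' `delta* = (mean_up_c* - mean_dw_c*) - (mean_up_ac* - mean_dw_ac*)`.
#' The two-sided p-value is
#' `min(1, 2 * min(#(delta* <= 0) + 1, #(delta* >= 0) + 1) / (B + 1))`,
#' which can never be exactly zero. A subject is flagged as sensitive to
#' interocular correlation when `p < alpha`.
#'
#' @param trials_c,trials_ac Kept eye-trial tables of the correlated and
#'   anticorrelated condition (columns `direction`, `eye_mov`), at least 2
#'   trials per direction each.
#' @param n_bootstrap Number of bootstrap replicates.
#' @param seed RNG seed recorded in the result.
#' @param alpha Significance level for the sensitivity flag.
#' @return An object of class `comparison_result`: `ofr_correlated`,
#'   `ofr_anticorrelated` (condition summaries), `delta`, `p_bootstrap`,
#'   `n_bootstrap`, `seed`, `alpha`, `sensitive_flag`.
#' @export
bootstrap_condition_comparison <- function(trials_c, trials_ac,
                                           n_bootstrap = 10000, seed = NULL,
                                           alpha = 0.05) {
  # cells are sorted so the resampling stream, and hence the p-value, is
  # invariant to trial order
  cells <- list(up_c = sort(trials_c$eye_mov[trials_c$direction == "up"]),
                dw_c = sort(trials_c$eye_mov[trials_c$direction == "down"]),
                up_ac = sort(trials_ac$eye_mov[trials_ac$direction == "up"]),
                dw_ac = sort(trials_ac$eye_mov[trials_ac$direction == "down"]))
  sizes <- lengths(cells)
  if (any(sizes < 2))
    stop("each condition x direction cell needs at least 2 trials",
         call. = FALSE)
  if (n_bootstrap < 100)
    warning("n_bootstrap < 100: the bootstrap p-value will be very coarse")
  if (!is.null(seed)) set.seed(seed)
  B <- as.integer(n_bootstrap)
  cell_means <- lapply(cells, function(v) {
    n <- length(v)
    rowMeans(matrix(sample(v, B * n, replace = TRUE), B, n))
  })
  deltas <- (cell_means$up_c - cell_means$dw_c) -
    (cell_means$up_ac - cell_means$dw_ac)
  p <- min(1, 2 * min(sum(deltas <= 0) + 1, sum(deltas >= 0) + 1) / (B + 1))
  sum_c <- summarize_condition(trials_c, condition = "correlated")
  sum_ac <- summarize_condition(trials_ac, condition = "anticorrelated")
  structure(list(ofr_correlated = sum_c, ofr_anticorrelated = sum_ac,
                 delta = sum_c$ofr - sum_ac$ofr,
                 p_bootstrap = p, n_bootstrap = B, seed = seed,
                 alpha = alpha, sensitive_flag = p < alpha),
            class = "comparison_result")
}

#' Classify a cohort's interocular-correlation sensitivity
#'
#' Counts, at level `alpha`, how many subjects show a significant
#' correlated-versus-anticorrelated OFR difference. Accepts a list of
#' `comparison_result` objects or a numeric vector of comparison p-values.
#'
#' @param results List of [bootstrap_condition_comparison()] results, or a
#'   numeric vector of p-values.
#' @param alpha Significance level.
#' @return List with `n_sensitive`, `n_insensitive`, `n_total` and the
#'   per-subject logical `sensitive` vector.
#' @export
classify_cohort <- function(results, alpha = 0.05) {
  p <- if (is.numeric(results)) results
       else vapply(results, `[[`, numeric(1), "p_bootstrap")
  if (!length(p)) stop("no results to classify", call. = FALSE)
  sensitive <- p < alpha
  list(n_sensitive = sum(sensitive), n_insensitive = sum(!sensitive),
       n_total = length(p), sensitive = sensitive)
}
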