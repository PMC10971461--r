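#' Reference cohort summary statistics
#'
#' Published per-subject summary statistics from a dichoptic OFR study of
#' twelve children: six stereo-normal controls (HC1-HC6) and six
#' stereo-deficient amblyopic patients (P1-P6). Two tables are shipped as
#' plain-text worked-example fixtures:
#'
#' * `direction_summary` — per subject x condition (correlated /
#'   anticorrelated): mean, SD and N of the movement-window vertical eye
#'   displacement for upward- and downward-drifting stimuli (deg; negative =
#'   downward), plus the printed direction-difference p-values (`p_t`
#'   unpaired t, `p_np` Mann-Whitney U; values below the printed precision
#'   appear as `"<0.001"` and are kept as character columns).
#' * `comparison` — per subject: OFR, combined SD and SEM for each
#'   condition, and the bootstrap p-value of the correlated-versus-
#'   anticorrelated comparison. p-values printed as `"<0.001"` are stored
#'   at their upper bound `0.001` in the numeric `p_comparison` column
#'   (this only matters for thresholding at conventional alpha levels).
#'
#' @return List with data frames `direction_summary` and `comparison`.
#' @export
reference_cohort <- function() {
  ds <- utils::read.csv(system.file("extdata", "cohort_direction_summary.csv",
                                    package = "ofrkit"),
                        stringsAsFactors = FALSE,
                        colClasses = c(p_t = "character",
                                       p_np = "character"))
  cp <- utils::read.csv(system.file("extdata", "cohort_comparison.csv",
                                    package = "ofrkit"),
                        stringsAsFactors = FALSE)
  cp$p_comparison <- as.numeric(sub("^<", "", cp$p_comparison))
  list(direction_summary = ds, comparison = cp)
}
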