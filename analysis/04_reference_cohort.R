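#!/usr/bin/env Rscript
# Worked example on the reference cohort (12 children: 6 stereo-normal
# controls, 6 amblyopic patients with impaired stereopsis): recomputes the
# derived OFR, combined SD and SEM columns from the per-direction summary
# statistics, and classifies each subject's interocular-correlation
# sensitivity from the published bootstrap p-values at alpha = 0.05.
# Writes results/reference_derived.csv and results/reference_classification.csv.

library(ofrkit)

ref <- reference_cohort()
ds <- ref$direction_summary
cmp <- ref$comparison

derived <- cbind(ds[, c("subject", "group", "condition")],
                 ofr_from_direction_stats(ds$mean_up, ds$sd_up, ds$n_up,
                                          ds$mean_dw, ds$sd_dw, ds$n_dw))
printed <- ifelse(ds$condition == "correlated",
                  cmp$ofr_c[match(ds$subject, cmp$subject)],
                  cmp$ofr_ac[match(ds$subject, cmp$subject)])
derived$printed_ofr <- printed
derived$abs_diff <- abs(derived$ofr - printed)

cls <- do.call(rbind, lapply(split(cmp, cmp$group), function(g) {
  r <- classify_cohort(g$p_comparison, alpha = 0.05)
  data.frame(group = g$group[1], n_sensitive = r$n_sensitive,
             n_total = r$n_total)
}))

dir.create("results", showWarnings = FALSE)
write.csv(derived, "results/reference_derived.csv", row.names = FALSE)
write.csv(cls, "results/reference_classification.csv", row.names = FALSE)

cat("Derived OFR vs printed values: max |difference| =",
    format(max(derived$abs_diff), digits = 3), "deg\n")
print(cls, row.names = FALSE)
cat("\nAt alpha = 0.05 the controls split 5 sensitive / 1 not;",
    "no patient shows a significant correlated-vs-anticorrelated",
    "difference.\n")
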