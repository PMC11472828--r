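#!/usr/bin/env Rscript
# Biomarker association analysis: age-residualised NfL as the
# neurodegeneration outcome, bivariate Pearson correlations (Fisher-z CIs)
# whole-sample and stratified by clinical diagnosis, and the post hoc
# WMH-by-GFAP interaction on p-tau217.

library(dswmh)

cohort <- read_biomarker_table("results/cohort.csv")
cohort <- residualize_age(cohort)

ct <- correlation_table(cohort)
write.table(ct, "results/correlation_table.tsv", sep = "\t",
            row.names = FALSE, quote = FALSE)
cat("associations with age-residualised NfL (whole sample):\n")
ws <- ct[ct$stratum == "whole_sample", ]
for (k in seq_len(nrow(ws))) {
  cat(sprintf("  %-10s r = %.2f (%.2f, %.2f), P = %.2g\n", ws$predictor[k],
              ws$r[k], ws$ci_low[k], ws$ci_high[k], ws$p_value[k]))
}

im <- fit_interaction_model(cohort)
jsonlite::write_json(
  list(coefficients = as.list(im$coefficients),
       conditional_slopes = im$conditional_slopes, n = im$n),
  "results/interaction_model.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE
)
cs <- im$conditional_slopes
g <- cs[cs$focal == "gfap", ]
cat(sprintf(
  "interaction coefficient %.3g; GFAP->p-tau217 slope by WMH tertile: %s\n",
  im$coefficients["wmh_cc:gfap"],
  paste(sprintf("%.3g", g$slope), collapse = " / ")
))
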