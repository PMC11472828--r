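#!/usr/bin/env Rscript
# Simulate the study inputs: a synthetic biomarker cohort generated from the
# hypothesised cerebrovascular cascade (age -> WMH -> GFAP -> p-tau217 ->
# NfL), and a set of FLAIR-like phantoms with known periventricular lesions.
# Downstream scripts consume these files; nothing here is real patient data.

library(dswmh)

seed <- 1
n_cohort <- 185   # matches the study's sample size
n_phantoms <- 12  # imaging demonstration subset

dir.create("results/phantoms", recursive = TRUE, showWarnings = FALSE)

cohort <- make_cohort(cohort_spec(n = n_cohort, seed = seed))
write.csv(cohort, "results/cohort.csv", row.names = FALSE)
cat(sprintf("wrote results/cohort.csv: %d subjects, %d sites, diagnoses %s\n",
            nrow(cohort), length(unique(cohort$site)),
            paste(table(cohort$diagnosis), collapse = "/")))

for (i in seq_len(n_phantoms)) {
  # lesion load tied to the subject's generated WMH volume, placed against
  # the ventricle wall (periventricular), one phantom per cohort subject
  r <- max(2, min(7, (3 * 0.12 * max(cohort$wmh_cc[i], 0) * 1000 /
                        (4 * pi))^(1 / 3)))
  sp <- phantom_spec(seed = seed + i)
  sp$lesions <- list(list(centre = c(7.04 + r, 0, 0), radius_mm = r))
  ph <- make_phantom(sp)
  write_volume(ph$flair, sprintf("results/phantoms/flair_%02d.nii.gz", i))
  write_volume(ph$wm_mask, sprintf("results/phantoms/wm_%02d.nii.gz", i))
  write_volume(ph$lesion_truth,
               sprintf("results/phantoms/truth_%02d.nii.gz", i))
  cat(sprintf("phantom %02d: true lesion volume %.3f cc\n",
              i, ph$true_volume_cc))
}
cat("done: phantoms under results/phantoms/\n")
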