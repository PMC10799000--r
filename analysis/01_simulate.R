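#!/usr/bin/env Rscript
# Generate the synthetic study cohort: 30 dryland sites spanning aridity
# index 0.04-0.59, two depths (0-10 and 35-50 cm), four moisture conditions
# (field, 20/40/60% WHC), and one six-step (5-30 degC) incubation gas series
# per sample. Ground truth goes to truth.csv; the other tables mimic what a
# field/lab campaign would deposit.

library(dryq10)

cfg <- cohort_config(seed = 1L)
cohort <- generate_cohort(cfg)
write_cohort(cohort, "results/cohort")
write_run_config(cfg, "results/cohort/config.yaml")

cat(sprintf("simulated %d sites, %d samples, %d incubation records\n",
            nrow(cohort$sites), nrow(cohort$samples),
            nrow(cohort$incubation)))
cat(sprintf("aridity index spans %.2f-%.2f; MAT %.1f-%.1f degC\n",
            min(cohort$sites$aridity_index), max(cohort$sites$aridity_index),
            min(cohort$sites$mat), max(cohort$sites$mat)))
cat("wrote results/cohort/{sites,samples,incubation,truth}.csv\n")
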