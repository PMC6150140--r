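#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort.
#
# The hospital's record-level data are not public, so the whole workflow
# runs on a simulated stand-in with the unit's published marginal structure:
# ~55 abstracted admissions/month before the April 2014 form revision and
# ~230 after, sepsis prevalence 16.7%, mortality 9%, birth weight ~2.88 kg,
# a 60% full-abstraction sample, and documentation probabilities that ramp
# over calendar time (gestational age 10% -> 80%; temperature stuck < 50%).

library(naraudit)

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

params <- cohort_params(seed = seed)
cohort <- simulate_cohort(params)

dir.create("results", showWarnings = FALSE)
write_cohort(cohort, "results/cohort")

cat(sprintf(
  "simulated %d admissions (%s baseline-form, %s revised-form) and %d gentamicin prescriptions\n",
  nrow(cohort$records),
  sum(cohort$records$schema_version == "baseline"),
  sum(cohort$records$schema_version == "revised2014"),
  nrow(cohort$prescriptions)
))
cat("wrote results/cohort/records.csv and results/cohort/prescriptions.csv\n")
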