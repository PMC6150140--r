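#!/usr/bin/env Rscript
# Stage 3: gentamicin dosing-correctness audit.
#
# Classifies every prescription against the weight-banded once-daily rule
# (3 mg/kg under 2 kg, 5 mg/kg at or above, +/-20% margin, first week of
# life) and tracks the proportion of correct doses per period and weight
# band.

library(naraudit)

cohort <- read_cohort("results/cohort")
config <- period_config()
rule <- dose_rule()

assessments <- audit_prescriptions(cohort$prescriptions, rule)
readr::write_csv(assessments, "results/dose_assessments.csv", na = "")

tab <- table(assessments$class)
cat(sprintf("prescriptions: %d | correct %d, overdose %d, underdose %d, unassessable %d\n",
            nrow(assessments), tab["correct"], tab["overdose"],
            tab["underdose"], tab["unassessable"]))

series <- dose_accuracy_series(assessments, config)
readr::write_csv(series, "results/dose_accuracy_by_band_period.csv", na = "")

cat("\ndose accuracy, under 2 kg:\n")
print(as.data.frame(series[series$band == "under_2kg" & series$n > 0, ]),
      digits = 3)
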