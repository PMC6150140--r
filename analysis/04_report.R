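#!/usr/bin/env Rscript
# Stage 4: the assembled audit-and-feedback report.
#
# Runs the pipeline end to end (validate -> bin -> score -> stratify ->
# dose-audit -> summarise) and serialises the report tables; trend figures
# with CI ribbons are written when ggplot2 is available.

library(naraudit)

schema <- load_schema("revised2014")
cohort <- read_cohort("results/cohort", schema)
config <- period_config()

report <- run_audit(cohort$records, cohort$prescriptions,
                    schema = schema, config = config)
print(report)
print(as.data.frame(report$summary), digits = 3)

paths <- write_report(report, "results/report",
                      plots = requireNamespace("ggplot2", quietly = TRUE),
                      records = cohort$records, schema = schema,
                      config = config)
cat("wrote:\n")
cat(paste(" ", paths, collapse = "\n"), "\n")
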