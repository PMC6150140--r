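#!/usr/bin/env Rscript
# Stage 2: documentation-completeness scoring.
#
# Pools binary documentation indicators over each domain and six-month
# period (Wilson 95% CIs), and stratifies individual variables in the final
# period into very poorly (<25%), poorly (25-50%) and adequately (>50%)
# documented.

library(naraudit)

schema <- load_schema("revised2014")
cohort <- read_cohort("results/cohort", schema)
config <- period_config()

findings <- validate_record(cohort$records, schema)
cat(sprintf("validity findings: %d in %d records\n",
            nrow(findings), nrow(cohort$records)))

comp <- completeness_table(cohort$records, schema, config)
readr::write_csv(comp, "results/completeness_by_domain_period.csv", na = "")

last_period <- tail(config$bins$label, 1)
bins <- assign_period(cohort$records$adm_date, config)
strata <- stratify_variables(
  cohort$records[as.character(bins$period) == last_period, ], schema
)
readr::write_csv(strata, "results/variable_strata.csv", na = "")

cat("\ncompleteness in the final period:\n")
final <- comp[comp$period == last_period & comp$n > 0, ]
print(as.data.frame(final[, c("domain", "x", "n", "point")]), digits = 3)

cat("\nvariables still very poorly documented (<25%):\n")
print(as.data.frame(strata[strata$stratum == "very_poor",
                           c("variable", "documented_fraction")]), digits = 2)
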