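#!/usr/bin/env Rscript
# Apply the current trial's eligibility criteria to the raw historical
# control cohort and record the step-by-step attrition.

library(hybridctrl)

data_dir <- file.path("results", "data")
ext <- read.csv(file.path(data_dir, "external_cohort.csv"),
                colClasses = c(ecog = "character"))

rules <- default_eligibility_rules()
res <- apply_eligibility(ext, rules)

print(res$attrition)
write_attrition(res$attrition, file.path("results", "attrition.csv"))
write.csv(res$cohort, file.path(data_dir, "external_filtered.csv"),
          row.names = FALSE)
message("external-control cohort after filtering: ", nrow(res$cohort),
        " patients")
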