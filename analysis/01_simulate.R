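#!/usr/bin/env Rscript
# Generate the default synthetic two-trial dataset: a small randomized
# current trial (15 experimental / 13 concurrent control, 6-weekly visits)
# and a 90-patient raw historical control cohort (8-weekly visits) with
# planted eligibility violations.  Writes the patient tables, assessment
# tables and the truth record under results/data/.

library(hybridctrl)

out_dir <- file.path("results", "data")
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

config <- scenario_config()
pair <- generate_trial_pair(config, seed = 20260901 %% 100000)

write_cohort(pair$current$cohort, file.path(out_dir, "current_cohort.csv"))
write.csv(pair$external$cohort, file.path(out_dir, "external_cohort.csv"),
          row.names = FALSE)
write.csv(pair$current$assessments,
          file.path(out_dir, "current_assessments.csv"), row.names = FALSE)
write.csv(pair$external$assessments,
          file.path(out_dir, "external_assessments.csv"), row.names = FALSE)
jsonlite::write_json(
  list(seed = pair$truth$seed, true_hr = pair$truth$true_hr,
       true_or_response = pair$truth$true_or_response,
       config = pair$truth$config[!vapply(pair$truth$config, is.list,
                                          logical(1))]),
  file.path(out_dir, "truth.json"), auto_unbox = TRUE, digits = NA)

message("current trial: ", nrow(pair$current$cohort), " patients (",
        sum(pair$current$cohort$arm == "experimental"), " experimental / ",
        sum(pair$current$cohort$arm == "control"), " control)")
message("external raw cohort: ", nrow(pair$external$cohort), " patients")
message("written to ", out_dir)
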