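#!/usr/bin/env Rscript
# Harmonize endpoints across the two assessment schedules: derive the
# 12-week disease-control outcome per patient (direct 6-weekly rule for
# the current trial, week-8/16 inference for the historical schedule) and
# truncate external survival times at the current trial's maxima.

library(hybridctrl)

data_dir <- file.path("results", "data")
cur <- read_cohort(file.path(data_dir, "current_cohort.csv"))
ext <- read.csv(file.path(data_dir, "external_filtered.csv"),
                colClasses = c(ecog = "character"))
cur_assess <- read_assessments(file.path(data_dir,
                                         "current_assessments.csv"))
ext_assess <- read_assessments(file.path(data_dir,
                                         "external_assessments.csv"))

cur_dcr <- derive_dcr_cohort(cur, cur_assess)
ext_dcr <- derive_dcr_cohort(ext, ext_assess)
message("current-trial disease control: ",
        sum(cur_dcr$dcr12 == "disease_control"), "/", nrow(cur_dcr))
message("external disease control: ",
        sum(ext_dcr$dcr12 == "disease_control"), "/", nrow(ext_dcr),
        " (", sum(ext_dcr$dcr12 == "unknown"),
        " unknown under the 8/16-week rule, excluded downstream)")

ext <- truncate_survival(ext, cur, "pfs")
ext <- truncate_survival(ext, cur, "os")

code <- function(x) ifelse(x == "unknown", NA_real_,
                           as.numeric(x == "disease_control"))
cur$dcr <- code(cur_dcr$dcr12[match(cur$patient_id, cur_dcr$patient_id)])
ext$dcr <- code(ext_dcr$dcr12[match(ext$patient_id, ext_dcr$patient_id)])

write.csv(cur, file.path(data_dir, "current_analysis.csv"),
          row.names = FALSE)
write.csv(ext, file.path(data_dir, "external_analysis.csv"),
          row.names = FALSE)
write.csv(rbind(cur_dcr, ext_dcr), file.path("results", "dcr_outcomes.csv"),
          row.names = FALSE)
message("analysis-ready cohorts written")
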