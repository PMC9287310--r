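#!/usr/bin/env Rscript
# Estimate the propensity of experimental-arm membership (experimental vs
# filtered external control), attach SMR weights, and tabulate balance
# before and after weighting alongside the baseline hypothesis tests.

library(hybridctrl)

data_dir <- file.path("results", "data")
cls <- c(ecog = "character")
cur <- read.csv(file.path(data_dir, "current_analysis.csv"),
                colClasses = cls)
ext <- read.csv(file.path(data_dir, "external_analysis.csv"),
                colClasses = cls)

exp_arm <- cur[cur$arm == "experimental", ]
cc <- cur[cur$arm == "control", ]

weighted <- fit_propensity(exp_arm, ext, concurrent = cc)
bal <- balance_table(weighted)
print(bal)
write_balance(bal, file.path("results", "balance_table.csv"))

pvals <- suppressWarnings(baseline_tests(ext, exp_arm))
write.csv(data.frame(covariate = names(pvals), p_value = pvals,
                     row.names = NULL),
          file.path("results", "baseline_tests.csv"), row.names = FALSE)

write.csv(as.data.frame(weighted),
          file.path(data_dir, "weighted_cohort.csv"), row.names = FALSE)
message("effective external-control size (sum of SMR weights): ",
        round(sum(weighted$weight[weighted$trial == "external"]), 1))
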