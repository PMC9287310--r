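# Shared fixture builders.  Everything is generated in code; nothing is
# read from disk except the package's own shipped configuration files.

make_cohort <- function(n, trial = "current", arm = "control",
                        id_prefix = "P", pfs = NULL, os = NULL,
                        pfs_event = 1, os_event = 1, ecog = "1",
                        liver = "yes") {
  if (is.null(pfs)) pfs <- seq_len(n)
  if (is.null(os)) os <- pfs + 1
  data.frame(
    patient_id = paste0(id_prefix, seq_len(n)),
    trial = trial, arm = arm,
    age = 60, sex = "male", race = "white", region = "europe",
    ecog = ecog, liver_mets = liver, time_from_met_dx = 20,
    ras_status = "mutant",
    pfs_time = pfs, pfs_event = pfs_event,
    os_time = os, os_event = os_event,
    stringsAsFactors = FALSE)
}

arm_labels <- function(n_exp, n_cc, n_ext = 0) {
  rep(c("experimental", "concurrent_control", "external_control"),
      c(n_exp, n_cc, n_ext))
}

# simulate arm-level exponential survival data for the borrowing models
sim_three_arm_exp <- function(n_exp, n_cc, n_ext, log_h_exp = -1.4,
                              log_h_ctrl = -1.4, drift = 0, horizon = 24) {
  n <- n_exp + n_cc + n_ext
  arm <- arm_labels(n_exp, n_cc, n_ext)
  lp <- c(experimental = log_h_exp, concurrent_control = log_h_ctrl,
          external_control = log_h_ctrl + drift)[arm]
  t <- stats::rexp(n, exp(lp))
  e <- as.integer(t <= horizon)
  list(times = pmin(t, horizon), events = e, arm = arm)
}
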