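test_that("generator is a deterministic function of (config, seed) with the configured sizes", {
  cfg <- scenario_config()
  p1 <- generate_trial_pair(cfg, seed = 5)
  p2 <- generate_trial_pair(cfg, seed = 5)
  expect_identical(p1$current$cohort, p2$current$cohort)
  expect_identical(p1$external$cohort, p2$external$cohort)
  expect_identical(p1$current$assessments, p2$current$assessments)
  p3 <- generate_trial_pair(cfg, seed = 6)
  expect_false(identical(p1$current$cohort$pfs_time,
                         p3$current$cohort$pfs_time))

  cur <- p1$current$cohort
  expect_equal(nrow(cur), 28)
  expect_equal(sum(cur$arm == "experimental"), 15)
  expect_equal(sum(cur$arm == "control"), 13)
  expect_equal(nrow(p1$external$cohort), 90)
  expect_silent(validate_cohort(cur))
  expect_silent(validate_cohort(p1$external$cohort))
  expect_true(all(cur$os_time >= cur$pfs_time))
})

test_that("assessment series follow each trial's schedule and derive from progression", {
  p <- generate_trial_pair(scenario_config(), seed = 8)
  expect_true(all(p$current$assessments$week %% 6 == 0))
  expect_true(all(p$external$assessments$week %% 8 == 0))
  for (pid in unique(p$current$assessments$patient_id)) {
    w <- p$current$assessments$week[p$current$assessments$patient_id == pid]
    expect_true(all(diff(w) > 0))
  }
  # a PD visit, when present, is terminal and unique
  by_pat <- split(p$external$assessments$response,
                  p$external$assessments$patient_id)
  for (r in by_pat) {
    pd <- which(r == "PD")
    if (length(pd) > 0) expect_equal(pd, length(r))
  }
})

test_that("generate_assessments applies the visit rules stated for the schedules", {
  wpm <- 365.25 / 12 / 7
  # progression at 10 weeks on the 8-weekly schedule: SD at 8, PD at 16
  a <- generate_assessments(10 / wpm, 8, 12)
  expect_equal(a$week, c(8L, 16L))
  expect_equal(a$response, c("SD", "PD"))
  # progression at 7 weeks: PD already at the first visit
  b <- generate_assessments(7 / wpm, 8, 12)
  expect_equal(b$response[1], "PD")
  expect_equal(nrow(b), 1)
  # progression beyond the horizon: all visits SD
  cc <- generate_assessments(100, 6, 6)
  expect_true(all(cc$response == "SD"))
  expect_gte(max(cc$week) / wpm, 12 / wpm)  # covers >= 12 weeks
  # responder reads PR before progression
  d <- generate_assessments(10 / wpm, 8, 12, responder = TRUE)
  expect_equal(d$response, c("PR", "PD"))
})

test_that("planted ineligibility is exact and switchable", {
  p0 <- generate_trial_pair(scenario_config(ineligible_fraction = 0),
                            seed = 9)
  res0 <- apply_eligibility(p0$external$cohort,
                            default_eligibility_rules())
  expect_equal(nrow(res0$cohort), 90)

  p <- generate_trial_pair(scenario_config(ineligible_fraction = 0.5),
                           seed = 9)
  res <- apply_eligibility(p$external$cohort, default_eligibility_rules())
  expect_equal(nrow(res$cohort), 45)
})

test_that("drift = 0 yields commensurate control arms at scale", {
  cfg <- scenario_config(n_concurrent_control = 400, n_external_raw = 500,
                         ineligible_fraction = 0, drift = 0)
  p <- generate_trial_pair(cfg, seed = 10)
  cc <- p$current$cohort[p$current$cohort$arm == "control", ]
  est <- commensurability_check(cc, p$external$cohort, "pfs")
  expect_true(est$ci_low < 1 && 1 < est$ci_high)
  expect_equal(log(est$estimate), 0, tolerance = 0.25)
})

test_that("the generator recovers a planted treatment effect", {
  cfg <- scenario_config(treatment_log_hr = log(1.5),
                         n_experimental = 150,
                         n_concurrent_control = 130)
  set.seed(11)
  lhr <- vapply(1:15, function(r) {
    p <- generate_trial_pair(cfg, seed = 1000 + r)
    cur <- p$current$cohort
    log(weighted_cox_hr(cur$pfs_time, cur$pfs_event, cur$arm)$estimate)
  }, numeric(1))
  # covariate mixing attenuates the marginal effect slightly below the
  # conditional truth; allow the Monte Carlo band plus that attenuation
  expect_lt(abs(mean(lhr) - log(1.5)),
            3 * sd(lhr) / sqrt(15) + 0.08)
})

test_that("truth record supports brute-force recomputation of target quantities", {
  cfg <- scenario_config(treatment_log_hr = log(0.7))
  tm <- true_marginals(cfg, nsim = 30000, seed = 12)
  expect_true(tm$p_dc_experimental > 0 && tm$p_dc_experimental < 1)
  expect_true(tm$p_dc_control > 0 && tm$p_dc_control < 1)
  expect_equal(tm$true_conditional_hr, 0.7)
  # marginal HR is attenuated toward 1 relative to the conditional HR but
  # close to it at these covariate effect sizes
  expect_lt(abs(log(tm$marginal_hr) - log(0.7)), 0.12)
  expect_gt(tm$p_dc_experimental, tm$p_dc_control)  # protective effect
})

test_that("configuration validation rejects impossible inputs", {
  expect_error(scenario_config(weibull_shape = -1))
  expect_error(scenario_config(ineligible_fraction = 1.5))
  bad_cov <- scenario_config()$covariates
  bad_cov$current$region <- c(north_america = 0.5, europe = 0.2,
                              asia_pacific = 0.2)
  expect_error(scenario_config(covariates = bad_cov), "sum to 1")
})
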