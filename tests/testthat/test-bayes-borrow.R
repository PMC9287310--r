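test_that("degenerate commensurate prior (huge fixed tau) reproduces pooled-control inference", {
  set.seed(40)
  y <- c(rbinom(15, 1, 0.15), rbinom(13, 1, 0.3), rbinom(23, 1, 0.3))
  arm <- arm_labels(15, 13, 23)
  glued <- fit_binary_borrow(
    y, arm, priors = prior_spec("fixed", 1e8),
    mcmc = mcmc_settings(chains = 2, production = 10000, seed = 9))
  # direct pooled fit: external outcomes relabelled as concurrent controls
  pooled_arm <- ifelse(arm == "external_control", "concurrent_control", arm)
  pooled <- fit_binary_borrow(
    y, pooled_arm, mcmc = mcmc_settings(chains = 2, production = 10000,
                                        seed = 9))
  g_glued <- glued$summary[glued$summary$parameter == "gamma[2]", ]
  g_pooled <- pooled$summary[pooled$summary$parameter == "gamma[2]", ]
  expect_equal(g_glued$mean, g_pooled$mean, tolerance = 0.03)
  expect_equal(g_glued$sd, g_pooled$sd, tolerance = 0.05)
  expect_equal(glued$effect$estimate, pooled$effect$estimate,
               tolerance = 0.05)
})

test_that("exponential special case matches the conjugate gamma posterior", {
  # shape fixed at 1, no censoring, near-flat prior on the log rate: the
  # posterior of the arm rate mu is Gamma(n, sum t) exactly (change of
  # variables from a flat log-scale prior)
  set.seed(41)
  n <- 200
  t_exp <- rexp(n, 0.5); t_cc <- rexp(n, 0.3)
  fit <- fit_weibull_borrow(
    c(t_exp, t_cc), rep(1, 2 * n), arm_labels(n, n),
    priors = prior_spec("gamma", c(1, 1), effect_sd = 100),
    mcmc = mcmc_settings(chains = 2, production = 10000, seed = 4),
    fix_shape = 1)
  mu2 <- exp(as.matrix(fit$draws)[, "beta[2]"])
  s <- sum(t_cc)
  expect_equal(mean(mu2), n / s, tolerance = 0.02)
  expect_equal(unname(quantile(mu2, c(0.025, 0.975))),
               qgamma(c(0.025, 0.975), n, s), tolerance = 0.02)
})

test_that("identical seeds and settings reproduce the fit exactly", {
  set.seed(42)
  y <- c(rbinom(15, 1, 0.2), rbinom(13, 1, 0.3), rbinom(23, 1, 0.3))
  arm <- arm_labels(15, 13, 23)
  m <- mcmc_settings(chains = 2, production = 3000, seed = 77)
  f1 <- fit_binary_borrow(y, arm, mcmc = m)
  f2 <- fit_binary_borrow(y, arm, mcmc = m)
  expect_identical(f1$summary, f2$summary)
  f3 <- fit_binary_borrow(y, arm,
                          mcmc = mcmc_settings(chains = 2,
                                               production = 3000,
                                               seed = 78))
  expect_false(identical(f1$summary$median, f3$summary$median))
})

test_that("default-configuration fits converge on the standard synthetic fixture", {
  set.seed(43)
  y <- c(rbinom(15, 1, 0.2), rbinom(13, 1, 0.35), rbinom(23, 1, 0.3))
  arm <- arm_labels(15, 13, 23)
  fit <- fit_binary_borrow(y, arm, mcmc = mcmc_settings(seed = 10))
  expect_true(fit$converged)
  expect_true(all(fit$summary$rhat < 1.05, na.rm = TRUE))
  expect_true(all(fit$summary$ess > 400))
  expect_gt(fit$tau_mean, 0)
  expect_s3_class(fit$effect, "effect_estimate")
  expect_true(fit$effect$ci_low <= fit$effect$estimate &&
                fit$effect$estimate <= fit$effect$ci_high)
})

test_that("arm-validation errors fire before any sampling", {
  expect_error(fit_binary_borrow(c(0, 1), c("experimental", "external_control")),
               "concurrent_control")
  expect_error(fit_binary_borrow(c(0, 1), c("exp", "cc")), "arm labels")
  expect_error(
    fit_weibull_borrow(c(1, 2, 3), c(1, 0, 1),
                       arm_labels(1, 1, 1)),
    "at least one observed event")
})

test_that("tau sensitivity scan: single spec equals a direct fit, several specs tabulate", {
  set.seed(44)
  d <- sim_three_arm_exp(15, 13, 28)
  m <- mcmc_settings(chains = 1, production = 2000, burn_in = 300,
                     seed = 5)
  scan1 <- suppressWarnings(
    tau_sensitivity_scan(list(default = default_priors("pfs")),
                         times = d$times, events = d$events, arm = d$arm,
                         mcmc = m))
  direct <- suppressWarnings(
    fit_weibull_borrow(d$times, d$events, d$arm, mcmc = m))
  expect_equal(nrow(scan1), 1)
  expect_equal(scan1$estimate, direct$effect$estimate, tolerance = 1e-10)
  expect_equal(scan1$tau_mean, direct$tau_mean, tolerance = 1e-10)

  scan3 <- suppressWarnings(tau_sensitivity_scan(
    list(hc25 = prior_spec("half_cauchy", c(0, 25)),
         hc1 = prior_spec("half_cauchy", c(0, 1)),
         g11 = prior_spec("gamma", c(1, 1))),
    times = d$times, events = d$events, arm = d$arm, mcmc = m))
  expect_equal(scan3$spec, c("hc25", "hc1", "g11"))
  expect_true(all(is.finite(scan3$estimate)))
})

test_that("prior-posterior overlap separates weak from strongly informative data", {
  set.seed(45)
  m <- mcmc_settings(chains = 1, production = 4000, burn_in = 300, seed = 6)
  # strongly informative: large sample far in the prior tail
  y_strong <- c(rbinom(500, 1, 0.9), rbinom(500, 1, 0.88))
  strong <- fit_binary_borrow(y_strong, arm_labels(500, 500), mcmc = m)
  ov_strong <- prior_posterior_overlap(strong)
  expect_true(all(ov_strong$overlap >= 0 & ov_strong$overlap <= 1))
  expect_lt(ov_strong$overlap[ov_strong$parameter == "gamma[1]"], 0.5)
  # nearly no data: posterior stays close to the prior
  weak <- fit_binary_borrow(c(0, 1, 0, 1), arm_labels(2, 2), mcmc = m)
  ov_weak <- prior_posterior_overlap(weak)
  expect_gt(ov_weak$overlap[ov_weak$parameter == "gamma[1]"], 0.6)
})

test_that("control-vs-control commensurability diagnostic recovers exchangeability and drift", {
  # identical datasets: exact label symmetry gives an estimate of 1
  cc <- make_cohort(30, pfs = rexp(30, 0.3) + 0.01)
  ec <- cc
  ec$patient_id <- paste0("E", seq_len(30)); ec$trial <- "external"
  ec$os_time <- cc$os_time
  est <- commensurability_check(cc, ec, "pfs")
  expect_equal(est$estimate, 1, tolerance = 1e-6)

  # doubled hazard is recovered at large n
  set.seed(46)
  cc2 <- make_cohort(400, pfs = rexp(400, 0.2) + 1e-4)
  ec2 <- make_cohort(400, trial = "external", id_prefix = "E",
                     pfs = rexp(400, 0.4) + 1e-4)
  est2 <- commensurability_check(cc2, ec2, "pfs")
  expect_gt(est2$estimate, 1.7)
  expect_lt(est2$estimate, 2.35)

  # exchangeable draws: the interval covers 1 at about the nominal rate
  set.seed(47)
  covered <- vapply(1:20, function(i) {
    cc3 <- make_cohort(100, pfs = rexp(100, 0.3) + 1e-4)
    ec3 <- make_cohort(100, trial = "external", id_prefix = "E",
                       pfs = rexp(100, 0.3) + 1e-4)
    est3 <- commensurability_check(cc3, ec3, "pfs")
    est3$ci_low < 1 && 1 < est3$ci_high
  }, logical(1))
  expect_gte(sum(covered), 16)  # >= 80% of 20 at nominal 95%

  expect_error(commensurability_check(make_cohort(3, arm = "experimental"),
                                      ec2, "pfs"), "control-only")
})

test_that("model configuration round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("endpoint: os", "tau_family: half_cauchy",
               "tau_params: [0, 1]", "chains: 2", "production: 5000",
               "seed: 99"), path)
  cfg <- read_model_config(path)
  expect_equal(cfg$endpoint, "os")
  expect_equal(cfg$priors$tau_family, "half_cauchy")
  expect_equal(cfg$priors$tau_params, c(0, 1))
  expect_equal(cfg$mcmc$chains, 2)
  expect_equal(cfg$mcmc$seed, 99)
})
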