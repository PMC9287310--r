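# Synthetic two-trial generator.
#
# Emulates the structure the analysis assumes: a small current randomized
# trial (experimental + concurrent control, 6-weekly tumour assessments)
# and a larger completed historical trial contributing a raw control cohort
# (8-weekly assessments) that must survive eligibility filtering.  Latent
# progression drives both the PFS time and the visit-level assessment
# series, so the derived 12-week disease-control outcome and PFS are
# internally consistent; OS is progression plus an independent positive
# survival increment.  A `drift` term shifts the external-control linear
# predictor, giving direct control over commensurability.

.weeks_per_month <- 365.25 / 12 / 7   # ~4.348 weeks per month

#' Scenario configuration for the synthetic two-trial generator
#'
#' Defaults emulate the motivating study conditions: 15 experimental and 13
#' concurrent-control patients assessed 6-weekly, a 90-patient raw external
#' control cohort assessed 8-weekly of which roughly 28 survive the
#' eligibility filter, control median progression-free survival of about
#' 2.8 months, median post-progression survival of about 7.5 months,
#' covariate prevalences drawn from the two trial populations (including
#' the strong region imbalance between a mainly-European historical cohort
#' and a North-America/Asia-Pacific current trial), and nonzero ECOG and
#' liver-metastasis effects on outcome so that the trials are genuinely
#' confounded when prevalences differ.  `drift = 0` makes the external and
#' concurrent outcome generators identical conditional on covariates.
#'
#' @param n_experimental,n_concurrent_control,n_external_raw cohort sizes.
#' @param treatment_log_hr true treatment effect on the log-hazard scale
#'   (0 = null).
#' @param treatment_log_or true treatment effect on the log-odds of a
#'   CR/PR response (0 = null).
#' @param control_log_hazard baseline log progression hazard per month.
#' @param control_logit_p baseline log-odds of a CR/PR response.
#' @param drift additive shift applied to the external-control linear
#'   predictor (log-hazard and response logit); 0 = perfectly commensurate.
#' @param weibull_shape Weibull shape of the progression time (1 =
#'   exponential).
#' @param os_increment_rate rate (per month) of the exponential
#'   post-progression survival increment.
#' @param beta_ecog,beta_liver covariate effects on the log hazard.
#' @param horizon_current,horizon_external administrative censoring
#'   horizons in months.
#' @param assessment_interval_current,assessment_interval_external visit
#'   spacing in weeks.
#' @param ineligible_fraction fraction of raw external records planted to
#'   fail an eligibility rule (default 62/90, so 28 of 90 survive).
#' @param covariates per-trial covariate distributions; see the default
#'   for the expected structure (`age` mean/sd, `tfd` meanlog/sdlog for
#'   months since metastatic diagnosis, and category probabilities).
#' @return A `scenario_config` list.
#' @export
scenario_config <- function(n_experimental = 15,
                            n_concurrent_control = 13,
                            n_external_raw = 90,
                            treatment_log_hr = 0,
                            treatment_log_or = 0,
                            control_log_hazard = log(log(2) / 2.8),
                            control_logit_p = stats::qlogis(0.02),
                            drift = 0,
                            weibull_shape = 1,
                            os_increment_rate = log(2) / 7.5,
                            beta_ecog = 0.4,
                            beta_liver = 0.3,
                            horizon_current = 18,
                            horizon_external = 30,
                            assessment_interval_current = 6,
                            assessment_interval_external = 8,
                            ineligible_fraction = 62 / 90,
                            covariates = NULL) {
  if (is.null(covariates)) {
    covariates <- list(
      current = list(age = c(mean = 55, sd = 11),
                     tfd = c(meanlog = log(20), sdlog = 0.55),
                     sex_male = 0.55,
                     region = c(north_america = 0.60, europe = 0.10,
                                asia_pacific = 0.30),
                     ecog1 = 0.62, liver_yes = 0.64,
                     ras_mutant = 0.55, race_nonwhite = 0.30),
      external = list(age = c(mean = 57, sd = 10),
                      tfd = c(meanlog = log(25), sdlog = 0.55),
                      sex_male = 0.57,
                      region = c(north_america = 0.21, europe = 0.61,
                                 asia_pacific = 0.18),
                      ecog1 = 0.54, liver_yes = 0.64,
                      ras_mutant = 0.62, race_nonwhite = 0.16))
  }
  for (tr in names(covariates)) {
    r <- covariates[[tr]]$region
    if (abs(sum(r) - 1) > 1e-8)
      stop("region probabilities must sum to 1 (", tr, ")", call. = FALSE)
    probs <- unlist(r)
    if (any(probs < 0 | probs > 1))
      stop("invalid probability in covariate config", call. = FALSE)
  }
  stopifnot(weibull_shape > 0, os_increment_rate > 0,
            ineligible_fraction >= 0, ineligible_fraction <= 1)
  structure(list(
    n_experimental = n_experimental,
    n_concurrent_control = n_concurrent_control,
    n_external_raw = n_external_raw,
    treatment_log_hr = treatment_log_hr,
    treatment_log_or = treatment_log_or,
    control_log_hazard = control_log_hazard,
    control_logit_p = control_logit_p,
    drift = drift,
    weibull_shape = weibull_shape,
    os_increment_rate = os_increment_rate,
    beta_ecog = beta_ecog,
    beta_liver = beta_liver,
    horizon_current = horizon_current,
    horizon_external = horizon_external,
    assessment_interval_current = assessment_interval_current,
    assessment_interval_external = assessment_interval_external,
    ineligible_fraction = ineligible_fraction,
    covariates = covariates), class = "scenario_config")
}

.draw_covariates <- function(n, dist, trial, id_prefix) {
  data.frame(
    patient_id = sprintf("%s%03d", id_prefix, seq_len(n)),
    trial = trial,
    age = pmax(round(stats::rnorm(n, dist$age["mean"], dist$age["sd"]), 1),
               18),
    sex = ifelse(stats::runif(n) < dist$sex_male, "male", "female"),
    race = ifelse(stats::runif(n) < dist$race_nonwhite, "nonwhite", "white"),
    region = sample(names(dist$region), n, replace = TRUE,
                    prob = dist$region),
    ecog = as.character(as.integer(stats::runif(n) < dist$ecog1)),
    liver_mets = ifelse(stats::runif(n) < dist$liver_yes, "yes", "no"),
    time_from_met_dx = round(stats::rlnorm(n, dist$tfd["meanlog"],
                                           dist$tfd["sdlog"]), 1),
    ras_status = ifelse(stats::runif(n) < dist$ras_mutant, "mutant",
                        "wild_type"),
    stringsAsFactors = FALSE)
}

.linear_predictor <- function(config, cov, treated, external) {
  config$control_log_hazard +
    treated * config$treatment_log_hr +
    external * config$drift +
    config$beta_ecog * (cov$ecog == "1") +
    config$beta_liver * (cov$liver_mets == "yes")
}

.rweib_hazard <- function(n, shape, mu) {
  # S(t) = exp(-mu t^shape)  =>  t = (-log U / mu)^(1/shape)
  (-log(stats::runif(n)) / mu)^(1 / shape)
}

#' Generate the visit-level assessment series implied by a progression time
#'
#' Scheduled visits before progression read SD (or PR for a responder), the
#' first visit at or after progression reads PD, and the series stops at
#' the administrative horizon.
#'
#' @param progression_time months to progression.
#' @param schedule_weeks visit spacing in weeks.
#' @param horizon_months administrative follow-up horizon.
#' @param responder if `TRUE`, visits before progression read PR.
#' @return Data frame with `week`, `response` (possibly zero rows when the
#'   first scheduled visit falls after the horizon).
#' @export
generate_assessments <- function(progression_time, schedule_weeks,
                                 horizon_months, responder = FALSE) {
  stopifnot(progression_time > 0, schedule_weeks > 0, horizon_months > 0)
  weeks <- seq(schedule_weeks, ceiling(horizon_months * .weeks_per_month),
               by = schedule_weeks)
  weeks <- weeks[weeks / .weeks_per_month <= horizon_months + 1e-9]
  if (length(weeks) == 0L)
    return(data.frame(week = integer(0), response = character(0),
                      stringsAsFactors = FALSE))
  months <- weeks / .weeks_per_month
  response <- ifelse(months < progression_time,
                     if (responder) "PR" else "SD", "PD")
  first_pd <- match("PD", response)
  if (!is.na(first_pd) && first_pd < length(response))
    response <- response[seq_len(first_pd)]
  data.frame(week = as.integer(weeks[seq_along(response)]),
             response = response, stringsAsFactors = FALSE)
}

.generate_outcomes <- function(config, cov, treated, external, horizon,
                               schedule_weeks) {
  n <- nrow(cov)
  mu <- exp(.linear_predictor(config, cov, treated, external))
  prog <- .rweib_hazard(n, config$weibull_shape, mu)
  responder <- stats::runif(n) < stats::plogis(
    config$control_logit_p + treated * config$treatment_log_or +
      external * config$drift)
  death <- prog + stats::rexp(n, config$os_increment_rate)
  # floor at 0.001 months so rounding can never produce a zero time
  cov$pfs_time <- pmax(round(pmin(prog, horizon), 4), 1e-3)
  cov$pfs_event <- as.integer(prog <= horizon)
  cov$os_time <- pmax(round(pmin(death, horizon), 4), 1e-3)
  cov$os_event <- as.integer(death <= horizon)
  # guard the validator's pfs <= os invariant against rounding at the cap
  cov$os_time <- pmax(cov$os_time, cov$pfs_time)
  assessments <- do.call(rbind, lapply(seq_len(n), function(i) {
    a <- generate_assessments(prog[i], schedule_weeks, horizon,
                              responder[i])
    if (nrow(a) == 0L) return(NULL)
    cbind(patient_id = cov$patient_id[i], a, stringsAsFactors = FALSE)
  }))
  if (is.null(assessments))
    assessments <- data.frame(patient_id = character(0), week = integer(0),
                              response = character(0),
                              stringsAsFactors = FALSE)
  list(cohort = cov, assessments = assessments,
       latent = data.frame(patient_id = cov$patient_id,
                           progression = prog, responder = responder,
                           stringsAsFactors = FALSE))
}

#' Generate a matched pair of synthetic trials
#'
#' Draws the current trial (randomized experimental and concurrent-control
#' arms) and the raw external-control cohort, each with covariates from its
#' own trial-specific distribution, Weibull progression times driven by a
#' shared linear predictor (treatment effect, ECOG and liver-metastasis
#' effects, plus `drift` for the external cohort only), administrative
#' censoring, assessment series on each trial's visit schedule, and planted
#' eligibility violations in the external cohort.
#'
#' @param config a [scenario_config()].
#' @param seed integer seed; the full output is a deterministic function of
#'   `(config, seed)`.
#' @return List with `current` (`$cohort`, `$assessments`), `external`
#'   (`$cohort` including eligibility columns `line_of_therapy`,
#'   `prior_chemo`, `biomarker_excluded`; `$assessments`), and `truth`
#'   (every generating parameter plus per-patient latent progression
#'   times).
#' @export
generate_trial_pair <- function(config = scenario_config(), seed = 1) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(seed)
  cur_cov <- .draw_covariates(
    config$n_experimental + config$n_concurrent_control,
    config$covariates$current, "current", "CUR")
  treated <- rep(c(1, 0), c(config$n_experimental,
                            config$n_concurrent_control))
  cur_cov$arm <- ifelse(treated == 1, "experimental", "control")
  cur <- .generate_outcomes(config, cur_cov, treated, external = 0,
                            horizon = config$horizon_current,
                            schedule_weeks = config$assessment_interval_current)

  ext_cov <- .draw_covariates(config$n_external_raw,
                              config$covariates$external, "external", "EXT")
  ext_cov$arm <- "control"
  ext <- .generate_outcomes(config, ext_cov, treated = 0, external = 1,
                            horizon = config$horizon_external,
                            schedule_weeks = config$assessment_interval_external)

  # plant eligibility violations: first n_inelig records fail one of the
  # three default rules (assignment shuffled so violations are not
  # correlated with outcomes, which were drawn before this step)
  n <- config$n_external_raw
  n_inelig <- round(config$ineligible_fraction * n)
  ext$cohort$line_of_therapy <- 3L
  ext$cohort$prior_chemo <- "yes"
  ext$cohort$biomarker_excluded <- "no"
  if (n_inelig > 0) {
    which_bad <- sample.int(n, n_inelig)
    rule_of <- rep(1:3, length.out = n_inelig)
    ext$cohort$line_of_therapy[which_bad[rule_of == 1]] <- 2L
    ext$cohort$prior_chemo[which_bad[rule_of == 2]] <- "no"
    ext$cohort$biomarker_excluded[which_bad[rule_of == 3]] <- "yes"
  }

  order_cols <- function(df) {
    extra <- setdiff(names(df), .patient_required)
    df[, c(.patient_required, extra), drop = FALSE]
  }
  cur$cohort <- order_cols(cur$cohort)
  ext$cohort <- order_cols(ext$cohort)
  validate_cohort(cur$cohort)
  validate_cohort(ext$cohort)

  truth <- list(config = config, seed = seed,
                true_hr = exp(config$treatment_log_hr),
                true_or_response = exp(config$treatment_log_or),
                latent_current = cur$latent, latent_external = ext$latent)
  list(current = list(cohort = cur$cohort,
                      assessments = cur$assessments),
       external = list(cohort = ext$cohort,
                       assessments = ext$assessments),
       truth = truth)
}

#' Monte-Carlo true marginal quantities implied by a scenario
#'
#' Recomputes, by brute-force simulation from the stored generating
#' parameters, the marginal quantities the estimators target: the
#' disease-control probability per arm and the marginal hazard ratio (from
#' a large uncensored two-arm draw).
#'
#' @param config a [scenario_config()].
#' @param nsim Monte Carlo size.
#' @param seed integer seed.
#' @return List with `p_dc_experimental`, `p_dc_control`,
#'   `true_conditional_hr`, `marginal_hr`.
#' @export
true_marginals <- function(config = scenario_config(), nsim = 50000,
                           seed = 1) {
  set.seed(seed)
  cov <- .draw_covariates(nsim, config$covariates$current, "current", "MC")
  dc_prob <- function(treated) {
    mu <- exp(.linear_predictor(config, cov, treated, external = 0))
    prog <- .rweib_hazard(nsim, config$weibull_shape, mu)
    resp <- stats::runif(nsim) < stats::plogis(
      config$control_logit_p + treated * config$treatment_log_or)
    # disease control: response, or progression after the week-12 visit
    twelve <- 12 / .weeks_per_month
    mean(resp | prog > twelve)
  }
  mu0 <- exp(.linear_predictor(config, cov, 0, 0))
  mu1 <- exp(.linear_predictor(config, cov, 1, 0))
  t0 <- .rweib_hazard(nsim, config$weibull_shape, mu0)
  t1 <- .rweib_hazard(nsim, config$weibull_shape, mu1)
  fit <- survival::coxph(
    survival::Surv(c(t0, t1), rep(1, 2 * nsim)) ~ rep(0:1, each = nsim))
  list(p_dc_experimental = dc_prob(1), p_dc_control = dc_prob(0),
       true_conditional_hr = exp(config$treatment_log_hr),
       marginal_hr = unname(exp(stats::coef(fit))))
}
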