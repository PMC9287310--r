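# Static-borrowing (frequentist) effect estimation: exact binomial rate
# intervals, SMR-weighted logistic and Cox fits with robust sandwich
# variance, and weighted Kaplan-Meier curves.

#' Effect-estimate record
#'
#' Uniform one-row container for an odds- or hazard-ratio estimate with its
#' interval and provenance.  The direction convention is fixed throughout
#' the package: experimental vs control, so values above 1 mean higher odds
#' of disease control (OR) or higher hazard (HR) under the experimental
#' treatment.
#'
#' @param endpoint `"dcr"`, `"pfs"` or `"os"`.
#' @param measure `"odds_ratio"` or `"hazard_ratio"`.
#' @param estimate,ci_low,ci_high positive reals with
#'   `ci_low <= estimate <= ci_high`.
#' @param comparator `"concurrent_control"`, `"hybrid_control"` or
#'   `"external_only"`.
#' @param method `"frequentist_smrw"` or `"bayesian_commensurate"`.
#' @param ci_level interval level (default 0.95).
#' @param n_experimental,n_control_effective sample sizes (effective size =
#'   sum of control weights).
#' @return One-row data frame of class `effect_estimate`.
#' @export
effect_estimate <- function(endpoint, measure, estimate, ci_low, ci_high,
                            comparator, method, ci_level = 0.95,
                            n_experimental = NA_real_,
                            n_control_effective = NA_real_) {
  stopifnot(estimate > 0, ci_low > 0, ci_high > 0,
            ci_low <= estimate + 1e-12, estimate <= ci_high + 1e-12)
  out <- data.frame(endpoint = endpoint, measure = measure,
                    estimate = estimate, ci_low = ci_low, ci_high = ci_high,
                    ci_level = ci_level, comparator = comparator,
                    method = method, n_experimental = n_experimental,
                    n_control_effective = n_control_effective,
                    stringsAsFactors = FALSE)
  class(out) <- c("effect_estimate", "data.frame")
  out
}

#' Exact (Clopper-Pearson) binomial confidence interval
#'
#' Two-sided exact interval from beta quantiles: the lower bound is 0 iff
#' there are no successes and the upper bound is 1 iff all trials succeed.
#' The closed-form upper bound at zero successes is
#' `1 - (alpha/2)^(1/total)`.
#'
#' @param successes,total counts with `0 <= successes <= total`,
#'   `total >= 1`.
#' @param level two-sided confidence level (default 0.95).
#' @return List of class `rate_ci`: `successes`, `total`, `rate`, `ci_low`,
#'   `ci_high`, `ci_level`.
#' @export
clopper_pearson <- function(successes, total, level = 0.95) {
  if (total < 1) stop("total must be >= 1", call. = FALSE)
  stopifnot(successes >= 0, successes <= total)
  alpha <- 1 - level
  lo <- if (successes == 0) 0 else
    stats::qbeta(alpha / 2, successes, total - successes + 1)
  hi <- if (successes == total) 1 else
    stats::qbeta(1 - alpha / 2, successes + 1, total - successes)
  structure(list(successes = successes, total = total,
                 rate = successes / total, ci_low = lo, ci_high = hi,
                 ci_level = level),
            class = "rate_ci")
}

#' @export
print.rate_ci <- function(x, ...) {
  cat(sprintf("%d/%d = %.1f%% [%.1f, %.1f] (%.0f%% exact CI)\n",
              x$successes, x$total, 100 * x$rate, 100 * x$ci_low,
              100 * x$ci_high, 100 * x$ci_level))
  invisible(x)
}

#' Robust (sandwich) variance of a fitted model's coefficients
#'
#' HC0-type sandwich treating each patient as one independent cluster:
#' bread = inverse information, meat = sum of weighted score outer
#' products.  For `coxph` fits request `robust = TRUE` at fit time, in
#' which case the stored variance is already the sandwich.
#'
#' @param fit a `glm` or a `coxph` fit.
#' @return Variance-covariance matrix of the coefficients.
#' @export
robust_variance <- function(fit) {
  if (inherits(fit, "coxph")) {
    if (is.null(fit$naive.var))
      stop("coxph fit was not run with robust = TRUE", call. = FALSE)
    return(stats::vcov(fit))
  }
  if (inherits(fit, "glm") || inherits(fit, "lm"))
    return(sandwich::vcovHC(fit, type = "HC0"))
  stop("unsupported fit class: ", paste(class(fit), collapse = "/"),
       call. = FALSE)
}

.check_arm_factor <- function(arm) {
  arm <- as.character(arm)
  if (!all(arm %in% c("experimental", "control")))
    stop("arm labels must be 'experimental'/'control'", call. = FALSE)
  factor(arm, levels = c("control", "experimental"))
}

#' Weighted logistic regression odds ratio
#'
#' Single-covariate (treatment group) logistic fit maximizing the
#' weight-multiplied log-likelihood; the interval uses the HC0 sandwich
#' variance so the weighting-induced pseudo-population dependence does not
#' bias the standard error.  With unit weights and all four 2x2 cells
#' positive the point estimate is the exact cross-product ratio.
#'
#' @param outcome 0/1 disease-control indicator (unknown outcomes must be
#'   excluded beforehand).
#' @param arm `"experimental"` / `"control"` labels.
#' @param weights per-patient nonnegative weights (default all 1).
#' @param level confidence level.
#' @param endpoint,comparator metadata passed into the estimate record.
#' @return An [effect_estimate()] row (odds ratio, experimental vs control).
#' @export
weighted_logistic_or <- function(outcome, arm, weights = NULL, level = 0.95,
                                 endpoint = "dcr",
                                 comparator = "hybrid_control") {
  arm <- .check_arm_factor(arm)
  if (is.null(weights)) weights <- rep(1, length(outcome))
  stopifnot(length(outcome) == length(arm),
            length(weights) == length(arm), all(weights >= 0))
  if (!all(outcome %in% c(0, 1)))
    stop("outcome must be 0/1", call. = FALSE)
  ev <- tapply(outcome, arm, sum)
  tot <- tapply(outcome, arm, length)
  if (any(is.na(ev)) || length(unique(arm)) < 2)
    stop("both arms must be represented", call. = FALSE)
  if (any(ev == 0) || any(ev == tot))
    stop("zero (or saturated) events in an arm; use exact methods instead",
         call. = FALSE)
  dat <- data.frame(outcome = outcome, arm = arm, .w = weights)
  fit <- suppressWarnings(
    stats::glm(outcome ~ arm, data = dat, weights = .w,
               family = stats::quasibinomial()))
  b <- stats::coef(fit)["armexperimental"]
  se <- sqrt(robust_variance(fit)["armexperimental", "armexperimental"])
  z <- stats::qnorm(1 - (1 - level) / 2)
  effect_estimate(endpoint, "odds_ratio", exp(b), exp(b - z * se),
                  exp(b + z * se), comparator, "frequentist_smrw",
                  ci_level = level,
                  n_experimental = sum(arm == "experimental"),
                  n_control_effective = sum(weights[arm == "control"]))
}

#' Weighted Cox proportional-hazards hazard ratio
#'
#' Weighted partial likelihood with the treatment indicator as the sole
#' covariate, Efron tie handling, and the robust sandwich variance (each
#' patient is one cluster).
#'
#' @param times positive event/censoring times.
#' @param events 0/1 event indicators.
#' @param arm `"experimental"` / `"control"` labels.
#' @param weights per-patient weights (default all 1).
#' @param level confidence level.
#' @param endpoint,comparator metadata for the estimate record.
#' @return An [effect_estimate()] row (hazard ratio, experimental vs
#'   control).
#' @export
weighted_cox_hr <- function(times, events, arm, weights = NULL,
                            level = 0.95, endpoint = "pfs",
                            comparator = "hybrid_control") {
  arm <- .check_arm_factor(arm)
  if (is.null(weights)) weights <- rep(1, length(times))
  stopifnot(all(times > 0), all(events %in% c(0, 1)), all(weights >= 0))
  if (any(tapply(events, arm, sum) < 1))
    stop("need at least one event per arm", call. = FALSE)
  dat <- data.frame(times = times, events = events, arm = arm, .w = weights)
  fit <- survival::coxph(survival::Surv(times, events) ~ arm, data = dat,
                         weights = .w, robust = TRUE, ties = "efron",
                         control = survival::coxph.control(eps = 1e-11,
                                                           iter.max = 50))
  b <- stats::coef(fit)["armexperimental"]
  se <- sqrt(robust_variance(fit)["armexperimental", "armexperimental"])
  z <- stats::qnorm(1 - (1 - level) / 2)
  effect_estimate(endpoint, "hazard_ratio", exp(b), exp(b - z * se),
                  exp(b + z * se), comparator, "frequentist_smrw",
                  ci_level = level,
                  n_experimental = sum(arm == "experimental"),
                  n_control_effective = sum(weights[arm == "control"]))
}

#' Weighted Kaplan-Meier curve with median and log-log interval
#'
#' Product-limit estimator with weighted risk and event counts.  The median
#' is the first time the curve drops to 0.5 or below; its interval uses the
#' log-log (Brookmeyer-Crowley style) transform, with open-ended bounds
#' reported as `NA` ("not estimable").  The curve is invariant to rescaling
#' all weights by a constant.
#'
#' @param times positive event/censoring times.
#' @param events 0/1 event indicators.
#' @param weights per-patient weights (default all 1).
#' @param level confidence level for the median interval.
#' @return List of class `survival_curve`: `times`, `survival`, `median`,
#'   `median_ci` (length-2, possibly NA), `weighted`, plus the underlying
#'   `survfit` object in `fit`.
#' @export
weighted_km <- function(times, events, weights = NULL, level = 0.95) {
  if (is.null(weights)) weights <- rep(1, length(times))
  stopifnot(all(times > 0), all(events %in% c(0, 1)), all(weights > 0))
  dat <- data.frame(times = times, events = events, .w = weights)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1, data = dat,
                           weights = .w, conf.type = "log-log",
                           conf.int = level)
  med <- summary(fit)$table
  structure(list(times = fit$time, survival = fit$surv,
                 median = unname(med["median"]),
                 median_ci = unname(c(med["0.95LCL"], med["0.95UCL"])),
                 weighted = !all(weights == weights[1]) ||
                   !isTRUE(all.equal(weights[1], 1)),
                 fit = fit),
            class = "survival_curve")
}

#' @export
print.survival_curve <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "NE" else sprintf("%.2f", v)
  cat(sprintf("Kaplan-Meier curve (%s): median %s (%s-%s) months\n",
              if (x$weighted) "weighted" else "unweighted",
              fmt(x$median), fmt(x$median_ci[1]), fmt(x$median_ci[2])))
  invisible(x)
}

#' Frequentist treatment-effect estimate against a chosen comparator
#'
#' Dispatches to the weighted logistic (DCR) or weighted Cox (PFS/OS) fit.
#' The concurrent-control comparison is a randomized contrast and is
#' computed unweighted; the hybrid comparison gives concurrent controls
#' weight 1 and external controls their SMR weights; the external-only
#' comparison uses SMR weights alone.
#'
#' @param weighted a `weighted_cohort` (see [fit_propensity()]) containing
#'   the experimental arm and the control sources, with a `dcr` 0/1 column
#'   when `endpoint = "dcr"` (unknown outcomes already excluded).
#' @param endpoint `"dcr"`, `"pfs"` or `"os"`.
#' @param comparator `"hybrid_control"`, `"concurrent_control"` or
#'   `"external_only"`.
#' @param level confidence level.
#' @return An [effect_estimate()] row.
#' @export
estimate_frequentist <- function(weighted, endpoint = c("dcr", "pfs", "os"),
                                 comparator = c("hybrid_control",
                                                "concurrent_control",
                                                "external_only"),
                                 level = 0.95) {
  endpoint <- match.arg(endpoint)
  comparator <- match.arg(comparator)
  exp_arm <- weighted[weighted$arm == "experimental", , drop = FALSE]
  ctrl <- switch(comparator,
    concurrent_control = weighted[weighted$arm == "control" &
                                    weighted$trial == "current", , drop = FALSE],
    external_only = weighted[weighted$trial == "external", , drop = FALSE],
    hybrid_control = weighted[weighted$arm == "control", , drop = FALSE])
  if (nrow(ctrl) == 0L) stop("comparator cohort is empty", call. = FALSE)
  dat <- rbind(exp_arm, ctrl)
  w <- if (comparator == "concurrent_control") rep(1, nrow(dat))
       else dat$weight
  if (endpoint == "dcr") {
    if (!"dcr" %in% names(dat))
      stop("cohort needs a 0/1 'dcr' column for the DCR endpoint",
           call. = FALSE)
    keep <- !is.na(dat$dcr)
    weighted_logistic_or(dat$dcr[keep], dat$arm[keep], w[keep],
                         level = level, endpoint = endpoint,
                         comparator = comparator)
  } else {
    tcol <- paste0(endpoint, "_time")
    ecol <- paste0(endpoint, "_event")
    weighted_cox_hr(dat[[tcol]], dat[[ecol]], dat$arm, w, level = level,
                    endpoint = endpoint, comparator = comparator)
  }
}
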