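# Propensity-score estimation between the experimental arm and the
# external-control cohort, standardized-mortality-ratio (SMR) weighting, and
# balance diagnostics.
#
# SMR weighting anchors the estimand to the experimental arm's covariate
# population: index patients keep weight 1 and each external patient is
# weighted by the odds e(x)/(1 - e(x)) of experimental-arm membership.
# Randomized concurrent controls are not in the propensity model and carry
# weight 1.

#' Propensity model specification
#'
#' The default covariate set is the usual prognostic quintet for the
#' refractory metastatic setting: age, sex, presence of liver metastases,
#' time from metastatic diagnosis to baseline (dichotomized at 18 months),
#' and ECOG performance status (0 vs 1).
#'
#' @param covariates character vector of cohort columns entering the
#'   logistic group-membership model.  `time_from_met_dx` is automatically
#'   dichotomized at `dichotomize_tfd_at` months.
#' @param dichotomize_tfd_at cutpoint in months for `time_from_met_dx`.
#' @return A `ps_model_spec` list.
#' @export
ps_model_spec <- function(covariates = c("age", "sex", "liver_mets",
                                         "time_from_met_dx", "ecog"),
                          dichotomize_tfd_at = 18) {
  structure(list(covariates = covariates,
                 dichotomize_tfd_at = dichotomize_tfd_at,
                 link = "logit"),
            class = "ps_model_spec")
}

.ps_design <- function(cohort, spec) {
  X <- data.frame(row.names = seq_len(nrow(cohort)))
  for (cv in spec$covariates) {
    if (!cv %in% names(cohort))
      stop("propensity covariate '", cv, "' not in cohort", call. = FALSE)
    x <- cohort[[cv]]
    if (cv == "time_from_met_dx") {
      X[[paste0("tfd_gt", spec$dichotomize_tfd_at)]] <-
        as.numeric(x > spec$dichotomize_tfd_at)
    } else if (is.numeric(x)) {
      X[[cv]] <- x
    } else {
      x <- as.character(x)
      x[x == "unknown"] <- NA
      X[[cv]] <- as.numeric(x == sort(unique(stats::na.omit(x)))[1])
      # reference coding on the alphabetically first observed level
      names(X)[ncol(X)] <- paste0(cv, "_", sort(unique(stats::na.omit(x)))[1])
    }
  }
  X
}

#' Fit the propensity model and attach SMR weights
#'
#' Logistic regression of experimental-arm membership (experimental = 1,
#' external control = 0), linear in the specified covariates.  The fit uses
#' complete cases only (a message reports how many records were dropped from
#' the fit); propensity scores for those records are still predicted when
#' possible.  Concurrent controls, if supplied, bypass the model entirely
#' and carry weight 1.
#'
#' @param experimental experimental-arm cohort.
#' @param external external-control cohort.
#' @param concurrent optional concurrent-control cohort (pass-through,
#'   weight 1).
#' @param spec a [ps_model_spec()].
#' @param max_weight optional cap applied to external weights
#'   (`Inf` = no trimming, the default).
#' @return A `weighted_cohort`: the row-bound cohorts with `ps` and
#'   `weight` columns and the fitted `glm` in attribute `ps_fit`.
#' @export
fit_propensity <- function(experimental, external, concurrent = NULL,
                           spec = ps_model_spec(), max_weight = Inf) {
  if (nrow(experimental) == 0L || nrow(external) == 0L)
    stop("experimental and external cohorts must be non-empty", call. = FALSE)
  shared <- intersect(names(experimental), names(external))
  fit_cohort <- rbind(
    cbind(experimental[, shared, drop = FALSE], .ps_group = 1L),
    cbind(external[, shared, drop = FALSE], .ps_group = 0L))
  X <- .ps_design(fit_cohort, spec)
  dat <- cbind(.ps_group = fit_cohort$.ps_group, X)
  cc <- stats::complete.cases(dat)
  if (sum(!cc) > 0)
    message(sum(!cc), " record(s) dropped from the propensity fit ",
            "(incomplete covariates)")
  fit <- suppressWarnings(
    stats::glm(.ps_group ~ ., data = dat[cc, , drop = FALSE],
               family = stats::binomial()))
  if (!fit$converged || any(abs(stats::coef(fit)[-1]) > 15, na.rm = TRUE))
    stop("propensity model did not converge (possible perfect separation); ",
         "reduce the covariate set", call. = FALSE)
  ps <- rep(NA_real_, nrow(fit_cohort))
  pred_ok <- stats::complete.cases(X)
  ps[pred_ok] <- stats::predict(fit, newdata = X[pred_ok, , drop = FALSE],
                                type = "response")
  w <- ifelse(fit_cohort$.ps_group == 1L, 1, ps / (1 - ps))
  w <- pmin(w, max_weight)
  out <- fit_cohort[, setdiff(names(fit_cohort), ".ps_group"), drop = FALSE]
  out$ps <- ps
  out$weight <- w
  if (!is.null(concurrent) && nrow(concurrent) > 0) {
    concurrent$ps <- NA_real_
    concurrent$weight <- 1
    out <- rbind(out, concurrent[, names(out), drop = FALSE])
  }
  rownames(out) <- NULL
  attr(out, "ps_fit") <- fit
  class(out) <- c("weighted_cohort", "data.frame")
  out
}

#' Standardized mean difference for a binary covariate
#'
#' `|p1 - p2| / sqrt((p1 (1 - p1) + p2 (1 - p2)) / 2)`.  Symmetric in the
#' two groups and in category relabelling; the degenerate 0/0 case (both
#' proportions equal at 0 or 1) is resolved to 0.
#'
#' @param p1,p2 group proportions in `[0, 1]`.
#' @return Nonnegative SMD.
#' @export
smd_binary <- function(p1, p2) {
  stopifnot(p1 >= 0, p1 <= 1, p2 >= 0, p2 <= 1)
  denom <- sqrt((p1 * (1 - p1) + p2 * (1 - p2)) / 2)
  if (denom == 0) return(0)
  abs(p1 - p2) / denom
}

#' Standardized mean difference for a continuous covariate
#'
#' `|m1 - m2| / sqrt((s1^2 + s2^2) / 2)`.
#'
#' @param mean1,sd1,mean2,sd2 group means and standard deviations.
#' @return Nonnegative SMD.
#' @export
smd_continuous <- function(mean1, sd1, mean2, sd2) {
  stopifnot(sd1 >= 0, sd2 >= 0)
  denom <- sqrt((sd1^2 + sd2^2) / 2)
  if (denom == 0) {
    if (isTRUE(all.equal(mean1, mean2))) return(0)
    stop("zero variance in both groups with unequal means", call. = FALSE)
  }
  abs(mean1 - mean2) / denom
}

#' Standardized mean difference for a multi-category covariate
#'
#' Mahalanobis form: `sqrt(T' S^-1 T)` where `T` holds the differences of
#' the first `k - 1` category proportions and `S` averages the two
#' multinomial covariance matrices.  Reduces exactly to [smd_binary()] at
#' `k = 2`.  A singular `S` falls back to the Moore-Penrose generalized
#' inverse with a warning.
#'
#' @param props1,props2 probability vectors over the same `k >= 2`
#'   categories (each sums to 1).
#' @return Nonnegative SMD.
#' @export
smd_multicategory <- function(props1, props2) {
  k <- length(props1)
  stopifnot(k >= 2, length(props2) == k)
  if (abs(sum(props1) - 1) > 1e-6 || abs(sum(props2) - 1) > 1e-6)
    stop("category proportions must each sum to 1", call. = FALSE)
  idx <- seq_len(k - 1)
  Tv <- (props1 - props2)[idx]
  covm <- function(p) diag(p[idx], k - 1) - outer(p[idx], p[idx])
  S <- (covm(props1) + covm(props2)) / 2
  Sinv <- tryCatch(solve(S), error = function(e) {
    warning("singular multinomial covariance; using generalized inverse",
            call. = FALSE)
    MASS::ginv(S)
  })
  val <- drop(t(Tv) %*% Sinv %*% Tv)
  sqrt(max(val, 0))
}

.wmean <- function(x, w) sum(w * x) / sum(w)
.wvar <- function(x, w) {
  m <- .wmean(x, w)
  sum(w * (x - m)^2) / sum(w)
}

#' Weighted and unweighted balance table
#'
#' Compares the experimental arm (weight 1) with the external-control arm,
#' unweighted and under the SMR weights, one row per covariate.  Continuous
#' covariates use weighted means/variances; binary covariates weighted
#' proportions; covariates with three or more observed levels the
#' Mahalanobis multinomial SMD.  `"unknown"` levels are excluded before
#' computing proportions.  The conventional acceptability threshold is
#' `smd_weighted < 0.25`.
#'
#' @param weighted a `weighted_cohort` from [fit_propensity()].
#' @param covariates cohort columns to tabulate.
#' @param threshold balance flag cutoff (default 0.25).
#' @return Data frame: `covariate`, `smd_unweighted`, `smd_weighted`,
#'   `balanced` (NA for a covariate that is all-missing in either group).
#' @export
balance_table <- function(weighted,
                          covariates = c("age", "sex", "liver_mets",
                                         "time_from_met_dx", "ecog"),
                          threshold = 0.25) {
  exp_arm <- weighted[weighted$arm == "experimental", , drop = FALSE]
  ext <- weighted[weighted$trial == "external", , drop = FALSE]
  one <- function(cv) {
    smd_of <- function(wts_ext) {
      x1 <- exp_arm[[cv]]; x2 <- ext[[cv]]
      w1 <- rep(1, length(x1)); w2 <- wts_ext
      if (is.numeric(x1)) {
        keep1 <- !is.na(x1); keep2 <- !is.na(x2)
        if (!any(keep1) || !any(keep2)) return(NA_real_)
        smd_continuous(.wmean(x1[keep1], w1[keep1]),
                       sqrt(.wvar(x1[keep1], w1[keep1])),
                       .wmean(x2[keep2], w2[keep2]),
                       sqrt(.wvar(x2[keep2], w2[keep2])))
      } else {
        x1 <- as.character(x1); x2 <- as.character(x2)
        drop1 <- is.na(x1) | x1 == "unknown"
        drop2 <- is.na(x2) | x2 == "unknown"
        x1 <- x1[!drop1]; w1 <- w1[!drop1]
        x2 <- x2[!drop2]; w2 <- w2[!drop2]
        if (length(x1) == 0 || length(x2) == 0) return(NA_real_)
        lev <- sort(unique(c(x1, x2)))
        if (length(lev) < 2) return(0)
        p1 <- vapply(lev, function(l) sum(w1[x1 == l]) / sum(w1), 0)
        p2 <- vapply(lev, function(l) sum(w2[x2 == l]) / sum(w2), 0)
        if (length(lev) == 2) smd_binary(p1[1], p2[1])
        else smd_multicategory(p1, p2)
      }
    }
    data.frame(covariate = cv,
               smd_unweighted = smd_of(rep(1, nrow(ext))),
               smd_weighted = smd_of(ext$weight),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(covariates, one))
  out$balanced <- out$smd_weighted < threshold
  out
}

#' Baseline hypothesis tests between two cohorts
#'
#' Categorical covariates: Pearson chi-squared without continuity
#' correction, switching to the Fisher exact test when any expected cell
#' count falls below 5.  Continuous covariates: two-sided Wilcoxon rank-sum.
#' `"unknown"` levels are excluded.  A degenerate table (a single observed
#' category) returns p = 1 with a warning.
#'
#' @param group1,group2 cohort data frames.
#' @param covariates columns to test.
#' @return Named numeric vector of two-sided p-values.
#' @export
baseline_tests <- function(group1, group2,
                           covariates = c("age", "sex", "race", "region",
                                          "time_from_met_dx", "ecog",
                                          "ras_status", "liver_mets")) {
  if (nrow(group1) < 2 || nrow(group2) < 2)
    stop("need at least 2 patients per group", call. = FALSE)
  one <- function(cv) {
    x1 <- group1[[cv]]; x2 <- group2[[cv]]
    if (is.numeric(x1)) {
      return(suppressWarnings(
        stats::wilcox.test(x1, x2, alternative = "two.sided")$p.value))
    }
    x1 <- as.character(x1); x2 <- as.character(x2)
    x1 <- x1[!is.na(x1) & x1 != "unknown"]
    x2 <- x2[!is.na(x2) & x2 != "unknown"]
    lev <- sort(unique(c(x1, x2)))
    if (length(lev) < 2) {
      warning("degenerate table for '", cv, "' (single category); p = 1",
              call. = FALSE)
      return(1)
    }
    tab <- rbind(table(factor(x1, levels = lev)),
                 table(factor(x2, levels = lev)))
    expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    if (any(expected < 5))
      stats::fisher.test(tab)$p.value
    else
      suppressWarnings(stats::chisq.test(tab, correct = FALSE)$p.value)
  }
  vapply(covariates, one, numeric(1))
}

#' Write a balance table as CSV (the data behind a love plot)
#'
#' @param balance output of [balance_table()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_balance <- function(balance, path) {
  utils::write.csv(balance, path, row.names = FALSE)
  invisible(path)
}
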