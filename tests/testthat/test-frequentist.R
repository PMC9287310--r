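test_that("exact binomial interval matches the beta-quantile oracle and closed forms", {
  # oracle: stats::binom.test (exact method), across a grid of counts
  for (n in c(1, 13, 15, 50)) {
    for (x in unique(c(0, 1, floor(n / 2), n))) {
      ci <- clopper_pearson(x, n)
      oracle <- binom.test(x, n)$conf.int
      expect_equal(c(ci$ci_low, ci$ci_high), as.numeric(oracle),
                   tolerance = 1e-10, label = sprintf("x=%d n=%d", x, n))
    }
  }
  # zero-success upper bound has the closed form 1 - (alpha/2)^(1/n)
  expect_equal(clopper_pearson(0, 15)$ci_high, 1 - 0.025^(1 / 15),
               tolerance = 1e-12)
  expect_equal(clopper_pearson(0, 15)$ci_low, 0)
  expect_equal(clopper_pearson(15, 15)$ci_high, 1)
  expect_error(clopper_pearson(0, 0), ">= 1")
})

test_that("unit-weight logistic OR equals the 2x2 cross-product ratio and is weight-scale invariant", {
  y <- rep(c(1, 0, 1, 0), c(8, 12, 5, 20))
  arm <- rep(c("experimental", "control"), c(20, 25))
  est <- weighted_logistic_or(y, arm)
  expect_equal(est$estimate, (8 * 20) / (12 * 5), tolerance = 1e-6)
  est2 <- weighted_logistic_or(y, arm, weights = rep(2, 45))
  expect_equal(est2$estimate, est$estimate, tolerance = 1e-6)
  expect_true(est$ci_low < est$estimate && est$estimate < est$ci_high)

  expect_error(weighted_logistic_or(rep(0:1, c(10, 10)),
                                    rep(c("experimental", "control"),
                                        each = 10)),
               "exact methods")
})

test_that("small-sample Cox coefficient solves the hand-written partial likelihood", {
  # four untied events, alternating arms, so the score has an interior
  # root; the oracle writes the Breslow/Efron partial likelihood (no ties,
  # so they coincide) directly from its definition and maximizes it
  times <- c(1, 3, 2, 4); events <- c(1, 1, 1, 1)
  arm <- c("experimental", "control", "control", "experimental")
  pl <- function(b) {
    eta <- ifelse(arm == "experimental", b, 0)
    ll <- 0
    for (i in order(times)) {
      if (events[i] == 1) {
        risk <- times >= times[i]
        ll <- ll + eta[i] - log(sum(exp(eta[risk])))
      }
    }
    ll
  }
  bhat <- optimize(pl, c(-10, 10), maximum = TRUE)$maximum
  est <- weighted_cox_hr(times, events, arm)
  expect_equal(log(est$estimate), bhat, tolerance = 1e-4)
})

test_that("identical arms give HR 1 and swapping labels inverts the estimate", {
  set.seed(30)
  t0 <- rexp(40, 0.3)
  times <- c(t0, t0); events <- rep(1, 80)
  arm <- rep(c("experimental", "control"), each = 40)
  est <- weighted_cox_hr(times, events, arm)
  expect_equal(est$estimate, 1, tolerance = 1e-6)

  times2 <- rexp(80, 0.3); events2 <- rbinom(80, 1, 0.8)
  arm2 <- rep(c("experimental", "control"), each = 40)
  swapped <- ifelse(arm2 == "experimental", "control", "experimental")
  e1 <- weighted_cox_hr(times2, events2, arm2)
  e2 <- weighted_cox_hr(times2, events2, swapped)
  expect_equal(e1$estimate, 1 / e2$estimate, tolerance = 1e-8)
  expect_equal(e1$ci_low, 1 / e2$ci_high, tolerance = 1e-8)
})

test_that("robust variance behaves like the sandwich estimator should", {
  set.seed(31)
  n <- 1000
  x <- rbinom(n, 1, 0.5)
  y <- rbinom(n, 1, plogis(-0.5 + 0.8 * x))
  fit <- glm(y ~ x, family = binomial)
  rob <- sqrt(robust_variance(fit)["x", "x"])
  naive <- sqrt(vcov(fit)["x", "x"])
  expect_lt(abs(rob - naive) / naive, 0.15)  # well-specified limit

  # duplicating every patient at half weight keeps the point estimate but
  # halves the sandwich variance (weights enter the meat quadratically,
  # the bread linearly) - a concrete check of the weighted sandwich form
  d2 <- data.frame(y = c(y, y), x = c(x, x), w = rep(0.5, 2 * n))
  fit2 <- suppressWarnings(glm(y ~ x, data = d2, weights = w,
                               family = quasibinomial))
  expect_equal(unname(coef(fit2)["x"]), unname(coef(fit)["x"]),
               tolerance = 1e-8)
  v2 <- robust_variance(fit2)["x", "x"]
  expect_equal(v2 / robust_variance(fit)["x", "x"], 0.5, tolerance = 0.02)

  # homoskedastic OLS: sandwich approximately equals classical variance
  xx <- rnorm(n); yy <- 1 + 2 * xx + rnorm(n)
  lmfit <- lm(yy ~ xx)
  expect_equal(robust_variance(lmfit)["xx", "xx"], vcov(lmfit)["xx", "xx"],
               tolerance = 0.15)
})

test_that("weighted Kaplan-Meier matches a hand-computed product limit and is ratio invariant", {
  # 5 patients: events at 1, 2, 4; censored at 3, 5
  times <- c(1, 2, 3, 4, 5); events <- c(1, 1, 0, 1, 0)
  km <- weighted_km(times, events)
  # product-limit by hand: S(1)=4/5, S(2)=4/5*3/4=3/5, S(4)=3/5*1/2=3/10
  expect_equal(km$survival[km$times == 1], 4 / 5, tolerance = 1e-12)
  expect_equal(km$survival[km$times == 2], 3 / 5, tolerance = 1e-12)
  expect_equal(km$survival[km$times == 4], 3 / 10, tolerance = 1e-12)
  expect_equal(km$median, 4)  # first time S <= 0.5

  km2 <- weighted_km(times, events, weights = rep(7, 5))
  expect_equal(km2$survival, km$survival, tolerance = 1e-10)
  expect_equal(km2$median, km$median)

  one <- weighted_km(3, 1)
  expect_equal(one$survival, 0)
  expect_equal(one$median, 3)

  allcens <- weighted_km(c(2, 3), c(0, 0))
  expect_true(is.na(allcens$median))
})

test_that("frequentist dispatch: empty external reduces hybrid to concurrent; known HR recovered", {
  cur <- make_cohort(60, id_prefix = "C")
  cur$arm <- rep(c("experimental", "control"), each = 30)
  set.seed(32)
  cur$pfs_time <- rexp(60, ifelse(cur$arm == "experimental", 0.45, 0.3))
  cur$pfs_event <- 1
  cur$os_time <- cur$pfs_time + 1
  w <- cur; w$ps <- NA_real_; w$weight <- 1
  hyb <- estimate_frequentist(w, "pfs", "hybrid_control")
  conc <- estimate_frequentist(w, "pfs", "concurrent_control")
  expect_equal(hyb$estimate, conc$estimate, tolerance = 1e-10)
  expect_equal(hyb$ci_low, conc$ci_low, tolerance = 1e-10)

  # parameter recovery: true conditional HR 1.5, 20 replicates
  set.seed(33)
  lhr <- replicate(20, {
    n <- 300
    arm <- rep(c("experimental", "control"), each = n)
    tt <- rexp(2 * n, ifelse(arm == "experimental", 1.5, 1) * 0.3)
    log(weighted_cox_hr(tt, rep(1, 2 * n), arm)$estimate)
  })
  expect_lt(abs(mean(lhr) - log(1.5)),
            3 * sd(lhr) / sqrt(20) + 0.02)  # MC band plus fit tolerance
})
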