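test_that("saturated single-covariate propensity fit matches the closed-form stratum solution", {
  # one binary covariate (ecog): the logistic fit is saturated, so the
  # propensity in stratum x is n_exp(x) / (n_exp(x) + n_ext(x)) and the SMR
  # weight is the stratum odds n_exp(x) / n_ext(x), computable by hand.
  n_exp1 <- 30; n_exp0 <- 10; n_ext1 <- 20; n_ext0 <- 40
  exp_arm <- make_cohort(n_exp1 + n_exp0, arm = "experimental",
                         id_prefix = "A",
                         ecog = rep(c("1", "0"), c(n_exp1, n_exp0)))
  ext <- make_cohort(n_ext1 + n_ext0, trial = "external", id_prefix = "B",
                     ecog = rep(c("1", "0"), c(n_ext1, n_ext0)))
  w <- fit_propensity(exp_arm, ext, spec = ps_model_spec("ecog"))
  ps1 <- n_exp1 / (n_exp1 + n_ext1)
  ps0 <- n_exp0 / (n_exp0 + n_ext0)
  expect_equal(unique(round(w$ps[w$arm == "experimental" & w$ecog == "1"], 8)),
               round(ps1, 8))
  expect_equal(unique(round(w$ps[w$trial == "external" & w$ecog == "0"], 8)),
               round(ps0, 8))
  expect_equal(w$weight[w$trial == "external" & w$ecog == "1"],
               rep(n_exp1 / n_ext1, n_ext1), tolerance = 1e-6)
  expect_true(all(w$weight[w$arm == "experimental"] == 1))
})

test_that("identically distributed groups give ps near 0.5 and unit weights; ps = 0.5 maps to weight 1", {
  set.seed(101)
  draw <- function(id) {
    d <- make_cohort(2000, id_prefix = id,
                     ecog = sample(c("0", "1"), 2000, TRUE))
    d$age <- rnorm(2000, 60, 8)
    d
  }
  exp_arm <- draw("A"); exp_arm$arm <- "experimental"
  ext <- draw("B"); ext$trial <- "external"
  w <- fit_propensity(exp_arm, ext, spec = ps_model_spec(c("age", "ecog")))
  fit <- attr(w, "ps_fit")
  ses <- sqrt(diag(vcov(fit)))[-1]
  expect_true(all(abs(coef(fit)[-1]) < 4 * ses))
  expect_equal(mean(w$ps), 0.5, tolerance = 0.03)
  expect_equal(mean(w$weight[w$trial == "external"]), 1, tolerance = 0.1)

  # exact: ps = 0.5 <=> weight 1 (balanced saturated stratum)
  exp2 <- make_cohort(10, arm = "experimental", id_prefix = "C")
  ext2 <- make_cohort(10, trial = "external", id_prefix = "D")
  w2 <- fit_propensity(exp2, ext2, spec = ps_model_spec("ecog"))
  expect_equal(w2$ps, rep(0.5, 20), tolerance = 1e-8)
  expect_equal(w2$weight[w2$trial == "external"], rep(1, 10),
               tolerance = 1e-8)
})

test_that("SMD variants satisfy symmetry, zero, scale and reduction properties", {
  expect_equal(smd_binary(0.3, 0.3), 0)
  expect_equal(smd_binary(0.2, 0.7), smd_binary(0.7, 0.2))
  # relabelling the two categories leaves the binary SMD unchanged
  expect_equal(smd_binary(0.2, 0.7), smd_binary(0.8, 0.3))
  expect_equal(smd_binary(0, 0), 0)
  expect_equal(smd_binary(1, 1), 0)

  expect_equal(smd_continuous(5, 2, 5, 3), 0)
  expect_equal(smd_continuous(4, 2, 6, 2) * 0.5,
               smd_continuous(4, 4, 6, 4), tolerance = 1e-12)
  expect_error(smd_continuous(1, 0, 2, 0), "zero variance")
  expect_equal(smd_continuous(1, 0, 1, 0), 0)

  p1 <- c(0.2, 0.8); p2 <- c(0.5, 0.5)
  expect_equal(smd_multicategory(p1, p2), smd_binary(0.2, 0.5),
               tolerance = 1e-12)
  expect_equal(smd_multicategory(c(.1, .4, .5), c(.1, .4, .5)), 0)
  expect_equal(smd_multicategory(c(.1, .4, .5), c(.3, .3, .4)),
               smd_multicategory(c(.3, .3, .4), c(.1, .4, .5)),
               tolerance = 1e-12)
  expect_error(smd_multicategory(c(.5, .6), c(.5, .5)), "sum to 1")
})

test_that("a correctly specified propensity model removes planted imbalance", {
  set.seed(202)
  n <- 600
  exp_arm <- make_cohort(n, arm = "experimental", id_prefix = "A",
                         ecog = sample(c("0", "1"), n, TRUE, c(0.3, 0.7)),
                         liver = sample(c("no", "yes"), n, TRUE, c(0.5, 0.5)))
  ext <- make_cohort(n, trial = "external", id_prefix = "B",
                     ecog = sample(c("0", "1"), n, TRUE, c(0.7, 0.3)),
                     liver = sample(c("no", "yes"), n, TRUE, c(0.5, 0.5)))
  w <- fit_propensity(exp_arm, ext, spec = ps_model_spec(c("ecog", "liver_mets")))
  bal <- balance_table(w, c("ecog", "liver_mets"))
  ecog_row <- bal[bal$covariate == "ecog", ]
  expect_gt(ecog_row$smd_unweighted, 0.25)
  expect_lt(ecog_row$smd_weighted, 0.25)
  expect_true(all(bal$balanced))

  # all weights 1 => weighted equals unweighted
  w1 <- w
  w1$weight <- 1
  bal1 <- balance_table(w1, c("ecog", "liver_mets"))
  expect_equal(bal1$smd_weighted, bal1$smd_unweighted, tolerance = 1e-12)

  # identical groups => SMDs near zero
  ext_same <- exp_arm
  ext_same$patient_id <- paste0("S", seq_len(n))
  ext_same$trial <- "external"; ext_same$arm <- "control"
  w2 <- suppressWarnings(fit_propensity(exp_arm, ext_same,
                                        spec = ps_model_spec("ecog")))
  bal2 <- balance_table(w2, c("ecog", "liver_mets"))
  expect_true(all(bal2$smd_unweighted < 1e-8))
})

test_that("baseline tests choose the documented test per covariate type", {
  # sex split 12/16 vs 6/9: Pearson chi-squared without continuity
  # correction (all expected cells >= 5), statistic 0.033 on 1 df
  g1 <- make_cohort(28, id_prefix = "A")
  g1$sex <- rep(c("female", "male"), c(12, 16))
  g2 <- make_cohort(15, id_prefix = "B")
  g2$sex <- rep(c("female", "male"), c(6, 9))
  p <- baseline_tests(g1, g2, "sex")
  expect_equal(unname(p["sex"]),
               chisq.test(rbind(c(12, 16), c(6, 9)),
                          correct = FALSE)$p.value, tolerance = 1e-10)
  expect_true(p["sex"] > 0.85 && p["sex"] < 0.87)

  # region 2x3 with small expected cells switches to Fisher
  g1$region <- rep(c("north_america", "europe", "asia_pacific"),
                   c(6, 17, 5))
  g2$region <- rep(c("north_america", "europe", "asia_pacific"),
                   c(11, 1, 3))
  p2 <- baseline_tests(g1, g2, "region")
  expect_lt(p2["region"], 0.01)
  expect_equal(unname(p2["region"]),
               fisher.test(rbind(c(5, 17, 6), c(3, 1, 11)))$p.value,
               tolerance = 1e-10)

  # continuous covariate goes through the Wilcoxon rank-sum test
  set.seed(5)
  g1$age <- rnorm(28, 57, 9.6); g2$age <- rnorm(15, 52, 12)
  p3 <- baseline_tests(g1, g2, "age")
  expect_equal(unname(p3["age"]),
               wilcox.test(g1$age, g2$age)$p.value, tolerance = 1e-10)

  # degenerate single-category table
  g1$liver_mets <- "yes"; g2$liver_mets <- "yes"
  expect_warning(p4 <- baseline_tests(g1, g2, "liver_mets"), "degenerate")
  expect_equal(unname(p4["liver_mets"]), 1)
})
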