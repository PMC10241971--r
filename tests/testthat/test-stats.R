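test_that("Clopper-Pearson reproduces the published intervals", {
  m <- clopper_pearson(21, 22)
  expect_equal(round(100 * m$estimate, 1), 95.5)
  expect_equal(round(100 * m$conf.low, 1), 77.2)
  expect_equal(round(100 * m$conf.high, 1), 99.9)
  s <- clopper_pearson(19, 21)
  expect_equal(round(100 * s$conf.low, 2), 69.62)
  expect_equal(round(100 * s$conf.high, 2), 98.83)
})

test_that("Clopper-Pearson handles boundaries and matches binom.test", {
  expect_equal(clopper_pearson(0, 10)$conf.low, 0)
  expect_equal(clopper_pearson(10, 10)$conf.high, 1)
  expect_error(clopper_pearson(1, 0))
  # binom.test is an independent implementation of the same exact interval
  for (xn in list(c(3, 17), c(0, 5), c(12, 12), c(19, 21))) {
    ours <- clopper_pearson(xn[1], xn[2])
    ref <- binom.test(xn[1], xn[2])$conf.int
    expect_equal(c(ours$conf.low, ours$conf.high), as.numeric(ref),
                 tolerance = 1e-10)
  }
})

test_that("logit predictive-value intervals reproduce the published row", {
  pv <- predictive_value_logit_ci(19, 351, 2, 4376)
  expect_equal(round(100 * pv$ppv$estimate, 2), 5.14)
  expect_equal(round(100 * pv$ppv$conf.low, 2), 4.36)
  expect_equal(round(100 * pv$ppv$conf.high, 2), 6.04)
  expect_equal(round(100 * pv$npv$estimate, 2), 99.95)
  expect_equal(round(100 * pv$npv$conf.low, 2), 99.83)
  expect_equal(round(100 * pv$npv$conf.high, 2), 99.99)
})

test_that("logit intervals are symmetric on a symmetric table and error on
          degenerate ones", {
  pv <- predictive_value_logit_ci(25, 25, 25, 25)
  expect_equal(pv$ppv$estimate, 0.5)
  expect_equal(pv$npv$estimate, 0.5)
  expect_equal(pv$ppv$conf.high - pv$ppv$conf.low,
               pv$npv$conf.high - pv$npv$conf.low, tolerance = 1e-12)
  expect_error(predictive_value_logit_ci(10, 5, 0, 20), "exact interval")
})

test_that("predictive-value points equal tp/(tp+fp) and tn/(tn+fn)", {
  set.seed(7)
  for (k in 1:20) {
    tp <- sample(1:50, 1); fp <- sample(1:50, 1)
    fn <- sample(1:50, 1); tn <- sample(1:50, 1)
    pv <- predictive_value_logit_ci(tp, fp, fn, tn)
    expect_equal(pv$ppv$estimate, tp / (tp + fp), tolerance = 1e-12)
    expect_equal(pv$npv$estimate, tn / (tn + fn), tolerance = 1e-12)
  }
})

test_that("accuracy measures from the published 2x2 match the report", {
  acc <- accuracy_measures(confusion_matrix(19, 351, 2, 4376))
  expect_equal(round(100 * acc$sensitivity$estimate, 2), 90.48)
  expect_equal(round(100 * acc$specificity$estimate, 2), 92.57)
  expect_equal(round(100 * acc$prevalence$estimate, 2), 0.44)
  expect_equal(round(100 * acc$prevalence$conf.low, 2), 0.27)
  expect_equal(round(100 * acc$prevalence$conf.high, 2), 0.68)
  perfect <- accuracy_measures(confusion_matrix(10, 0, 0, 90))
  expect_equal(perfect$sensitivity$estimate, 1)
  expect_equal(perfect$specificity$estimate, 1)
  expect_true(is.na(perfect$ppv$estimate))  # logit interval degenerate
})

test_that("management accuracy drops inconclusive labels from the denominator", {
  m <- management_accuracy(c(rep("CORRECT", 21), "INCORRECT"))
  expect_equal(round(100 * m$estimate, 1), 95.5)
  mix <- management_accuracy(c("CORRECT", "CORRECT", "INCORRECT",
                               "INCONCLUSIVE", "INCONCLUSIVE"))
  expect_equal(mix$n, 3L)
  expect_equal(mix$x, 2L)
  all_correct <- management_accuracy(rep("CORRECT", 5))
  expect_equal(all_correct$estimate, 1)
  expect_equal(all_correct$conf.high, 1)
  expect_error(management_accuracy(rep("INCONCLUSIVE", 3)), "conclusive")
})

test_that("test yield follows the published accounting", {
  expect_equal(round(test_yield(5389, 172, 91, 4748), 3), 0.926)
  expect_equal(test_yield(100, 0, 0, 100), 1)
  expect_equal(test_yield(100, 10, 10, 60), 0.75)
  expect_error(test_yield(10, 5, 5, 1), "denominator")
})

test_that("Buderer sample size reproduces 2930 and scales as expected", {
  b <- buderer_sample_size(0.83, 0.92, 0.0185, 0.10, z = 1.96)
  expect_equal(b$n_required, 2930)
  expect_equal(b$driver, "SENSITIVITY")
  # symmetric inputs give equal branch sizes
  s <- buderer_sample_size(0.8, 0.8, 0.5, 0.05)
  expect_equal(s$n_se, s$n_sp)
  # halving the width quadruples the requirement (before ceiling)
  w1 <- buderer_sample_size(0.83, 0.92, 0.0185, 0.10, z = 1.96)
  w2 <- buderer_sample_size(0.83, 0.92, 0.0185, 0.05, z = 1.96)
  expect_true(abs(w2$n_se - 4 * w1$n_se) <= 4)
  # non-increasing in prevalence on the sensitivity branch
  prevs <- c(0.01, 0.05, 0.1, 0.3, 0.6)
  ns <- sapply(prevs, function(p)
    buderer_sample_size(0.83, 0.92, p, 0.10)$n_se)
  expect_true(all(diff(ns) <= 0))
  expect_error(buderer_sample_size(0.83, 0.92, 0, 0.1), "prevalence")
})

test_that("interval widths shrink with n at fixed proportion", {
  cp_w <- sapply(c(20, 80, 320, 1280), function(n)
    with(clopper_pearson(round(0.3 * n), n), conf.high - conf.low))
  expect_true(all(diff(cp_w) < 0))
  pv_w <- sapply(c(1, 4, 16), function(f) {
    pv <- predictive_value_logit_ci(10 * f, 20 * f, 5 * f, 100 * f)
    pv$ppv$conf.high - pv$ppv$conf.low
  })
  expect_true(all(diff(pv_w) < 0))
})
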