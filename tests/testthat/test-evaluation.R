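test_that("roc_curve traces the expected points", {
  sep <- roc_curve(c(1, 2, 10, 11), c(FALSE, FALSE, TRUE, TRUE))
  expect_true(any(sep$fpr == 0 & sep$tpr == 1))

  hand <- roc_curve(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(hand$fpr[1], 0)
  expect_equal(hand$tpr[nrow(hand)], 1)
  expect_equal(auc_mann_whitney(c(3, 5, 1, 4), c(TRUE, TRUE, FALSE, FALSE)),
               0.75)

  expect_error(roc_curve(1:3, c(TRUE, TRUE, TRUE)), "positive and.*negative")
})

test_that("Mann-Whitney AUC equals the trapezoidal area, ties included", {
  trapezoid <- function(roc) {
    sum(diff(roc$fpr) * (head(roc$tpr, -1) + tail(roc$tpr, -1)) / 2)
  }
  set.seed(101)
  for (i in 1:20) {
    n <- sample(5:40, 1)
    scores <- if (i %% 2) rnorm(n) else sample(0:5, n, replace = TRUE)
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(labels) || all(labels)) next
    for (dir in c("high", "low")) {
      expect_equal(auc_mann_whitney(scores, labels, dir),
                   trapezoid(roc_curve(scores, labels, dir)),
                   tolerance = 1e-12)
    }
  }
  # degenerate cases
  expect_equal(auc_mann_whitney(c(1, 1, 1, 1), c(TRUE, TRUE, FALSE, FALSE)),
               0.5)
  expect_equal(auc_mann_whitney(c(9, 8, 1, 2), c(TRUE, TRUE, FALSE, FALSE)),
               1)
})

test_that("AUC agrees with pROC on random data", {
  skip_if_not_installed("pROC")
  set.seed(103)
  scores <- c(rnorm(30, 1), rnorm(30))
  labels <- rep(c(TRUE, FALSE), each = 30)
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(auc_mann_whitney(scores, labels), ref, tolerance = 1e-12)
})

test_that("the AUC significance test matches exact enumeration", {
  mg <- mason_graham_test(c(3, 4, 1, 2), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(mg$auc, 1)
  expect_equal(mg$p_value, 1 / 6)
  expect_equal(mg$method, "exact")

  # null centre: AUC exactly one half gives p about one half
  null <- mason_graham_test(c(1, 4, 2, 3), c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(null$auc, 0.5)
  expect_gt(null$p_value, 0.4)

  set.seed(105)
  big <- mason_graham_test(c(rnorm(100, 3), rnorm(100)),
                           rep(c(TRUE, FALSE), each = 100))
  expect_lt(big$p_value, 0.001)
})

test_that("null p-values of the AUC test are uniform", {
  set.seed(107)
  ps <- vapply(1:2000, function(i) {
    scores <- rnorm(40)
    labels <- rep(c(TRUE, FALSE), each = 20)
    mason_graham_test(scores, labels)$p_value
  }, numeric(1))
  # exact null p-values are discrete, hence tied; the KS warning about
  # ties is immaterial for this calibration check
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif"))$p.value, 0.01)
})

test_that("optimal_point minimises distance to perfect classification", {
  perfect <- tibble::tibble(threshold = c(Inf, 5, -Inf),
                            fpr = c(0, 0, 1), tpr = c(0, 1, 1))
  opt <- optimal_point(perfect)
  expect_equal(c(opt$optimal_sens, opt$optimal_spec), c(1, 1))

  three <- tibble::tibble(threshold = c(Inf, 2, -Inf),
                          fpr = c(0, 0.2, 1), tpr = c(0, 0.9, 1))
  opt3 <- optimal_point(three)
  expect_equal(c(opt3$optimal_sens, opt3$optimal_spec), c(0.9, 0.8))

  # equidistant candidates: tie broken toward the highest sensitivity
  tied <- tibble::tibble(threshold = c(Inf, 3, 1, -Inf),
                         fpr = c(0, 0, 0.4, 1), tpr = c(0, 0.6, 1, 1))
  expect_equal(optimal_point(tied)$optimal_sens, 1)
  expect_equal(optimal_point(tied)$optimal_spec, 0.6)
})

test_that("achieved_at_cut counts sensitivity and specificity directly", {
  got <- achieved_at_cut(c(5, 6, 1, 9), c(TRUE, TRUE, FALSE, FALSE), 4)
  expect_equal(c(got$achieved_sens, got$achieved_spec), c(1, 0.5))

  low <- achieved_at_cut(c(1, 2, 10, 20), c(TRUE, TRUE, FALSE, FALSE), 5,
                         direction = "low")
  expect_equal(c(low$achieved_sens, low$achieved_spec), c(1, 1))

  # sedentary rule at 100 cpm on the published sitting values against a
  # uniformly high locomotor class: 49 of the 52 sitting values pass
  scores <- c(sitting_vector, rep(3000, 52))
  labels <- rep(c(TRUE, FALSE), each = 52)
  sed <- achieved_at_cut(scores, labels, 100, direction = "low")
  expect_equal(sed$achieved_sens, 49 / 52)
  expect_equal(sed$achieved_spec, 1)
})

test_that("evaluate_cutpoints handles separable and shuffled data", {
  cuts <- list(sedentary_max = 100, light_max = 2240, moderate_max = 3840,
               model = NULL)
  sep <- make_summaries(
    sitting = rep(c(0, 10), 10), slow_walk = rep(c(500, 1000), 10),
    brisk_walk = rep(c(2500, 3000), 10), jog = rep(c(5000, 6000), 10)
  )
  ev <- evaluate_cutpoints(sep, cuts)
  expect_equal(ev$misclassification_rate, 0)
  aucs <- vapply(ev$roc, function(r) r$auc, numeric(1))
  expect_true(all(aucs[c("sedentary", "vigorous")] == 1))

  set.seed(109)
  shuf <- sep
  shuf$mean_cpm <- sample(shuf$mean_cpm)
  ev2 <- evaluate_cutpoints(shuf, cuts)
  expect_gt(ev2$misclassification_rate, 0.5)
  aucs2 <- vapply(ev2$roc, function(r) r$auc, numeric(1))
  expect_lt(max(abs(aucs2 - 0.5)), 0.25)

  expect_error(evaluate_cutpoints(sep[sep$activity != "jog", ], cuts),
               "Missing calibration")
})

test_that("the default synthetic study discriminates sedentary sharply", {
  s <- cached_default_summaries()
  cuts <- derive_cutpoints(s)
  ev <- evaluate_cutpoints(s, cuts)
  expect_gte(ev$roc$sedentary$auc, 0.95)
  expect_gte(ev$roc$vigorous$auc, 0.90)
  # confusion matrix bookkeeping
  expect_equal(sum(ev$confusion), 53 * 4)
  expect_equal(unname(rowSums(ev$confusion)), rep(53, 4))
})
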