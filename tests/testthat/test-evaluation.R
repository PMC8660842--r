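# Confusion counts, the four statistics, ROC, comparison tables.

test_that("counts tally correctly including degenerate cases", {
  expect_equal(confusionCounts(rep("POS", 5), rep("POS", 5)),
               c(tp = 5L, tn = 0L, fp = 0L, fn = 0L))
  expect_equal(confusionCounts(c("POS", "NEG"), c("NEG", "POS")),
               c(tp = 0L, tn = 0L, fp = 1L, fn = 1L))
  yt <- c("POS", "POS", "NEG", "NEG", "POS", "NEG")
  yp <- c("POS", "NEG", "NEG", "POS", "POS", "NEG")
  expect_equal(confusionCounts(yt, yp),
               c(tp = 2L, tn = 2L, fp = 1L, fn = 1L))
  expect_error(confusionCounts("POS", c("POS", "NEG")), "length")
})

test_that("metrics match an independent vector-level oracle", {
  # oracle: rebuild label vectors from counts, score with mean()/cor()
  set.seed(33)
  for (i in 1:1000) {
    ct <- c(tp = sample(1:40, 1), tn = sample(1:40, 1),
            fp = sample(1:40, 1), fn = sample(1:40, 1))
    y_true <- rep(c("POS", "NEG", "NEG", "POS"), ct[c(1, 2, 3, 4)])
    y_pred <- rep(c("POS", "NEG", "POS", "NEG"), ct[c(1, 2, 3, 4)])
    m <- evalMetrics(metricsFromCounts(ct))
    expect_equal(m[["se"]],
                 mean(y_pred[y_true == "POS"] == "POS"), tolerance = 1e-12)
    expect_equal(m[["sp"]],
                 mean(y_pred[y_true == "NEG"] == "NEG"), tolerance = 1e-12)
    expect_equal(m[["q"]], mean(y_true == y_pred), tolerance = 1e-12)
    expect_equal(m[["mcc"]],
                 suppressWarnings(cor(as.numeric(y_true == "POS"),
                                      as.numeric(y_pred == "POS"))),
                 tolerance = 1e-12)
  }
})

test_that("MCC is symmetric under class-label swap", {
  set.seed(35)
  for (i in 1:50) {
    ct <- sample(1:50, 4)
    m1 <- evalMetrics(metricsFromCounts(ct[1], ct[2], ct[3], ct[4]))
    # swap POS<->NEG: tp<->tn, fp<->fn
    m2 <- evalMetrics(metricsFromCounts(ct[2], ct[1], ct[4], ct[3]))
    expect_equal(m1[["mcc"]], m2[["mcc"]], tolerance = 1e-12)
  }
})

test_that("Q is the prevalence-weighted mean of SE and SP", {
  set.seed(37)
  for (i in 1:50) {
    ct <- sample(1:50, 4)
    m <- evalMetrics(metricsFromCounts(ct[1], ct[2], ct[3], ct[4]))
    tot <- sum(ct)
    w_pos <- (ct[1] + ct[4]) / tot
    w_neg <- (ct[2] + ct[3]) / tot
    expect_equal(m[["q"]], w_pos * m[["se"]] + w_neg * m[["sp"]],
                 tolerance = 1e-12)
  }
})

test_that("an MCC with a zero marginal is flagged and reported as 0", {
  r <- metricsFromCounts(5, 0, 5, 0)
  expect_true(r@mccUndefined)
  expect_equal(evalMetrics(r)[["mcc"]], 0)
  expect_error(metricsFromCounts(0, 0, 0, 0), "zero")
})

test_that("perfect and reversed scores bound the ROC sweep", {
  y <- c(rep("POS", 6), rep("NEG", 6))
  perfect <- c(runif(6, 0.8, 1), runif(6, 0, 0.2))
  r <- rocCurve(y, perfect)
  expect_equal(r$auc, 1.0)
  expect_equal(unlist(r$points[1, ]), c(fpr = 0, tpr = 0))
  expect_equal(unlist(r$points[nrow(r$points), ]), c(fpr = 1, tpr = 1))
  expect_true(all(diff(r$points$tpr) >= 0))
  expect_equal(rocCurve(y, 1 - perfect)$auc, 0.0)
  expect_error(rocCurve(rep("POS", 5), runif(5)), "both classes")
})

test_that("label-independent scores give chance-level AUC", {
  set.seed(39)
  y <- rep(c("POS", "NEG"), 500)
  auc <- rocCurve(y, runif(1000))$auc
  expect_gt(auc, 0.45); expect_lt(auc, 0.55)
})

test_that("tied scores collapse into single ROC steps", {
  y <- c("POS", "POS", "NEG", "NEG")
  r <- rocCurve(y, c(0.7, 0.7, 0.7, 0.1))
  # one step covers the three tied scores jointly
  expect_true(all(c(0.5) %in% r$points$fpr))
  expect_equal(nrow(r$points), 3L)
})

test_that("ROC agrees with the pROC reference on a mixed fixture", {
  skip_if_not_installed("pROC")
  set.seed(41)
  y <- rep(c("POS", "NEG"), 60)
  s <- ifelse(y == "POS", rnorm(120, 0.7, 0.2), rnorm(120, 0.4, 0.2))
  ours <- rocCurve(y, s)$auc
  ref <- suppressMessages(as.numeric(pROC::auc(
    pROC::roc(response = y, predictor = s, levels = c("NEG", "POS"),
              direction = "<"))))
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("comparison tables order by MCC then Q", {
  reps <- list(strong = metricsFromCounts(441, 435, 62, 60),
               weak = metricsFromCounts(391, 362, 138, 107))
  tab <- comparisonTable(reps, oob = c(strong = 0.88, weak = 0.77))
  expect_identical(tab$model, c("strong", "weak"))
  expect_equal(tab$mcc, c(0.76, 0.51))
  expect_equal(tab$q_train, c(0.88, 0.77))
  # equal MCC resolved by Q
  a <- metricsFromCounts(90, 90, 10, 10)
  reps2 <- list(low = metricsFromCounts(45, 45, 5, 5), high = a)
  tab2 <- comparisonTable(reps2)
  expect_equal(nrow(tab2), 2L)
  expect_equal(nrow(comparisonTable(list(solo = a))), 1L)
})
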