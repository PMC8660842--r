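# Forest training, vote probabilities, feature selection, trees, SVM,
# MLP, Y-scrambling, cross-validation.

test_that("a forest learns a separable fixture and reports OOB accuracy", {
  fx <- separableFixture(n = 200, seed = 4)
  m <- trainForest(fx$X, fx$y, rfConfig(n_trees = 200, seed = 4))
  expect_gte(oobAccuracy(m), 0.95)
  preds <- predictSpectrumClass(m, fx$X)
  expect_gte(mean(preds$predicted == fx$y), 0.95)
  expect_true(all(preds$probability >= 0.5 & preds$probability <= 1))
})

test_that("single-class labels are rejected; one tree still works", {
  fx <- separableFixture(n = 60, seed = 2)
  expect_error(trainForest(fx$X, rep("POS", 60)), "single class")
  m1 <- trainForest(fx$X, fx$y, rfConfig(n_trees = 1, seed = 1))
  expect_s4_class(m1, "SpectrumModel")
  expect_equal(nrow(predictSpectrumClass(m1, fx$X)), 60)
})

test_that("prediction enforces the training column provenance", {
  fx <- separableFixture(n = 80, seed = 6)
  m <- trainForest(fx$X, fx$y, rfConfig(n_trees = 50, seed = 6))
  Xbad <- fx$X[, rev(colnames(fx$X))]
  expect_error(predictSpectrumClass(m, Xbad), "provenance")
})

test_that("identical seed and data give identical predictions", {
  fx <- separableFixture(n = 120, seed = 8)
  m1 <- trainForest(fx$X, fx$y, rfConfig(n_trees = 100, seed = 31))
  m2 <- trainForest(fx$X, fx$y, rfConfig(n_trees = 100, seed = 31))
  expect_identical(predictSpectrumClass(m1, fx$X),
                   predictSpectrumClass(m2, fx$X))
})

test_that("informative columns surface in the top-k across seeds", {
  fx <- separableFixture(n = 150, p = 30, n_inf = 4, seed = 10)
  for (s in 1:5) {
    m <- trainForest(fx$X, fx$y, rfConfig(n_trees = 150, seed = s))
    top <- selectTopFeatures(m, 4)
    expect_setequal(top, fx$informative)
  }
})

test_that("feature selection is validated and ties break by column index", {
  fx <- separableFixture(n = 80, seed = 12)
  m <- trainForest(fx$X, fx$y, rfConfig(n_trees = 50, seed = 12))
  expect_error(selectTopFeatures(m, 0), "positive")
  expect_error(selectTopFeatures(m, 1e4), "exceeds")
  expect_length(selectTopFeatures(m, ncol(fx$X)), ncol(fx$X))
  # force exact ties: all-constant importances
  m@importances[, "MeanDecreaseAccuracy"] <- 0
  expect_identical(selectTopFeatures(m, 3), colnames(fx$X)[1:3])
  # gini ranking is also available
  expect_length(selectTopFeatures(m, 5, measure = "gini"), 5)
})

test_that("vote ties resolve to POS with probability 0.5", {
  fx <- separableFixture(n = 40, seed = 14)
  m <- trainForest(fx$X, fx$y, rfConfig(n_trees = 2, seed = 14))
  v <- predict(m@fit, fx$X, type = "vote", norm.votes = TRUE)
  preds <- predictSpectrumClass(m, fx$X)
  tied <- which(abs(v[, "POS"] - 0.5) < 1e-12)
  if (length(tied)) {
    expect_true(all(preds$predicted[tied] == "POS"))
    expect_true(all(abs(preds$probability[tied] - 0.5) < 1e-12))
  } else skip("no tied votes in this fixture")
})

test_that("a tree recovers a single perfectly separating bit", {
  fx <- separableFixture(n = 100, p = 20, n_inf = 1, seed = 16)
  m <- trainTree(fx$X, fx$y)
  expect_identical(as.character(m@fit$frame$var[1]), "bit001")
  rules <- extractRules(m)
  expect_true(any(grepl("bit001", rules$rule)))
  expect_setequal(rules$class, c("POS", "NEG"))
})

test_that("a huge cp collapses the tree to one majority leaf", {
  fx <- separableFixture(n = 90, seed = 18)
  m <- trainTree(fx$X, fx$y, cp = 10)
  rules <- extractRules(m)
  expect_equal(nrow(rules), 1L)
  expect_identical(rules$rule, "TRUE")
})

test_that("Y-scrambling sits at chance level and is seed-reproducible", {
  fx <- separableFixture(n = 300, p = 30, seed = 20)
  acc <- yScramble(fx$X, fx$y, rfConfig(n_trees = 100), n_rounds = 5,
                   seed = 20)
  expect_length(acc, 5)
  expect_true(all(acc > 0.35 & acc < 0.65))
  acc2 <- yScramble(fx$X, fx$y, rfConfig(n_trees = 100), n_rounds = 5,
                    seed = 20)
  expect_identical(acc, acc2)
})

test_that("stratified cross-validation scores a separable fixture highly", {
  fx <- separableFixture(n = 120, p = 20, seed = 22)
  acc <- crossValidate(fx$X, fx$y,
                       function(X, y) trainForest(X, y,
                         rfConfig(n_trees = 60, seed = 1)),
                       k = 5, seed = 3)
  expect_gte(acc, 0.9)
})

test_that("the SVM plug-in trains with the tuned defaults recorded", {
  fx <- separableFixture(n = 120, seed = 24)
  m <- trainSVM(fx$X, fx$y)
  expect_equal(m@config$C, 500)
  expect_equal(m@config$gamma, 0.004)
  preds <- predictSpectrumClass(m, fx$X)
  expect_gte(mean(preds$predicted == fx$y), 0.95)
  expect_error(trainSVM(fx$X, rep("NEG", 120)), "single class")
})

test_that("the MLP plug-in echoes its architecture and fits separable data", {
  cfg <- mlpConfig(epochs = 60, seed = 5)
  expect_equal(cfg$hidden, c(250L, 250L, 8L, 4L))
  expect_identical(cfg$activations, c(rep("relu", 4), "sigmoid"))
  expect_equal(cfg$batch_size, 36L)
  expect_equal(cfg$lr, 0.001)
  fx <- separableFixture(n = 150, p = 30, n_inf = 6, seed = 26)
  m <- trainMLP(fx$X, fx$y, cfg)
  preds <- predictSpectrumClass(m, fx$X)
  expect_true(all(preds$prob_pos >= 0 & preds$prob_pos <= 1))
  expect_gte(mean(preds$predicted == fx$y), 0.9)
})
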