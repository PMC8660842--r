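# Classifier training and validation. Random forests are the primary
# algorithm (randomForest backend: unpruned trees on bootstrap samples,
# OOB internal validation, permutation and Gini importances, vote
# probabilities); classification trees (rpart) provide interpretable
# rules; SVM (e1071) and a small feed-forward network are optional
# plug-ins.

.asLabelFactor <- function(y) {
  y <- as.character(y)
  bad <- setdiff(unique(y), c("POS", "NEG"))
  if (length(bad)) stop("labels must be POS/NEG; found: ",
                        paste(bad, collapse = ", "))
  factor(y, levels = c("NEG", "POS"))
}

.featureInput <- function(X) {
  if (is(X, "FeatureMatrix"))
    list(vals = featureValues(X), prov = provenance(X))
  else list(vals = as.matrix(X), prov = "user")
}

#' Random-forest configuration
#'
#' @param n_trees number of trees (the study protocol explores 500-1000;
#'   default 500).
#' @param mtry "sqrt" or "third" of the column count.
#' @param seed integer training seed.
#' @return an rfConfig list.
#' @export
rfConfig <- function(n_trees = 500L, mtry = c("sqrt", "third"), seed = 1L) {
  mtry <- match.arg(mtry)
  stopifnot(n_trees >= 1L)
  structure(list(n_trees = as.integer(n_trees), mtry = mtry,
                 seed = as.integer(seed)), class = "rfConfig")
}

.resolveMtry <- function(mtry, p) {
  m <- if (mtry == "sqrt") floor(sqrt(p)) else floor(p / 3)
  max(1L, as.integer(m))
}

#' Train a random forest on a feature matrix
#'
#' Grows \code{n_trees} unpruned classification trees on bootstrap samples
#' with \code{mtry} descriptors available per split. Out-of-bag accuracy is
#' recorded as the internal validation estimate, and both the permutation
#' (mean decrease in accuracy) and Gini importances are kept.
#'
#' @param X a \linkS4class{FeatureMatrix} or numeric matrix with mol_id
#'   rownames.
#' @param y POS/NEG labels aligned with the rows of \code{X}.
#' @param cfg an \code{\link{rfConfig}}.
#' @return a \linkS4class{SpectrumModel}.
#' @export
trainForest <- function(X, y, cfg = rfConfig()) {
  inp <- .featureInput(X)
  y <- .asLabelFactor(y)
  stopifnot(length(y) == nrow(inp$vals))
  if (nlevels(droplevels(y)) < 2L)
    stop("training labels contain a single class")
  set.seed(cfg$seed)
  fit <- randomForest::randomForest(
    x = inp$vals, y = y, ntree = cfg$n_trees,
    mtry = .resolveMtry(cfg$mtry, ncol(inp$vals)), importance = TRUE)
  oob <- 1 - unname(fit$err.rate[cfg$n_trees, "OOB"])
  imp <- fit$importance[, c("MeanDecreaseAccuracy", "MeanDecreaseGini"),
                        drop = FALSE]
  new("SpectrumModel", algorithm = "rf", fit = fit,
      config = unclass(cfg), featureNames = colnames(inp$vals),
      provenance = inp$prov, oobAccuracy = oob, importances = imp,
      seed = cfg$seed)
}

#' Predict the spectrum class with vote probabilities
#'
#' For a forest, the probability is the vote fraction of the predicted
#' class (in [0.5, 1]); an exact vote tie is resolved to POS, since in
#' photosafety screening sensitivity outranks specificity. Prediction
#' columns must match the training provenance exactly.
#'
#' @param model a \linkS4class{SpectrumModel}.
#' @param X features with the training columns.
#' @return data.frame with columns mol_id, predicted, probability (vote
#'   fraction of the predicted class, in [0.5, 1]) and prob_pos (POS-class
#'   score, used for ROC sweeps).
#' @export
predictSpectrumClass <- function(model, X) {
  stopifnot(is(model, "SpectrumModel"))
  inp <- .featureInput(X)
  if (!identical(colnames(inp$vals), model@featureNames))
    stop("feature columns do not match the model's training provenance")
  ids <- rownames(inp$vals)
  if (is.null(ids)) ids <- sprintf("row%05d", seq_len(nrow(inp$vals)))
  prob_pos <- switch(model@algorithm,
    rf = {
      v <- stats::predict(model@fit, inp$vals, type = "vote",
                          norm.votes = TRUE)
      unname(v[, "POS"])
    },
    cart = {
      p <- stats::predict(model@fit, as.data.frame(inp$vals),
                          type = "prob")
      unname(p[, "POS"])
    },
    svm = {
      cls <- stats::predict(model@fit, inp$vals)
      as.numeric(cls == "POS")  # class output only; no calibrated score
    },
    mlp = as.numeric(.mlpForward(model@fit, inp$vals)))
  predicted <- ifelse(prob_pos >= 0.5, "POS", "NEG")
  probability <- ifelse(predicted == "POS", prob_pos, 1 - prob_pos)
  data.frame(mol_id = ids, predicted = predicted,
             probability = probability, prob_pos = prob_pos,
             stringsAsFactors = FALSE)
}

#' Select the k most important descriptors
#'
#' Ranks columns by random-forest importance — permutation-based mean
#' decrease in accuracy by default, Gini alternatively — with deterministic
#' ties broken by column index.
#'
#' @param model a trained forest \linkS4class{SpectrumModel}.
#' @param k number of columns to keep.
#' @param measure "accuracy" or "gini".
#' @return character vector of k column names, importance-ordered.
#' @export
selectTopFeatures <- function(model, k,
                              measure = c("accuracy", "gini")) {
  measure <- match.arg(measure)
  stopifnot(is(model, "SpectrumModel"))
  if (k <= 0L) stop("k must be positive")
  if (k > length(model@featureNames))
    stop("k exceeds the number of features")
  col <- if (measure == "accuracy") "MeanDecreaseAccuracy"
         else "MeanDecreaseGini"
  sc <- model@importances[, col]
  ord <- order(-sc, seq_along(sc))
  model@featureNames[ord[seq_len(k)]]
}

#' Train a classification tree with extractable rules
#'
#' rpart tree (default parameters unless \code{cp} is given); a
#' single-class response yields a trivial one-leaf tree with a warning.
#'
#' @param X features.
#' @param y POS/NEG labels.
#' @param cp rpart complexity parameter.
#' @param seed integer seed.
#' @return a \linkS4class{SpectrumModel} with algorithm "cart".
#' @export
trainTree <- function(X, y, cp = 0.01, seed = 1L) {
  inp <- .featureInput(X)
  y <- .asLabelFactor(y)
  stopifnot(length(y) == nrow(inp$vals))
  if (nlevels(droplevels(y)) < 2L)
    warning("single-class response: the tree is a single leaf")
  d <- as.data.frame(inp$vals)
  d$.y <- y
  set.seed(as.integer(seed))
  fit <- rpart::rpart(.y ~ ., data = d, method = "class",
                      control = rpart::rpart.control(cp = cp))
  imp <- matrix(0, length(colnames(inp$vals)), 1,
                dimnames = list(colnames(inp$vals), "VariableImportance"))
  if (!is.null(fit$variable.importance)) {
    hit <- intersect(names(fit$variable.importance), rownames(imp))
    imp[hit, 1] <- fit$variable.importance[hit]
  }
  new("SpectrumModel", algorithm = "cart", fit = fit,
      config = list(cp = cp, seed = as.integer(seed)),
      featureNames = colnames(inp$vals), provenance = inp$prov,
      oobAccuracy = NA_real_, importances = imp, seed = as.integer(seed))
}

#' Extract human-readable rules from a classification tree
#'
#' One row per leaf: the conjunction of split conditions on the path from
#' the root, and the class predicted at the leaf.
#'
#' @param model a "cart" \linkS4class{SpectrumModel}.
#' @return data.frame with columns rule, class, n (training molecules at
#'   the leaf).
#' @export
extractRules <- function(model) {
  stopifnot(is(model, "SpectrumModel"), model@algorithm == "cart")
  fit <- model@fit
  fr <- fit$frame
  leaves <- as.integer(rownames(fr))[fr$var == "<leaf>"]
  cls <- attr(fit, "ylevels")[fr$yval[fr$var == "<leaf>"]]
  paths <- rpart::path.rpart(fit, nodes = leaves, print.it = FALSE)
  rules <- vapply(paths, function(p) {
    conds <- p[-1]                       # drop the "root" element
    if (length(conds) == 0L) "TRUE" else paste(conds, collapse = " & ")
  }, character(1))
  data.frame(rule = unname(rules), class = cls,
             n = fr$n[fr$var == "<leaf>"], stringsAsFactors = FALSE)
}

#' Y-scrambling validation
#'
#' Retrains on uniformly permuted labels \code{n_rounds} times and records
#' the internal-validation accuracy of each round (OOB accuracy for the
#' forest). A valid model's scrambled accuracies sit at chance level.
#'
#' @param X features.
#' @param y POS/NEG labels.
#' @param cfg an \code{\link{rfConfig}} used for every round.
#' @param n_rounds number of scrambling rounds.
#' @param seed integer seed driving the permutations.
#' @return numeric vector of accuracies, one per round.
#' @export
yScramble <- function(X, y, cfg = rfConfig(), n_rounds = 5L, seed = 1L) {
  stopifnot(n_rounds >= 1L)
  inp <- .featureInput(X)
  y <- .asLabelFactor(y)
  vapply(seq_len(n_rounds), function(r) {
    set.seed(subSeed(seed, r))
    y_perm <- sample(y)
    m <- trainForest(inp$vals, y_perm,
                     rfConfig(cfg$n_trees, cfg$mtry,
                              seed = subSeed(seed, 1000L + r)))
    oobAccuracy(m)
  }, numeric(1))
}

#' Stratified k-fold cross-validation accuracy
#'
#' Ten-fold stratified cross-validation (the internal-validation mode used
#' for the non-forest algorithms), seed-reproducible.
#'
#' @param X features.
#' @param y labels.
#' @param trainer function(X, y) returning a \linkS4class{SpectrumModel}.
#' @param k number of folds.
#' @param seed integer seed.
#' @return mean held-out accuracy across folds.
#' @export
crossValidate <- function(X, y, trainer, k = 10L, seed = 1L) {
  inp <- .featureInput(X)
  y <- .asLabelFactor(y)
  set.seed(as.integer(seed))
  folds <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  accs <- vapply(seq_len(k), function(f) {
    tr <- folds != f
    m <- trainer(inp$vals[tr, , drop = FALSE], y[tr])
    pred <- predictSpectrumClass(m, inp$vals[!tr, , drop = FALSE])
    mean(pred$predicted == as.character(y[!tr]))
  }, numeric(1))
  mean(accs)
}

#' Train a support-vector machine (optional plug-in)
#'
#' C-classification with a radial-basis kernel; the defaults are the
#' study's final tuned values (C = 500, gamma = 0.004). Class output only
#' (no calibrated probability).
#'
#' @param X features.
#' @param y POS/NEG labels.
#' @param C,gamma SVM hyperparameters.
#' @param seed integer seed.
#' @return a \linkS4class{SpectrumModel} with algorithm "svm".
#' @export
trainSVM <- function(X, y, C = 500, gamma = 0.004, seed = 1L) {
  inp <- .featureInput(X)
  y <- .asLabelFactor(y)
  stopifnot(length(y) == nrow(inp$vals))
  if (nlevels(droplevels(y)) < 2L)
    stop("training labels contain a single class")
  set.seed(as.integer(seed))
  fit <- e1071::svm(x = inp$vals, y = y, type = "C-classification",
                    kernel = "radial", cost = C, gamma = gamma)
  imp <- matrix(numeric(0), 0, 0)
  new("SpectrumModel", algorithm = "svm", fit = fit,
      config = list(C = C, gamma = gamma, seed = as.integer(seed)),
      featureNames = colnames(inp$vals), provenance = inp$prov,
      oobAccuracy = NA_real_, importances = imp, seed = as.integer(seed))
}
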