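# Statistical evaluation: confusion counts, the four performance
# statistics, ROC curves and model-comparison tables. POS is the positive
# class throughout.

#' Confusion counts from true and predicted labels
#'
#' @param y_true,y_pred equal-length POS/NEG label vectors.
#' @return named integer vector (tp, tn, fp, fn).
#' @export
confusionCounts <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred))
    stop("y_true and y_pred differ in length")
  y_true <- as.character(y_true); y_pred <- as.character(y_pred)
  c(tp = sum(y_true == "POS" & y_pred == "POS"),
    tn = sum(y_true == "NEG" & y_pred == "NEG"),
    fp = sum(y_true == "NEG" & y_pred == "POS"),
    fn = sum(y_true == "POS" & y_pred == "NEG"))
}

#' Performance statistics from confusion counts
#'
#' Sensitivity SE = TP/(TP+FN), specificity SP = TN/(TN+FP), overall
#' predictive accuracy Q = (TP+TN)/(TP+FN+TN+FP) and the Matthews
#' correlation coefficient
#' MCC = (TP*TN - FN*FP) / sqrt((TP+FN)(TP+FP)(TN+FN)(TN+FP)).
#' When an MCC marginal is zero the coefficient is undefined and is
#' reported as 0 with \code{mccUndefined = TRUE}. Full-precision values
#' are stored; the show method rounds half-up to two decimals as in the
#' report tables.
#'
#' @param tp,tn,fp,fn nonnegative confusion counts (or a single named
#'   vector passed as \code{tp}).
#' @return an \linkS4class{EvalReport} (metrics only; no ROC).
#' @export
metricsFromCounts <- function(tp, tn = NULL, fp = NULL, fn = NULL) {
  if (length(tp) == 4L && is.null(tn)) {
    ct <- tp; tp <- ct[["tp"]]; tn <- ct[["tn"]]
    fp <- ct[["fp"]]; fn <- ct[["fn"]]
  }
  counts <- c(tp = as.integer(tp), tn = as.integer(tn),
              fp = as.integer(fp), fn = as.integer(fn))
  total <- sum(counts)
  if (total == 0L) stop("no evaluated molecules (all counts zero)")
  se <- tp / (tp + fn)
  sp <- tn / (tn + fp)
  q <- (tp + tn) / total
  denom2 <- (tp + fn) * (tp + fp) * (tn + fn) * (tn + fp)
  undef <- denom2 == 0
  mcc <- if (undef) 0 else (tp * tn - fn * fp) / sqrt(denom2)
  new("EvalReport", counts = counts,
      metrics = c(se = se, sp = sp, q = q, mcc = mcc),
      mccUndefined = undef,
      roc = data.frame(fpr = numeric(0), tpr = numeric(0)),
      auc = NA_real_)
}

#' Evaluate predictions against true labels
#'
#' Convenience wrapper: confusion counts, the four statistics and (when
#' POS-class probabilities are supplied) the ROC curve and AUC.
#'
#' @param y_true,y_pred POS/NEG label vectors.
#' @param prob_pos optional POS-class scores for the ROC sweep.
#' @return an \linkS4class{EvalReport}.
#' @export
evaluatePredictions <- function(y_true, y_pred, prob_pos = NULL) {
  rep <- metricsFromCounts(confusionCounts(y_true, y_pred))
  if (!is.null(prob_pos)) {
    roc <- rocCurve(y_true, prob_pos)
    rep@roc <- roc$points
    rep@auc <- roc$auc
  }
  rep
}

#' ROC curve by threshold sweep
#'
#' Sweeps the distinct POS-class scores as thresholds (predict POS when
#' score >= threshold), grouping tied scores into a single step; returns
#' the (FPR, TPR) points from (0,0) to (1,1) and the trapezoidal AUC.
#'
#' @param y_true POS/NEG labels (both classes must occur).
#' @param prob_pos numeric POS-class scores.
#' @return list with \code{points} (data.frame fpr, tpr) and \code{auc}.
#' @export
rocCurve <- function(y_true, prob_pos) {
  y_true <- as.character(y_true)
  stopifnot(length(y_true) == length(prob_pos))
  n_pos <- sum(y_true == "POS"); n_neg <- sum(y_true == "NEG")
  if (n_pos == 0L || n_neg == 0L)
    stop("ROC requires both classes in y_true")
  ord <- order(prob_pos, decreasing = TRUE)
  y <- y_true[ord]; s <- prob_pos[ord]
  # cumulative counts at each distinct-score step (ties grouped)
  last_of_group <- c(s[-1] != s[-length(s)], TRUE)
  cum_tp <- cumsum(y == "POS")[last_of_group]
  cum_fp <- cumsum(y == "NEG")[last_of_group]
  pts <- data.frame(fpr = c(0, cum_fp / n_neg, 1),
                    tpr = c(0, cum_tp / n_pos, 1))
  pts <- unique(pts)
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) +
                              utils::tail(pts$tpr, -1)) / 2)
  list(points = pts, auc = auc)
}

#' Model-comparison table
#'
#' Rows sorted by descending MCC, ties by descending Q; columns mirror the
#' evaluation tables (OOB training accuracy where available, Q, SP, SE,
#' MCC, TP, TN, FP, FN), rounded half-up to two decimals.
#'
#' @param reports named list of \linkS4class{EvalReport}s.
#' @param oob optional named numeric of OOB accuracies.
#' @return data.frame, one row per model.
#' @export
comparisonTable <- function(reports, oob = NULL) {
  stopifnot(length(reports) >= 1L)
  rows <- lapply(names(reports), function(nm) {
    r <- reports[[nm]]
    m <- evalMetrics(r); ct <- evalCounts(r)
    data.frame(model = nm,
               q_train = if (!is.null(oob) && nm %in% names(oob))
                 roundHalfUp(oob[[nm]], 2) else NA_real_,
               q = roundHalfUp(m[["q"]], 2),
               sp = roundHalfUp(m[["sp"]], 2),
               se = roundHalfUp(m[["se"]], 2),
               mcc = roundHalfUp(m[["mcc"]], 2),
               tp = ct[["tp"]], tn = ct[["tn"]],
               fp = ct[["fp"]], fn = ct[["fn"]],
               .mcc_full = m[["mcc"]], .q_full = m[["q"]],
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$.mcc_full, -tab$.q_full), ]
  tab$.mcc_full <- NULL; tab$.q_full <- NULL
  rownames(tab) <- NULL
  tab
}
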