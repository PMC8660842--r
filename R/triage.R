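# Outlier triage: isolate misclassifications the model was confident
# about, then explain them via peak-list quality heuristics and
# nearest-neighbour similarity searches against the training set.

#' Tanimoto coefficient of two binary fingerprints
#'
#' Intersection over union of the set bits; two all-zero fingerprints give
#' 1 by convention.
#'
#' @param a,b equal-length binary (0/1) vectors.
#' @return similarity in [0, 1].
#' @export
tanimoto <- function(a, b) {
  if (length(a) != length(b)) stop("fingerprint lengths differ")
  a <- a != 0; b <- b != 0
  un <- sum(a | b)
  if (un == 0L) return(1)
  sum(a & b) / un
}

#' High-confidence misclassifications
#'
#' Entries for every misclassified molecule whose vote probability is
#' strictly greater than \code{p_threshold} (a probability of exactly the
#' threshold is excluded), typed FP or FN.
#'
#' @param preds data.frame from \code{\link{predictSpectrumClass}}.
#' @param truth data.frame with columns mol_id, label.
#' @param p_threshold probability cut (strict).
#' @return data.frame with columns mol_id, error_type, probability.
#' @export
highConfidenceErrors <- function(preds, truth, p_threshold = 0.8) {
  lab <- truth$label[match(preds$mol_id, truth$mol_id)]
  if (anyNA(lab)) stop("missing true labels for: ",
                       paste(utils::head(preds$mol_id[is.na(lab)], 5),
                             collapse = ", "))
  wrong <- preds$predicted != lab & preds$probability > p_threshold
  data.frame(mol_id = preds$mol_id[wrong],
             error_type = ifelse(preds$predicted[wrong] == "POS",
                                 "FP", "FN"),
             probability = preds$probability[wrong],
             stringsAsFactors = FALSE)
}

#' Explain high-confidence errors
#'
#' Populates reason codes for each triage entry: the advisory quality
#' flags of its spectrum record (near_lower_endpoint, near_mec_threshold,
#' suspect_log_mec), plus training_neighbor_conflict when a training
#' molecule with Tanimoto similarity at least \code{sim_floor} carries the
#' label matching the wrong prediction; unexplained when no rule fires.
#' The top \code{k_neighbors} training neighbours (descending similarity,
#' self-matches by id excluded) are attached.
#'
#' @param entries data.frame from \code{\link{highConfidenceErrors}}.
#' @param labels labelling table from \code{\link{labelSpectra}} (source of
#'   quality flags).
#' @param query_fp \linkS4class{FeatureMatrix} of binary fingerprints for
#'   the evaluated molecules.
#' @param train_fp \linkS4class{FeatureMatrix} of the same fingerprint
#'   family for the training set.
#' @param train_labels data.frame with columns mol_id, label for the
#'   training set.
#' @param k_neighbors neighbours kept per entry.
#' @param sim_floor similarity floor for a neighbour conflict.
#' @return data.frame: mol_id, error_type, probability, reasons
#'   (semicolon-joined), neighbor_ids, neighbor_sims, neighbor_labels.
#' @export
explainErrors <- function(entries, labels, query_fp, train_fp,
                          train_labels, k_neighbors = 3L,
                          sim_floor = 0.7) {
  qv <- featureValues(query_fp)
  tv <- featureValues(train_fp)
  stopifnot(identical(colnames(qv), colnames(tv)))
  tl <- train_labels$label[match(rownames(tv), train_labels$mol_id)]
  out <- entries
  blank <- character(nrow(entries))
  out$reasons <- blank
  out$neighbor_ids <- blank
  out$neighbor_sims <- blank
  out$neighbor_labels <- blank
  if (nrow(entries) == 0L) return(out)
  t_bin <- tv != 0
  t_pop <- rowSums(t_bin)
  for (i in seq_len(nrow(entries))) {
    id <- entries$mol_id[i]
    reasons <- intersect(
      splitFlags(labels$quality_flags[match(id, labels$mol_id)]),
      c("near_lower_endpoint", "near_mec_threshold", "suspect_log_mec"))
    if (id %in% rownames(qv)) {
      q <- qv[id, ] != 0
      inter <- as.numeric(t_bin %*% q)
      un <- t_pop + sum(q) - inter
      sims <- ifelse(un == 0, 1, inter / un)
      keep <- rownames(tv) != id
      ord <- order(-sims[keep])[seq_len(min(k_neighbors, sum(keep)))]
      nb_ids <- rownames(tv)[keep][ord]
      nb_sims <- sims[keep][ord]
      nb_lab <- tl[keep][ord]
      wrong_label <- ifelse(entries$error_type[i] == "FP", "POS", "NEG")
      if (any(nb_sims >= sim_floor & nb_lab == wrong_label))
        reasons <- c(reasons, "training_neighbor_conflict")
      out$neighbor_ids[i] <- joinFlags(nb_ids)
      out$neighbor_sims[i] <- joinFlags(sprintf("%.4f", nb_sims))
      out$neighbor_labels[i] <- joinFlags(nb_lab)
    }
    if (length(reasons) == 0L) reasons <- "unexplained"
    out$reasons[i] <- joinFlags(reasons)
  }
  out
}
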