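# Cross-evaluation of the UV-Vis spectrum class (predicted or
# experimental) against 3T3 NRU in vitro phototoxicity outcomes, treating
# the POS spectrum class as the toxicity alarm.

#' Cross-tabulate spectrum class against phototoxicity outcomes
#'
#' Builds the 2x2 table (rows: toxic / non_toxic assay outcome; columns:
#' POS / NEG spectrum class) and the alarm statistics
#' se_tox = toxic-and-POS / all-toxic and
#' sp_tox = non_toxic-and-NEG / all-non_toxic. An empty margin leaves the
#' corresponding rate NaN and flags it as undefined rather than zeroing it.
#'
#' @param classes data.frame with columns mol_id and a class column named
#'   either label or predicted (POS/NEG).
#' @param outcomes data.frame with columns mol_id, outcome
#'   ("toxic"/"non_toxic").
#' @return a \linkS4class{PhototoxCrossTab}.
#' @export
phototoxCrossTab <- function(classes, outcomes) {
  cls_col <- intersect(c("label", "predicted"), names(classes))[1]
  if (is.na(cls_col)) stop("classes needs a label or predicted column")
  cls <- classes[[cls_col]][match(outcomes$mol_id, classes$mol_id)]
  if (anyNA(cls))
    stop("no spectrum class for outcome molecules: ",
         paste(outcomes$mol_id[is.na(cls)], collapse = ", "))
  stopifnot(all(outcomes$outcome %in% c("toxic", "non_toxic")))
  counts <- matrix(
    c(sum(outcomes$outcome == "toxic" & cls == "POS"),
      sum(outcomes$outcome == "toxic" & cls == "NEG"),
      sum(outcomes$outcome == "non_toxic" & cls == "POS"),
      sum(outcomes$outcome == "non_toxic" & cls == "NEG")),
    nrow = 2, byrow = TRUE,
    dimnames = list(c("toxic", "non_toxic"), c("POS", "NEG")))
  storage.mode(counts) <- "integer"
  crossTabFromCounts(counts)
}

#' Build a PhototoxCrossTab from a 2x2 count matrix
#'
#' @param counts 2x2 matrix; rows toxic/non_toxic, columns POS/NEG.
#' @return a \linkS4class{PhototoxCrossTab}.
#' @export
crossTabFromCounts <- function(counts) {
  counts <- matrix(as.integer(counts), 2, 2,
                   dimnames = list(c("toxic", "non_toxic"),
                                   c("POS", "NEG")))
  n_tox <- sum(counts["toxic", ])
  n_non <- sum(counts["non_toxic", ])
  undef <- character(0)
  se_tox <- if (n_tox == 0L) { undef <- c(undef, "se_tox"); NaN }
            else counts["toxic", "POS"] / n_tox
  sp_tox <- if (n_non == 0L) { undef <- c(undef, "sp_tox"); NaN }
            else counts["non_toxic", "NEG"] / n_non
  new("PhototoxCrossTab", counts = counts, seTox = se_tox,
      spTox = sp_tox, undefined = undef)
}

#' Compare predicted- and experimental-class cross-tabs
#'
#' Side-by-side counts, concordant totals (toxic-and-POS plus
#' non_toxic-and-NEG) and per-cell deltas for two cross-tabs over the same
#' cohort.
#'
#' @param ct_predicted,ct_experimental \linkS4class{PhototoxCrossTab}s.
#' @return list with elements predicted, experimental (count matrices),
#'   concordant (named vector), delta (predicted - experimental).
#' @export
comparePredictors <- function(ct_predicted, ct_experimental) {
  cp <- ct_predicted@counts; ce <- ct_experimental@counts
  if (sum(cp) != sum(ce))
    stop("cross-tabs cover different cohort sizes (", sum(cp), " vs ",
         sum(ce), ")")
  conc <- c(predicted = cp["toxic", "POS"] + cp["non_toxic", "NEG"],
            experimental = ce["toxic", "POS"] + ce["non_toxic", "NEG"])
  list(predicted = cp, experimental = ce, concordant = conc,
       delta = cp - ce)
}
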