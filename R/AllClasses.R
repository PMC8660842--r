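#' @import methods
NULL

#' MoleculeSet: curated molecular structures
#'
#' Container for a set of parsed (and optionally standardized) molecular
#' structures. One row per molecule with its canonical SMILES, a
#' stereochemistry-free InChIKey used for duplicate detection, average
#' molecular weight and fragment count, plus per-molecule curation flags.
#'
#' @slot molData data.frame with columns \code{mol_id}, \code{smiles}
#'   (input), \code{canonical_smiles}, \code{inchi_key_nostereo},
#'   \code{mol_weight} (g/mol), \code{n_fragments}, \code{formula},
#'   \code{valence_ok} (logical), \code{standardized} (logical).
#' @slot nSkipped integer; input entries that failed to parse.
#'
#' @export
setClass("MoleculeSet",
  representation(molData = "data.frame", nSkipped = "integer"),
  prototype(molData = data.frame(), nSkipped = 0L)
)

setValidity("MoleculeSet", function(object) {
  need <- c("mol_id", "smiles", "canonical_smiles", "inchi_key_nostereo",
            "mol_weight", "n_fragments")
  d <- object@molData
  if (nrow(d) == 0L) return(TRUE)
  if (!all(need %in% names(d)))
    return(paste("molData lacks columns:",
                 paste(setdiff(need, names(d)), collapse = ", ")))
  if (anyDuplicated(d$mol_id)) return("mol_id values must be unique")
  if (any(d$mol_weight <= 0, na.rm = TRUE)) return("mol_weight must be > 0")
  if (any(d$n_fragments < 1, na.rm = TRUE)) return("n_fragments must be >= 1")
  TRUE
})

#' SpectrumSet: per-molecule UV-Vis absorption maxima
#'
#' Long-format peak list: one row per listed absorption maximum. The molar
#' extinction coefficient (MEC, L/mol/cm) may be missing (NA) for a peak,
#' reflecting incomplete literature peak lists. A molecule known to the set
#' but with no listed peaks is represented in \code{molIds} only.
#'
#' @slot peaks data.frame with columns \code{mol_id}, \code{wavelength_nm},
#'   \code{mec}, \code{solvent}, \code{source_id}.
#' @slot molIds character; the full molecule universe (superset of
#'   \code{peaks$mol_id}) so that empty peak lists are representable.
#'
#' @export
setClass("SpectrumSet",
  representation(peaks = "data.frame", molIds = "character"),
  prototype(peaks = data.frame(), molIds = character(0))
)

setValidity("SpectrumSet", function(object) {
  p <- object@peaks
  if (nrow(p) > 0L) {
    need <- c("mol_id", "wavelength_nm", "mec")
    if (!all(need %in% names(p)))
      return(paste("peaks lacks columns:",
                   paste(setdiff(need, names(p)), collapse = ", ")))
    if (any(p$wavelength_nm <= 0, na.rm = TRUE))
      return("wavelength_nm must be > 0")
    if (any(p$mec < 0, na.rm = TRUE)) return("mec must be >= 0 when present")
    if (!all(p$mol_id %in% object@molIds))
      return("peaks reference mol_ids absent from molIds")
  }
  TRUE
})

#' FeatureMatrix: molecules x descriptors
#'
#' Dense numeric feature matrix with molecule identifiers as row names and
#' descriptor provenance (which descriptor families, in order, produced the
#' columns). Molecules a calculator failed on are tracked in \code{dropped},
#' mirroring the per-family training-set size differences seen with real
#' descriptor calculators.
#'
#' @slot values numeric matrix, rows = molecules (rownames = mol_id).
#' @slot provenance character vector of descriptor-set names.
#' @slot dropped character vector of mol_ids that failed featurization.
#'
#' @export
setClass("FeatureMatrix",
  representation(values = "matrix", provenance = "character",
                 dropped = "character"),
  prototype(values = matrix(numeric(0), 0, 0), provenance = character(0),
            dropped = character(0))
)

setValidity("FeatureMatrix", function(object) {
  v <- object@values
  if (nrow(v) > 0L && is.null(rownames(v)))
    return("values must carry mol_id rownames")
  if (anyNA(v)) return("feature matrix must not contain missing values")
  if (!is.null(rownames(v)) && anyDuplicated(rownames(v)))
    return("duplicate mol_id rownames")
  TRUE
})

#' SpectrumModel: a trained spectrum-class model
#'
#' Wrapper around a fitted classifier predicting the POS/NEG UV-Vis spectrum
#' class, retaining its configuration, feature provenance, seed, per-column
#' importances and (for random forests) the out-of-bag accuracy.
#'
#' @slot algorithm one of "rf", "cart", "svm", "mlp".
#' @slot fit the fitted model object.
#' @slot config list; configuration snapshot.
#' @slot featureNames character; training column names (provenance contract
#'   for prediction).
#' @slot provenance character; descriptor-set names.
#' @slot oobAccuracy numeric; out-of-bag accuracy (rf) or NA.
#' @slot importances matrix or NULL-like matrix; per-column importance scores
#'   (columns \code{MeanDecreaseAccuracy}, \code{MeanDecreaseGini} for rf).
#' @slot seed integer seed used for training.
#'
#' @export
setClass("SpectrumModel",
  representation(algorithm = "character", fit = "ANY", config = "list",
                 featureNames = "character", provenance = "character",
                 oobAccuracy = "numeric", importances = "matrix",
                 seed = "integer")
)

setValidity("SpectrumModel", function(object) {
  if (!object@algorithm %in% c("rf", "cart", "svm", "mlp"))
    return("algorithm must be rf, cart, svm or mlp")
  if (nrow(object@importances) > 0L &&
      nrow(object@importances) != length(object@featureNames))
    return("importances rows must match feature count")
  TRUE
})

#' EvalReport: confusion counts and the four performance statistics
#'
#' Holds TP/TN/FP/FN and the derived sensitivity SE = TP/(TP+FN),
#' specificity SP = TN/(TN+FP), overall accuracy Q = (TP+TN)/total and the
#' Matthews correlation coefficient, plus (optionally) ROC points and AUC.
#'
#' @slot counts named integer vector (tp, tn, fp, fn).
#' @slot metrics named numeric vector (se, sp, q, mcc), full precision.
#' @slot mccUndefined logical; TRUE when an MCC marginal was zero and the
#'   value was reported as 0 by convention.
#' @slot roc data.frame with columns fpr, tpr (possibly empty).
#' @slot auc numeric; trapezoidal AUC or NA.
#'
#' @export
setClass("EvalReport",
  representation(counts = "integer", metrics = "numeric",
                 mccUndefined = "logical", roc = "data.frame",
                 auc = "numeric")
)

setValidity("EvalReport", function(object) {
  if (!all(c("tp", "tn", "fp", "fn") %in% names(object@counts)))
    return("counts must be named tp, tn, fp, fn")
  if (any(object@counts < 0)) return("counts must be nonnegative")
  TRUE
})

#' PhototoxCrossTab: spectrum class vs in vitro phototoxicity
#'
#' 2x2 cross-tabulation of a POS/NEG spectrum class (predicted or
#' experimental) against 3T3 NRU phototoxicity outcomes, with the POS class
#' treated as the toxicity alarm.
#'
#' @slot counts 2x2 integer matrix; rows toxic/non_toxic, columns POS/NEG.
#' @slot seTox numeric; toxic-and-POS / all-toxic.
#' @slot spTox numeric; non_toxic-and-NEG / all-non_toxic.
#' @slot undefined character; which of se_tox/sp_tox had an empty margin.
#'
#' @export
setClass("PhototoxCrossTab",
  representation(counts = "matrix", seTox = "numeric", spTox = "numeric",
                 undefined = "character")
)

setValidity("PhototoxCrossTab", function(object) {
  if (!identical(dim(object@counts), c(2L, 2L)))
    return("counts must be a 2x2 matrix")
  if (any(object@counts < 0)) return("counts must be nonnegative")
  TRUE
})
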