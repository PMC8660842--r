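#' Accessor generics
#'
#' Small accessor family for the package's S4 containers: molecule
#' identifiers, molecule-level tables, peak tables and feature values.
#'
#' @param object an S4 object from this package
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("molIds", function(object) standardGeneric("molIds"))

#' @rdname accessors
#' @export
setGeneric("molData", function(object) standardGeneric("molData"))

#' @rdname accessors
#' @export
setGeneric("peakTable", function(object) standardGeneric("peakTable"))

#' @rdname accessors
#' @export
setGeneric("featureValues", function(object) standardGeneric("featureValues"))

#' @rdname accessors
#' @export
setGeneric("provenance", function(object) standardGeneric("provenance"))

#' @rdname accessors
#' @export
setGeneric("droppedMolecules",
           function(object) standardGeneric("droppedMolecules"))

#' @rdname accessors
#' @export
setGeneric("oobAccuracy", function(object) standardGeneric("oobAccuracy"))

#' @rdname accessors
#' @export
setGeneric("importances", function(object) standardGeneric("importances"))

#' @rdname accessors
#' @export
setGeneric("evalCounts", function(object) standardGeneric("evalCounts"))

#' @rdname accessors
#' @export
setGeneric("evalMetrics", function(object) standardGeneric("evalMetrics"))

# ---- methods -----------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("molIds", "MoleculeSet", function(object) object@molData$mol_id)

#' @rdname accessors
#' @export
setMethod("molIds", "SpectrumSet", function(object) object@molIds)

#' @rdname accessors
#' @export
setMethod("molIds", "FeatureMatrix", function(object) rownames(object@values))

#' @rdname accessors
#' @export
setMethod("molData", "MoleculeSet", function(object) object@molData)

#' @rdname accessors
#' @export
setMethod("peakTable", "SpectrumSet", function(object) object@peaks)

#' @rdname accessors
#' @export
setMethod("featureValues", "FeatureMatrix", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("provenance", "FeatureMatrix", function(object) object@provenance)

#' @rdname accessors
#' @export
setMethod("provenance", "SpectrumModel", function(object) object@provenance)

#' @rdname accessors
#' @export
setMethod("droppedMolecules", "FeatureMatrix",
          function(object) object@dropped)

#' @rdname accessors
#' @export
setMethod("oobAccuracy", "SpectrumModel", function(object) object@oobAccuracy)

#' @rdname accessors
#' @export
setMethod("importances", "SpectrumModel", function(object) object@importances)

#' @rdname accessors
#' @export
setMethod("evalCounts", "EvalReport", function(object) object@counts)

#' @rdname accessors
#' @export
setMethod("evalMetrics", "EvalReport", function(object) object@metrics)

# ---- show methods ------------------------------------------------------

setMethod("show", "MoleculeSet", function(object) {
  d <- object@molData
  cat("MoleculeSet with", nrow(d), "molecules",
      sprintf("(%d unparseable entries skipped)\n", object@nSkipped))
  if (nrow(d) > 0L) {
    cat("  standardized:", sum(isTRUE(d$standardized) | d$standardized %in% TRUE),
        " MW range:", sprintf("%.1f-%.1f g/mol\n",
                              min(d$mol_weight), max(d$mol_weight)))
    utils::head(d[, c("mol_id", "canonical_smiles", "mol_weight")], 3) |>
      print()
    if (nrow(d) > 3L) cat("  ...\n")
  }
})

setMethod("show", "SpectrumSet", function(object) {
  cat("SpectrumSet:", length(object@molIds), "molecules,",
      nrow(object@peaks), "listed absorption maxima\n")
  if (nrow(object@peaks) > 0L)
    cat("  wavelength range:",
        sprintf("%.0f-%.0f nm; MEC missing for %d peaks\n",
                min(object@peaks$wavelength_nm),
                max(object@peaks$wavelength_nm),
                sum(is.na(object@peaks$mec))))
})

setMethod("show", "FeatureMatrix", function(object) {
  cat("FeatureMatrix:", nrow(object@values), "molecules x",
      ncol(object@values), "descriptors\n")
  cat("  provenance:", paste(object@provenance, collapse = " + "), "\n")
  if (length(object@dropped))
    cat("  dropped (featurization failure):", length(object@dropped), "\n")
})

setMethod("show", "SpectrumModel", function(object) {
  cat("SpectrumModel [", object@algorithm, "] on",
      length(object@featureNames), "features (",
      paste(object@provenance, collapse = " + "), ")\n")
  if (!is.na(object@oobAccuracy))
    cat("  out-of-bag accuracy:", sprintf("%.4f\n", object@oobAccuracy))
})

setMethod("show", "EvalReport", function(object) {
  ct <- object@counts
  m <- object@metrics
  cat(sprintf("EvalReport: TP %d  TN %d  FP %d  FN %d\n",
              ct["tp"], ct["tn"], ct["fp"], ct["fn"]))
  cat(sprintf("  SE %.2f  SP %.2f  Q %.2f  MCC %.2f%s\n",
              roundHalfUp(m["se"], 2), roundHalfUp(m["sp"], 2),
              roundHalfUp(m["q"], 2), roundHalfUp(m["mcc"], 2),
              if (object@mccUndefined) "  (MCC undefined -> 0)" else ""))
  if (!is.na(object@auc)) cat(sprintf("  AUC %.3f\n", object@auc))
})

setMethod("show", "PhototoxCrossTab", function(object) {
  cat("PhototoxCrossTab (rows: assay outcome; cols: spectrum class)\n")
  print(object@counts)
  cat(sprintf("  se_tox %.2f  sp_tox %.2f  concordant %d\n",
              roundHalfUp(object@seTox, 2), roundHalfUp(object@spTox, 2),
              object@counts[1, 1] + object@counts[2, 2]))
  if (length(object@undefined))
    cat("  undefined:", paste(object@undefined, collapse = ", "), "\n")
})
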