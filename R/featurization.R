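# Feature-matrix assembly. Fingerprints are computed by Open Babel through
# ChemmineOB: the circular "morgan" family is ECFP4 (radius-2 circular
# environments) folded from 4096 to 1024 bits, "maccs" is the 166-key MACCS
# set. "md" is the package's own modified-distance histogram and "oned2d"
# a documented set of 1D/2D constitutional and physicochemical descriptors.

.FP_SETS <- c("morgan", "maccs", "md", "oned2d")

# OR-fold a wide binary fingerprint matrix down to n_bits columns.
.foldBits <- function(mat, n_bits) {
  if (ncol(mat) <= n_bits) return(mat)
  folded <- matrix(0L, nrow(mat), n_bits)
  for (k in seq_len(ncol(mat) / n_bits)) {
    block <- mat[, ((k - 1L) * n_bits + 1L):(k * n_bits), drop = FALSE]
    folded <- pmax(folded, block)
  }
  folded
}

.obFingerprints <- function(smiles, name) {
  refs <- ChemmineOB::forEachMol("SMILES",
                                 paste(smiles, collapse = "\n"), identity)
  m <- suppressWarnings(ChemmineOB::fingerprint_OB(refs, name))
  if (is.null(dim(m))) m <- matrix(m, nrow = 1L)
  m
}

# 1D/2D descriptor row(s): Open Babel properties plus connectivity counts.
.oned2dMatrix <- function(smiles) {
  refs <- ChemmineOB::forEachMol("SMILES",
                                 paste(smiles, collapse = "\n"), identity)
  props <- suppressWarnings(ChemmineOB::prop_OB(refs))
  graphs <- lapply(smiles, smilesToGraph, addH = TRUE)
  conn <- t(vapply(graphs, function(g) {
    if (is.null(g)) return(rep(NA_real_, 7))
    heavy <- g$elements != "H"
    n_heavy <- sum(heavy)
    n_bonds_heavy <- if (nrow(g$bonds)) sum(g$elements[g$bonds[, 1]] != "H" &
                                            g$elements[g$bonds[, 2]] != "H")
                     else 0L
    comps <- 1L  # curated single-fragment molecules
    c(n_atoms = g$n,
      n_heavy = n_heavy,
      n_bonds_heavy = n_bonds_heavy,
      n_rings = max(0L, n_bonds_heavy - n_heavy + comps),
      n_hetero = sum(heavy & !(g$elements %in% c("C", "H"))),
      n_halogen = sum(g$elements %in% c("F", "Cl", "Br", "I")),
      n_unsat_bonds = if (nrow(g$bonds)) sum(g$bonds[, 3] > 1L) else 0L)
  }, numeric(7)))
  out <- cbind(MW = props$MW, logP = props$logP, TPSA = props$TPSA,
               MR = props$MR, HBA = props$HBA2, HBD = props$HBD, conn)
  out
}

#' Compute one descriptor family for a molecule set
#'
#' Families: \code{"morgan"} — circular (ECFP4-type) fingerprint folded to
#' 1024 bits; \code{"maccs"} — 166 MACCS keys; \code{"md"} —
#' modified-distance histogram (1010 counts, see \code{\link{mdMatrix}});
#' \code{"oned2d"} — 13 1D/2D descriptors (MW, logP, TPSA, MR, HBA, HBD
#' and connectivity counts). Binary families yield 0/1 columns; molecules a
#' calculator fails on are dropped and recorded in the result.
#'
#' @param mols a \linkS4class{MoleculeSet} or named character vector of
#'   SMILES.
#' @param set descriptor family name.
#' @param md_cfg \code{\link{mdConfig}} for the "md" family.
#' @return a \linkS4class{FeatureMatrix}.
#' @export
computeFingerprints <- function(mols, set = c("morgan", "maccs", "md",
                                              "oned2d"),
                                md_cfg = mdConfig()) {
  set <- match.arg(set)
  if (set == "md") return(mdMatrix(mols, md_cfg))
  if (is(mols, "MoleculeSet")) {
    smiles <- molData(mols)$canonical_smiles
    ids <- molIds(mols)
  } else {
    smiles <- unname(mols)
    ids <- names(mols)
    if (is.null(ids)) ids <- sprintf("mol%05d", seq_along(smiles))
  }
  parseable <- vapply(smiles, function(s) {
    out <- tryCatch(
      suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN",
                                                 paste0(s, "\n"))),
      error = function(e) "")
    nzchar(trimws(out))
  }, logical(1), USE.NAMES = FALSE)
  use <- which(parseable)
  vals <- switch(set,
    morgan = {
      m <- .foldBits(.obFingerprints(smiles[use], "ECFP4"), 1024L)
      colnames(m) <- sprintf("Morgan%04d", seq_len(1024L))
      m
    },
    maccs = {
      m <- .obFingerprints(smiles[use], "MACCS")[, 1:166, drop = FALSE]
      colnames(m) <- sprintf("MACCS%03d", seq_len(166L))
      m
    },
    oned2d = {
      m <- .oned2dMatrix(smiles[use])
      colnames(m) <- c("MW", "logP", "TPSA", "MR", "HBA", "HBD",
                       "n_atoms", "n_heavy", "n_bonds_heavy", "n_rings",
                       "n_hetero", "n_halogen", "n_unsat_bonds")
      m
    })
  if (length(use) == 1L && is.null(dim(vals)))
    vals <- matrix(vals, nrow = 1L, dimnames = list(NULL, names(vals)))
  bad <- apply(vals, 1L, anyNA)
  vals <- vals[!bad, , drop = FALSE]
  rownames(vals) <- ids[use][!bad]
  dropped <- c(ids[!parseable], ids[use][bad])
  new("FeatureMatrix", values = vals,
      provenance = c(morgan = "Morgan", maccs = "MACCS",
                     oned2d = "1D2D")[[set]],
      dropped = dropped)
}

#' Column-wise combination of feature matrices
#'
#' Restricts to the molecules successfully featurized by every input set
#' and concatenates columns; provenance lists all source sets in order.
#'
#' @param mats list of \linkS4class{FeatureMatrix} objects.
#' @return a combined \linkS4class{FeatureMatrix}.
#' @export
combineFeatureMatrices <- function(mats) {
  stopifnot(length(mats) >= 1L,
            all(vapply(mats, is, logical(1), "FeatureMatrix")))
  if (length(mats) == 1L) return(mats[[1]])
  common <- Reduce(intersect, lapply(mats, molIds))
  if (length(common) == 0L)
    stop("no molecule is covered by every feature matrix")
  vals <- do.call(cbind, lapply(mats, function(m)
    featureValues(m)[common, , drop = FALSE]))
  dropped <- setdiff(Reduce(union, lapply(mats, molIds)), common)
  dropped <- union(dropped, unlist(lapply(mats, droppedMolecules)))
  new("FeatureMatrix", values = vals,
      provenance = unlist(lapply(mats, provenance)),
      dropped = dropped)
}

#' Read an externally computed quantum-descriptor table
#'
#' Pass-through loader for estimated molecular-orbital energies (E_HOMO,
#' E_LUMO and GAP estimates from several models; 10 columns, eV). These
#' values come from external models and are not computed here.
#'
#' @param path CSV with a mol_id column plus exactly 10 numeric columns.
#' @return a \linkS4class{FeatureMatrix} with provenance "QD".
#' @export
readExternalQD <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"mol_id" %in% names(d)) stop("QD table needs a mol_id column")
  vals <- as.matrix(d[, setdiff(names(d), "mol_id"), drop = FALSE])
  if (ncol(vals) != 10L)
    stop("QD table must have exactly 10 descriptor columns, found ",
         ncol(vals))
  storage.mode(vals) <- "double"
  rownames(vals) <- as.character(d$mol_id)
  new("FeatureMatrix", values = vals, provenance = "QD",
      dropped = character(0))
}
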