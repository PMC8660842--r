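#' Parse molecular structures into a MoleculeSet
#'
#' Reads a SMILES file (one record per line, optional tab-separated
#' identifier) or an SDF v2000 file and returns one \linkS4class{MoleculeSet}
#' record per parseable entry. Unparseable entries are skipped and counted.
#'
#' @param path input file path.
#' @param format "smiles" or "sdf".
#' @return a \linkS4class{MoleculeSet}; the number of skipped entries is
#'   available via \code{nSkipped()}.
#' @export
parseStructures <- function(path, format = c("smiles", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("input file does not exist: ", path)
  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines) == 0L) stop("no entries found in ", path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    smiles <- vapply(parts, `[[`, character(1), 1)
    ids <- vapply(seq_along(parts), function(i) {
      if (length(parts[[i]]) >= 2 && nzchar(parts[[i]][2])) parts[[i]][2]
      else sprintf("mol%05d", i)
    }, character(1))
  } else {
    txt <- readChar(path, file.size(path), useBytes = TRUE)
    blocks <- strsplit(txt, "\\${4}[ \t]*\r?\n?")[[1]]
    blocks <- blocks[nzchar(trimws(blocks))]
    if (length(blocks) == 0L) stop("no entries found in ", path)
    smiles <- vapply(blocks, function(b) {
      out <- tryCatch(
        suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", b)),
        error = function(e) "")
      if (nzchar(out)) strsplit(trimws(out), "\t")[[1]][1] else NA_character_
    }, character(1), USE.NAMES = FALSE)
    ids <- vapply(seq_along(blocks), function(i) {
      ttl <- trimws(strsplit(blocks[[i]], "\n")[[1]][1])
      if (nzchar(ttl)) ttl else sprintf("mol%05d", i)
    }, character(1))
  }
  recs <- .describeMolecules(ids, smiles)
  skipped <- sum(is.na(recs$canonical_smiles))
  if (skipped > 0L)
    message(skipped, " entr", if (skipped == 1L) "y" else "ies",
            " could not be parsed and were skipped")
  recs <- recs[!is.na(recs$canonical_smiles), , drop = FALSE]
  if (nrow(recs) == 0L) stop("zero parseable entries in ", path)
  if (anyDuplicated(recs$mol_id))
    recs$mol_id <- make.unique(recs$mol_id, sep = "_dup")
  rownames(recs) <- NULL
  new("MoleculeSet", molData = recs, nSkipped = as.integer(skipped))
}

# Compute the per-molecule record table for a vector of SMILES. Entries that
# Open Babel cannot parse get NA canonical_smiles. Not exported.
.describeMolecules <- function(ids, smiles, standardized = FALSE) {
  n <- length(smiles)
  out <- data.frame(
    mol_id = ids, smiles = smiles,
    canonical_smiles = NA_character_, inchi_key_nostereo = NA_character_,
    mol_weight = NA_real_, n_fragments = NA_integer_,
    formula = NA_character_, net_charge = NA_integer_,
    has_metal = NA, has_radical = NA, valence_ok = NA,
    standardized = standardized, stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    smi <- smiles[i]
    if (is.na(smi) || !nzchar(trimws(smi))) next
    props <- tryCatch(
      suppressWarnings(ChemmineOB::prop_OB(
        ChemmineOB::forEachMol("SMILES", trimws(smi), identity))),
      error = function(e) NULL)
    if (is.null(props) || nrow(props) == 0L || !nzchar(props$cansmi[1]) ||
        is.na(props$MW[1]) || props$MW[1] <= 0) next
    can <- trimws(props$cansmi[1])
    canNS <- trimws(props$cansmiNS[1])
    ik <- tryCatch(
      suppressWarnings(trimws(ChemmineOB::convertFormat(
        "SMI", "INCHIKEY", paste0(canNS, "\n")))),
      error = function(e) NA_character_)
    if (is.na(ik) || !nzchar(ik)) next
    g <- smilesToGraph(can, addH = TRUE)
    out$canonical_smiles[i] <- can
    out$inchi_key_nostereo[i] <- ik
    out$mol_weight[i] <- props$MW[1]
    out$n_fragments[i] <- length(gregexpr(".", can, fixed = TRUE)[[1]][
      gregexpr(".", can, fixed = TRUE)[[1]] > 0]) + 1L
    out$formula[i] <- props$formula[1]
    out$net_charge[i] <- graphNetCharge(g)
    out$has_metal[i] <- graphHasMetal(g)
    out$has_radical[i] <- if (is.null(g)) NA else g$radical
    out$valence_ok[i] <- graphValenceOK(g)
  }
  out
}

#' Standardize molecular structures
#'
#' Normalizes tautomerism, mesomerism and aromaticity by round-tripping each
#' structure through the standard InChI: SMILES -> InChI -> structure ->
#' canonical SMILES. The InChI mobile-hydrogen layer collapses tautomers to
#' one fixed representative, its charge rearrangement collapses
#' charge-separated mesomers (e.g. the two nitro-group conventions), and the
#' output canonical SMILES fixes one aromaticity perception. The operation
#' is deterministic and idempotent. Structures whose explicit-hydrogen
#' connection table violates the neutral-valence model are flagged
#' (\code{valence_ok = FALSE}) for the eligibility filter.
#'
#' @param mols a \linkS4class{MoleculeSet}.
#' @return a \linkS4class{MoleculeSet} with refreshed canonical SMILES,
#'   identifiers and structure flags, \code{standardized = TRUE}.
#' @export
standardizeMolecules <- function(mols) {
  stopifnot(is(mols, "MoleculeSet"))
  d <- molData(mols)
  if (nrow(d) == 0L) return(mols)
  std <- vapply(d$canonical_smiles, function(smi) {
    inchi <- tryCatch(
      suppressWarnings(trimws(ChemmineOB::convertFormat(
        "SMI", "INCHI", paste0(smi, "\n")))),
      error = function(e) "")
    if (!nzchar(inchi)) return(NA_character_)
    back <- tryCatch(
      suppressWarnings(trimws(ChemmineOB::convertFormat(
        "INCHI", "CAN", paste0(inchi, "\n")))),
      error = function(e) "")
    if (!nzchar(back)) return(NA_character_)
    strsplit(back, "\t")[[1]][1]
  }, character(1), USE.NAMES = FALSE)
  ok <- !is.na(std)
  newd <- .describeMolecules(d$mol_id, ifelse(ok, std, d$canonical_smiles),
                             standardized = TRUE)
  # A failed round-trip keeps the parsed structure but is marked as a
  # valence problem so filterEligible() discards it.
  newd$valence_ok[!ok] <- FALSE
  newd$smiles <- d$smiles
  rownames(newd) <- NULL
  new("MoleculeSet", molData = newd, nSkipped = mols@nSkipped)
}

#' Eligibility rule for the modelling set
#'
#' Structure-eligibility thresholds: molecular weight within
#' [\code{mw_min}, \code{mw_max}] g/mol (98-1080 by default), a single
#' fragment, no metal atoms, zero net charge, no radicals and no valence
#' errors.
#'
#' @param mw_min,mw_max molecular-weight window in g/mol.
#' @param max_fragments maximum number of disconnected components.
#' @param allow_metals,allow_net_charge,allow_radicals logicals; defaults
#'   FALSE.
#' @return an eligibility-rule list.
#' @export
eligibilityRule <- function(mw_min = 98, mw_max = 1080, max_fragments = 1L,
                            allow_metals = FALSE, allow_net_charge = FALSE,
                            allow_radicals = FALSE) {
  stopifnot(mw_min < mw_max, max_fragments >= 1L)
  structure(list(mw_min = mw_min, mw_max = mw_max,
                 max_fragments = as.integer(max_fragments),
                 allow_metals = allow_metals,
                 allow_net_charge = allow_net_charge,
                 allow_radicals = allow_radicals),
            class = "eligibilityRule")
}

#' Filter molecules by the eligibility rule
#'
#' Partitions a standardized \linkS4class{MoleculeSet} into kept and
#' rejected molecules. Each rejection carries exactly one primary reason
#' code, assigned in the precedence order metal > charged > radical >
#' valence > multifragment > mw_low > mw_high.
#'
#' @param mols a \linkS4class{MoleculeSet}.
#' @param rule an \code{\link{eligibilityRule}}.
#' @return list with elements \code{kept} (MoleculeSet) and \code{rejected}
#'   (data.frame with columns mol_id, reason).
#' @export
filterEligible <- function(mols, rule = eligibilityRule()) {
  stopifnot(is(mols, "MoleculeSet"), inherits(rule, "eligibilityRule"))
  d <- molData(mols)
  reason <- rep(NA_character_, nrow(d))
  pick <- function(cond, code) ifelse(is.na(reason) & cond, code, reason)
  if (!rule$allow_metals) reason <- pick(d$has_metal %in% TRUE, "metal")
  if (!rule$allow_net_charge)
    reason <- pick(!is.na(d$net_charge) & d$net_charge != 0L, "charged")
  if (!rule$allow_radicals) reason <- pick(d$has_radical %in% TRUE, "radical")
  reason <- pick(!d$valence_ok %in% TRUE, "valence")
  reason <- pick(d$n_fragments > rule$max_fragments, "multifragment")
  reason <- pick(d$mol_weight < rule$mw_min, "mw_low")
  reason <- pick(d$mol_weight > rule$mw_max, "mw_high")
  keep <- is.na(reason)
  kept <- new("MoleculeSet", molData = d[keep, , drop = FALSE],
              nSkipped = mols@nSkipped)
  rejected <- data.frame(mol_id = d$mol_id[!keep],
                         reason = reason[!keep],
                         stringsAsFactors = FALSE)
  rownames(kept@molData) <- NULL
  list(kept = kept, rejected = rejected)
}

#' Remove duplicate structures
#'
#' Collapses molecules sharing one stereochemistry-free InChIKey (so
#' stereoisomers count as duplicates) to the first occurrence. When a
#' \linkS4class{SpectrumSet} is supplied, the peak lists of removed
#' duplicates are unioned onto the kept molecule, so a peak reported for any
#' stereoisomer contributes to the kept record's label.
#'
#' @param mols a \linkS4class{MoleculeSet}.
#' @param spectra optional \linkS4class{SpectrumSet} to merge alongside.
#' @return the deduplicated MoleculeSet, or (when \code{spectra} is given) a
#'   list with elements \code{molecules} and \code{spectra}.
#' @export
deduplicateMolecules <- function(mols, spectra = NULL) {
  stopifnot(is(mols, "MoleculeSet"))
  d <- molData(mols)
  first <- !duplicated(d$inchi_key_nostereo)
  kept <- new("MoleculeSet", molData = d[first, , drop = FALSE],
              nSkipped = mols@nSkipped)
  rownames(kept@molData) <- NULL
  if (is.null(spectra)) return(kept)
  stopifnot(is(spectra, "SpectrumSet"))
  # map every duplicate id onto the id kept for its key
  keeper <- d$mol_id[first][match(d$inchi_key_nostereo,
                                  d$inchi_key_nostereo[first])]
  names(keeper) <- d$mol_id
  pk <- peakTable(spectra)
  if (nrow(pk) > 0L) {
    mapped <- keeper[pk$mol_id]
    pk$mol_id <- ifelse(is.na(mapped), pk$mol_id, unname(mapped))
    pk <- unique(pk)
    rownames(pk) <- NULL
  }
  ids <- union(kept@molData$mol_id, setdiff(molIds(spectra), names(keeper)))
  list(molecules = kept,
       spectra = new("SpectrumSet", peaks = pk, molIds = ids))
}

#' Write a curation audit table
#'
#' One row per input molecule recording whether it was kept and, if not,
#' the primary rejection reason.
#'
#' @param kept MoleculeSet of retained molecules.
#' @param rejected data.frame from \code{\link{filterEligible}}.
#' @param path output CSV path.
#' @return the audit data.frame, invisibly.
#' @export
writeCurationAudit <- function(kept, rejected, path) {
  aud <- rbind(
    data.frame(mol_id = molIds(kept), status = "kept", reason = "",
               stringsAsFactors = FALSE),
    data.frame(mol_id = rejected$mol_id, status = "rejected",
               reason = rejected$reason, stringsAsFactors = FALSE))
  utils::write.csv(aud, path, row.names = FALSE)
  invisible(aud)
}
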