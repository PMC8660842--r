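# Internal connection-table layer shared by the curation checks and the
# modified-distance descriptors. Structures are parsed by Open Babel
# (ChemmineOB) into kekulized V2000 molfiles with explicit hydrogens; the
# atom/bond blocks are lifted with ChemmineR.

# Elements of the organic subset; anything else counts as a metal for the
# eligibility filter.
.ORGANIC_ELEMENTS <- c("H", "B", "C", "N", "O", "F", "Si", "P", "S",
                       "Cl", "Se", "Br", "I")

# Allowed total bond orders (explicit-H kekulized molfile) per element for
# the neutral-valence check. Pentavalent N is included because the
# mesomerism normalization writes nitro/N-oxide groups uncharged.
.ALLOWED_VALENCE <- list(
  H = 1L, B = 3L, C = 4L, N = c(3L, 5L), O = 2L, F = 1L, Si = 4L,
  P = c(3L, 5L), S = c(2L, 4L, 6L), Cl = 1L, Se = c(2L, 4L, 6L),
  Br = 1L, I = c(1L, 3L)
)

# SMILES -> V2000 molfile text (explicit hydrogens on request). Returns NA
# on conversion failure.
smilesToMolfile <- function(smiles, addH = TRUE) {
  opts <- if (addH) data.frame(names = "h", args = "") else
    data.frame(names = character(0), args = character(0))
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF",
                                               paste0(smiles, "\n"),
                                               options = opts)),
    error = function(e) NA_character_)
  if (is.na(out) || !nzchar(out)) NA_character_ else out
}

# Molfile text -> molecular graph: elements, charges, radical flag,
# bond list with orders, adjacency. Uses ChemmineR's SDF parser for the
# atom/bond blocks; M CHG / M RAD property lines are read from the text
# (ChemmineR keeps them in the data block header lines).
molfileToGraph <- function(sdftext) {
  lines <- strsplit(sdftext, "\n", fixed = TRUE)[[1]]
  while (length(lines) && !nzchar(trimws(lines[length(lines)])))
    lines <- lines[-length(lines)]
  if (!any(grepl("^\\$\\$\\$\\$", lines))) lines <- c(lines, "$$$$")
  tf <- tempfile(fileext = ".sdf")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  sdfset <- tryCatch(suppressWarnings(ChemmineR::read.SDFset(tf)),
                     error = function(e) NULL)
  if (is.null(sdfset) || length(sdfset) == 0L) return(NULL)
  sdf <- sdfset[[1]]
  ab <- ChemmineR::atomblock(sdf)
  bb <- ChemmineR::bondblock(sdf)
  elements <- sub("_.*$", "", rownames(ab))
  n <- length(elements)
  charges <- integer(n)
  radical <- FALSE
  for (ln in grep("^M  (CHG|RAD)", lines, value = TRUE)) {
    toks <- strsplit(trimws(ln), "\\s+")[[1]]
    kind <- toks[2]
    k <- as.integer(toks[3])
    pairs <- matrix(as.integer(toks[4:(3 + 2 * k)]), ncol = 2, byrow = TRUE)
    if (kind == "CHG") charges[pairs[, 1]] <- pairs[, 2]
    if (kind == "RAD") radical <- TRUE
  }
  bonds <- if (is.null(dim(bb)) || nrow(bb) == 0L || ncol(bb) < 3L) {
    matrix(integer(0), 0, 3)
  } else {
    cbind(as.integer(bb[, 1]), as.integer(bb[, 2]), as.integer(bb[, 3]))
  }
  bonds <- bonds[bonds[, 1] >= 1L & bonds[, 2] >= 1L &
                 bonds[, 1] <= n & bonds[, 2] <= n, , drop = FALSE]
  adj <- vector("list", n)
  if (nrow(bonds) > 0L) {
    for (b in seq_len(nrow(bonds))) {
      i <- bonds[b, 1]; j <- bonds[b, 2]
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
    }
  }
  list(elements = elements, charges = charges, radical = radical,
       bonds = bonds, adj = adj, n = n)
}

#' Parse a SMILES into a molecular graph
#'
#' Explicit-hydrogen connection table: elements, formal charges, bond list
#' with orders and an adjacency list. This is the structure representation
#' the modified-distance descriptors operate on.
#'
#' @param smiles SMILES string.
#' @param addH add explicit hydrogens (default TRUE).
#' @return list with elements, charges, radical, bonds, adj, n; NULL when
#'   the SMILES cannot be parsed.
#' @export
smilesToGraph <- function(smiles, addH = TRUE) {
  sdftext <- smilesToMolfile(smiles, addH = addH)
  if (is.na(sdftext)) return(NULL)
  molfileToGraph(sdftext)
}

# Neutral-valence check on an explicit-H graph: TRUE when every uncharged
# atom's total bond order is an allowed valence for its element. Charged
# atoms are not checked (charged molecules are rejected separately).
graphValenceOK <- function(g) {
  if (is.null(g)) return(FALSE)
  orders <- numeric(g$n)
  if (nrow(g$bonds) > 0L) {
    for (b in seq_len(nrow(g$bonds))) {
      o <- g$bonds[b, 3]
      orders[g$bonds[b, 1]] <- orders[g$bonds[b, 1]] + o
      orders[g$bonds[b, 2]] <- orders[g$bonds[b, 2]] + o
    }
  }
  for (i in seq_len(g$n)) {
    if (g$charges[i] != 0L) next
    allowed <- .ALLOWED_VALENCE[[g$elements[i]]]
    if (is.null(allowed)) next        # unusual element; metal rule handles it
    if (!(orders[i] %in% allowed)) return(FALSE)
  }
  TRUE
}

graphHasMetal <- function(g) {
  if (is.null(g)) return(NA)
  any(!(g$elements %in% .ORGANIC_ELEMENTS))
}

graphNetCharge <- function(g) if (is.null(g)) NA_integer_ else sum(g$charges)
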