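# Modified-distance (Md) atom-pair descriptors.
#
# The descriptor counts heavy-atom pairs at "modified" topological
# distances: the bond-count distance is scaled by a distance factor and
# corrected by per-atom effective radii built from Bondi van der Waals
# radii and the Sanderson electronegativities of each atom's neighbours
# (hydrogens included in the neighbour averaging). Only connectivity is
# used: no bond orders, formal charges, aromaticity perception or 3D
# coordinates enter the computation.

# Bondi van der Waals radii (Angstrom); B and Si from the common extension
# of the Bondi set.
.VDW_RADII <- c(H = 1.20, B = 1.92, C = 1.70, N = 1.55, O = 1.52,
                F = 1.47, Si = 2.10, P = 1.80, S = 1.80, Cl = 1.75,
                Se = 1.90, Br = 1.85, I = 1.98)

# Sanderson electronegativities.
.SANDERSON_EN <- c(H = 2.592, B = 2.275, C = 2.746, N = 3.194, O = 3.654,
                   F = 4.000, Si = 2.138, P = 2.515, S = 2.957,
                   Cl = 3.475, Se = 3.014, Br = 3.219, I = 2.778)

.ELEMENT_TABLE_VERSION <- "bondi-sanderson-1"

#' Md descriptor configuration
#'
#' Defaults: 1010 histogram intervals at resolution 0.017, atom pairs up to
#' 4 bonds apart, distance factor 4. The histogram is anchored at modified
#' distance 0; values outside the range clip to the end bins.
#'
#' @param n_bins number of histogram intervals.
#' @param resolution bin width in modified-distance units.
#' @param max_bonds maximum topological (bond-count) distance.
#' @param distance_factor multiplier applied to the bond-count distance.
#' @return an mdConfig list.
#' @export
mdConfig <- function(n_bins = 1010L, resolution = 0.017, max_bonds = 4L,
                     distance_factor = 4) {
  stopifnot(n_bins > 0L, resolution > 0, max_bonds >= 1L)
  structure(list(n_bins = as.integer(n_bins), resolution = resolution,
                 max_bonds = as.integer(max_bonds),
                 distance_factor = distance_factor,
                 element_table = .ELEMENT_TABLE_VERSION),
            class = "mdConfig")
}

# Effective radius of every atom in an explicit-H graph: vdW radius scaled
# by the mean Sanderson electronegativity of the atom's neighbours
# (including hydrogens) relative to carbon. Atoms without neighbours fall
# back to their own electronegativity.
.effectiveRadii <- function(g) {
  en <- .SANDERSON_EN[g$elements]
  en[is.na(en)] <- .SANDERSON_EN["C"]
  rv <- .VDW_RADII[g$elements]
  rv[is.na(rv)] <- .VDW_RADII["C"]
  vapply(seq_len(g$n), function(i) {
    nb <- g$adj[[i]]
    mean_en <- if (length(nb)) mean(en[nb]) else en[i]
    unname(rv[i] * mean_en / .SANDERSON_EN[["C"]])
  }, numeric(1))
}

# Breadth-first shortest path lengths (bond counts) from one heavy atom to
# all heavy atoms, limited to max_bonds, walking the heavy-atom subgraph.
.bfsDistances <- function(adj_heavy, start, max_bonds) {
  n <- length(adj_heavy)
  dist <- rep(NA_integer_, n)
  dist[start] <- 0L
  frontier <- start
  d <- 0L
  while (length(frontier) && d < max_bonds) {
    d <- d + 1L
    nxt <- unique(unlist(adj_heavy[frontier]))
    nxt <- nxt[is.na(dist[nxt])]
    dist[nxt] <- d
    frontier <- nxt
  }
  dist
}

#' Modified distance between two atoms
#'
#' \code{path_len * distance_factor - rho_i - rho_j}, where rho is the
#' atom's van der Waals radius scaled by the mean Sanderson
#' electronegativity of its neighbours relative to carbon. Symmetric in the
#' two atoms and strictly increasing in the path length for fixed end-atom
#' environments.
#'
#' @param rho_i,rho_j effective radii of the two end atoms.
#' @param path_len topological distance in bonds (>= 1).
#' @param cfg an \code{\link{mdConfig}}.
#' @return the modified distance (dimensionless).
#' @export
modifiedDistance <- function(rho_i, rho_j, path_len, cfg = mdConfig()) {
  stopifnot(path_len >= 1L, path_len <= cfg$max_bonds)
  path_len * cfg$distance_factor - rho_i - rho_j
}

#' Md descriptor vector of one molecule
#'
#' Histogram over all unordered heavy-atom pairs whose topological distance
#' is at most \code{max_bonds}: bin index \code{floor(d / resolution)},
#' clipped to [0, n_bins - 1]. Invariant under atom renumbering; a
#' single-heavy-atom molecule yields the all-zero vector.
#'
#' @param x a SMILES string, or a graph from \code{smilesToGraph()}.
#' @param cfg an \code{\link{mdConfig}}.
#' @return integer vector of length \code{n_bins}.
#' @export
mdVector <- function(x, cfg = mdConfig()) {
  g <- if (is.character(x)) smilesToGraph(x, addH = TRUE) else x
  if (is.null(g)) stop("unparseable structure for mdVector()")
  counts <- integer(cfg$n_bins)
  heavy <- which(g$elements != "H")
  if (length(heavy) < 2L) return(counts)
  # heavy-atom subgraph, reindexed 1..n_heavy
  hidx <- match(seq_len(g$n), heavy)
  adj_heavy <- lapply(heavy, function(i) {
    nb <- g$adj[[i]]
    hidx[nb[!is.na(hidx[nb])]]
  })
  rho <- .effectiveRadii(g)[heavy]
  nh <- length(heavy)
  for (i in seq_len(nh - 1L)) {
    dist <- .bfsDistances(adj_heavy, i, cfg$max_bonds)
    for (j in seq((i + 1L), nh)) {
      pl <- dist[j]
      if (is.na(pl) || pl < 1L) next
      d <- pl * cfg$distance_factor - rho[i] - rho[j]
      bin <- floor(d / cfg$resolution)
      bin <- max(0L, min(cfg$n_bins - 1L, bin))
      counts[bin + 1L] <- counts[bin + 1L] + 1L
    }
  }
  counts
}

#' Md descriptor matrix for a molecule set
#'
#' @param mols a \linkS4class{MoleculeSet} or character vector of SMILES
#'   (named by mol_id).
#' @param cfg an \code{\link{mdConfig}}.
#' @return a \linkS4class{FeatureMatrix} with columns Md0001..Md1010 and
#'   provenance "Md"; unparseable molecules are dropped and recorded.
#' @export
mdMatrix <- function(mols, cfg = mdConfig()) {
  if (is(mols, "MoleculeSet")) {
    smiles <- molData(mols)$canonical_smiles
    ids <- molIds(mols)
  } else {
    smiles <- unname(mols)
    ids <- names(mols)
    if (is.null(ids)) ids <- sprintf("mol%05d", seq_along(smiles))
  }
  rows <- vector("list", length(smiles))
  ok <- logical(length(smiles))
  for (i in seq_along(smiles)) {
    v <- tryCatch(mdVector(smiles[i], cfg), error = function(e) NULL)
    if (!is.null(v)) { rows[[i]] <- v; ok[i] <- TRUE }
  }
  vals <- do.call(rbind, rows[ok])
  if (is.null(vals)) vals <- matrix(numeric(0), 0, cfg$n_bins)
  rownames(vals) <- ids[ok]
  colnames(vals) <- sprintf("Md%04d", seq_len(cfg$n_bins))
  new("FeatureMatrix", values = vals, provenance = "Md",
      dropped = ids[!ok])
}

#' Renumber the atoms of a molecular graph
#'
#' Applies a permutation to the atom indices (perm[i] is the new index of
#' atom i); descriptor values must be invariant under this operation.
#'
#' @param g graph from \code{\link{smilesToGraph}}.
#' @param perm integer permutation of 1..n.
#' @return the renumbered graph.
#' @export
renumberGraph <- function(g, perm) {
  inv <- integer(g$n)
  inv[perm] <- seq_len(g$n)
  bonds <- g$bonds
  if (nrow(bonds) > 0L) {
    bonds[, 1] <- perm[bonds[, 1]]
    bonds[, 2] <- perm[bonds[, 2]]
  }
  adj <- vector("list", g$n)
  for (i in seq_len(g$n)) adj[[perm[i]]] <- perm[g$adj[[i]]]
  list(elements = g$elements[inv], charges = g$charges[inv],
       radical = g$radical, bonds = bonds, adj = adj, n = g$n)
}
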