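# Shared fixture builders. Everything is generated in code; no data files.

splitFlagsT <- function(x) {
  if (is.na(x) || !nzchar(x)) character(0)
  else strsplit(x, ";", fixed = TRUE)[[1]]
}

# Small chemically diverse SMILES set for structure-level tests.
fixtureSmiles <- function() {
  c(anisole = "COc1ccccc1",
    octanol = "CCCCCCCCO",
    naphthalene = "c1ccc2ccccc2c1",
    pyridine = "c1ccncc1",
    stilbene = "c1ccccc1/C=C/c1ccccc1",
    dmab = "CN(C)c1ccc(C=O)cc1",
    chlorobenzene = "Clc1ccccc1CCCC",
    thiophene = "c1ccsc1CCCCCC",
    isopentane = "CCC(C)C",
    benzamide = "NC(=O)c1ccccc1")
}

# Linearly separable binary feature fixture: the first n_inf columns carry
# the class signal, the rest are noise bits.
separableFixture <- function(n = 200, p = 40, n_inf = 5, seed = 1) {
  set.seed(seed)
  y <- rep(c("POS", "NEG"), length.out = n)
  X <- matrix(rbinom(n * p, 1, 0.3), n, p)
  X[, seq_len(n_inf)] <- matrix(rep(as.numeric(y == "POS"), n_inf), n)
  colnames(X) <- sprintf("bit%03d", seq_len(p))
  rownames(X) <- sprintf("m%04d", seq_len(n))
  list(X = X, y = y, informative = colnames(X)[seq_len(n_inf)])
}

# Random peak tables for labelling property tests.
randomPeakTable <- function(n_records, seed) {
  set.seed(seed)
  n_peaks <- sample(1:4, n_records, replace = TRUE)
  data.frame(
    mol_id = rep(sprintf("r%05d", seq_len(n_records)), n_peaks),
    wavelength_nm = runif(sum(n_peaks), 150, 800),
    mec = ifelse(runif(sum(n_peaks)) < 0.1, NA_real_,
                 10^runif(sum(n_peaks), 0, 5.5)),
    stringsAsFactors = FALSE)
}

# Independent shortest-path pair counter on the heavy-atom graph (igraph),
# used as the oracle for the Md histogram mass.
igraphPairCount <- function(smiles, max_bonds = 4) {
  g <- smilesToGraph(smiles, addH = TRUE)
  heavy <- which(g$elements != "H")
  hidx <- match(seq_len(g$n), heavy)
  eb <- g$bonds[g$elements[g$bonds[, 1]] != "H" &
                g$elements[g$bonds[, 2]] != "H", , drop = FALSE]
  ig <- igraph::make_empty_graph(n = length(heavy), directed = FALSE)
  if (nrow(eb) > 0L)
    ig <- igraph::add_edges(ig, rbind(hidx[eb[, 1]], hidx[eb[, 2]]))
  d <- igraph::distances(ig)
  sum(d[upper.tri(d)] >= 1 & d[upper.tri(d)] <= max_bonds)
}
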