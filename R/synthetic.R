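# Seeded synthetic study generator. Emits valid, curation-eligible
# molecules from two scaffold families (saturated vs conjugated), UV-Vis
# peak lists driven by a transparent monotone structure->spectrum rule
# (primary-maximum wavelength linear in the latent conjugation size), and
# phototoxicity outcomes with the POS-class alarm asymmetry. Corruption
# processes (log-unit MEC, boundary-proximal peaks, missing MEC) are
# injected at configured rates with ground truth retained, so triage
# heuristics can be scored against known corruption labels.

#' Synthetic-study configuration
#'
#' The defaults define the emulated study conditions: an approximately
#' class-balanced population (target POS fraction 0.5), a primary
#' absorption maximum at \code{lambda_intercept + lambda_slope *
#' conjugation} nm with Gaussian noise, log-normal MEC with a
#' family-dependent location (log10 means for conjugated vs saturated
#' scaffolds), 0-3 secondary peaks, and small corruption rates.
#'
#' @param n_molecules number of molecules (>= 2).
#' @param pos_fraction target POS fraction (diagnostic only; realized by
#'   the family mix).
#' @param lambda_intercept,lambda_slope,lambda_sd structure->wavelength
#'   rule (nm).
#' @param mec_log_mean_conj,mec_log_mean_sat,mec_log_sd log10-MEC
#'   distribution per scaffold family.
#' @param p_log_corrupt probability a molecule's MECs are recorded in log
#'   units.
#' @param p_boundary probability the primary peak sits just around the
#'   290 nm window edge.
#' @param p_missing_mec probability one peak loses its MEC.
#' @param p_tox_pos,p_tox_neg P(toxic | POS), P(toxic | NEG).
#' @param seed master seed.
#' @return a simConfig list.
#' @export
simConfig <- function(n_molecules = 1000L, pos_fraction = 0.5,
                      lambda_intercept = 175, lambda_slope = 17,
                      lambda_sd = 12, mec_log_mean_conj = 4.2,
                      mec_log_mean_sat = 2.6, mec_log_sd = 0.5,
                      p_log_corrupt = 0.02, p_boundary = 0.05,
                      p_missing_mec = 0.05, p_tox_pos = 0.55,
                      p_tox_neg = 0.25, seed = 42L) {
  stopifnot(n_molecules >= 2L,
            all(c(p_log_corrupt, p_boundary, p_missing_mec, p_tox_pos,
                  p_tox_neg) >= 0),
            all(c(p_log_corrupt, p_boundary, p_missing_mec, p_tox_pos,
                  p_tox_neg) <= 1))
  structure(list(n_molecules = as.integer(n_molecules),
                 pos_fraction = pos_fraction,
                 lambda_intercept = lambda_intercept,
                 lambda_slope = lambda_slope, lambda_sd = lambda_sd,
                 mec_log_mean_conj = mec_log_mean_conj,
                 mec_log_mean_sat = mec_log_mean_sat,
                 mec_log_sd = mec_log_sd,
                 p_log_corrupt = p_log_corrupt, p_boundary = p_boundary,
                 p_missing_mec = p_missing_mec, p_tox_pos = p_tox_pos,
                 p_tox_neg = p_tox_neg, seed = as.integer(seed)),
            class = "simConfig")
}

# Aromatic-ring substituents: neutral donors/acceptors only, so every
# emitted structure stays curation-eligible.
.AROM_SUBS <- c("", "OC", "O", "N(C)C", "C#N", "C(=O)C", "Cl", "Br")

.alkyl <- function(n) paste(rep("C", n), collapse = "")

# One scaffold draw per family; returns list(smiles, conjugation).
# Conjugation = atoms in the largest pi system of the core.
.drawScaffold <- function(family) {
  tail <- .alkyl(sample(2:8, 1))
  sub <- sample(.AROM_SUBS, 1)
  ring_sub <- if (nzchar(sub)) sub else "C"
  switch(family,
    sat = {
      len <- sample(8:16, 1)
      kind <- sample(1:5, 1)
      smi <- switch(kind,
        .alkyl(len),
        paste0("OC", .alkyl(len - 1)),                     # 1-alkanol
        paste0("NC", .alkyl(len - 1)),                     # 1-alkylamine
        paste0(.alkyl(4), "O", .alkyl(len - 4)),           # dialkyl ether
        paste0("C1CCCCC1", .alkyl(max(2, len - 6))))       # cyclohexyl
      conj <- 0L
      if (stats::runif(1) < 0.3 && kind == 1L) {           # isolated alkene
        smi <- paste0("CC=C", .alkyl(len - 3))
        conj <- 2L
      }
      list(smiles = smi, conjugation = conj)
    },
    pi6 = list(smiles = paste0(tail, "c1ccc(", ring_sub, ")cc1"),
               conjugation = 6L),
    pi8 = list(smiles = paste0("C=Cc1ccc(", tail, ")cc1"),
               conjugation = 8L),
    pi10 = list(smiles = sample(c(
                  paste0(tail, "c1ccc2ccccc2c1"),
                  paste0("C=CC=Cc1ccc(", tail, ")cc1")), 1),
                conjugation = 10L),
    pi12 = list(smiles = sample(c(
                  paste0(tail, "c1ccc(-c2ccccc2)cc1"),
                  paste0("C=CC=CC=Cc1ccc(", tail, ")cc1")), 1),
                conjugation = 12L),
    pi14 = list(smiles = sample(c(
                  paste0(tail, "c1ccc(C=Cc2ccccc2)cc1"),
                  paste0(tail, "c1ccc2cc3ccccc3cc2c1")), 1),
                conjugation = 14L))
}

.FAMILY_WEIGHTS <- c(sat = 0.36, pi6 = 0.12, pi8 = 0.13, pi10 = 0.13,
                     pi12 = 0.13, pi14 = 0.13)

#' Generate synthetic molecules with latent conjugation sizes
#'
#' Draws scaffolds from a finite template library (branched
#' alkanes/alcohols/amines/ethers and cyclohexanes at latent conjugation
#' 0-2; substituted benzenes, styrenes, polyene-benzenes, naphthalenes,
#' biphenyls and stilbene/anthracene cores at 6-14), each padded with an
#' alkyl tail so every structure parses, standardizes and passes the
#' eligibility filter.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @return data.frame: mol_id, smiles, family, conjugation.
#' @export
simulateMolecules <- function(cfg = simConfig()) {
  set.seed(cfg$seed)
  fams <- sample(names(.FAMILY_WEIGHTS), cfg$n_molecules, replace = TRUE,
                 prob = .FAMILY_WEIGHTS)
  recs <- lapply(fams, .drawScaffold)
  data.frame(mol_id = sprintf("syn%05d", seq_len(cfg$n_molecules)),
             smiles = vapply(recs, `[[`, character(1), "smiles"),
             family = fams,
             conjugation = vapply(recs, `[[`, integer(1), "conjugation"),
             stringsAsFactors = FALSE)
}

#' Generate synthetic UV-Vis peak lists
#'
#' Primary maximum at \code{lambda_intercept + lambda_slope * conjugation
#' + N(0, lambda_sd)} nm; MEC log-normal with the family-dependent
#' location; 0-3 secondary maxima at shorter wavelengths with scaled-down
#' MECs. Corruptions are then injected molecule-wise at the configured
#' rates — all MECs replaced by their log10 (the log-unit recording
#' error), the primary wavelength displaced to the 281-317 nm boundary
#' region, or one MEC dropped — and recorded in the returned truth table.
#'
#' @param mols data.frame from \code{\link{simulateMolecules}}.
#' @param cfg a \code{\link{simConfig}}.
#' @return list with \code{spectra} (a \linkS4class{SpectrumSet}) and
#'   \code{truth} (data.frame: mol_id, family, conjugation,
#'   log_corrupted, boundary_shift, missing_mec).
#' @export
simulateSpectra <- function(mols, cfg = simConfig()) {
  set.seed(subSeed(cfg$seed, 2L))
  n <- nrow(mols)
  lam <- cfg$lambda_intercept + cfg$lambda_slope * mols$conjugation +
    stats::rnorm(n, 0, cfg$lambda_sd)
  lam <- pmax(120, lam)
  logm <- ifelse(mols$family == "sat", cfg$mec_log_mean_sat,
                 cfg$mec_log_mean_conj)
  mec <- 10^stats::rnorm(n, logm, cfg$mec_log_sd)
  log_draw <- stats::runif(n) < cfg$p_log_corrupt
  boundary <- stats::runif(n) < cfg$p_boundary
  missing <- stats::runif(n) < cfg$p_missing_mec
  lam[boundary] <- stats::runif(sum(boundary), 281, 317)
  log_corr <- logical(n)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    k <- sample(0:3, 1)
    wl <- c(lam[i],
            if (k > 0) pmax(120, lam[i] - stats::runif(k, 30, 120)))
    me <- c(mec[i], if (k > 0) mec[i] * stats::runif(k, 0.2, 0.8))
    # The log-unit transcription error is only plausible (and only
    # detectable) for MECs in the 1e3-1e5 range, where log10 lands in the
    # suspect [3, 5] band; corruption is restricted accordingly.
    if (log_draw[i] && all(me >= 1e3 & me <= 1e5)) {
      me <- log10(me)
      log_corr[i] <- TRUE
    }
    if (missing[i]) me[sample(length(me), 1)] <- NA_real_
    rows[[i]] <- data.frame(mol_id = mols$mol_id[i],
                            wavelength_nm = wl, mec = me,
                            solvent = "methanol",
                            source_id = sprintf("sim:%s", mols$mol_id[i]),
                            stringsAsFactors = FALSE)
  }
  truth <- data.frame(mol_id = mols$mol_id, family = mols$family,
                      conjugation = mols$conjugation,
                      log_corrupted = log_corr,
                      boundary_shift = boundary, missing_mec = missing,
                      stringsAsFactors = FALSE)
  list(spectra = spectrumSet(do.call(rbind, rows),
                             mol_ids = mols$mol_id),
       truth = truth)
}

#' Generate synthetic phototoxicity outcomes
#'
#' Bernoulli outcomes conditioned on the spectrum class,
#' P(toxic | POS) >> P(toxic | NEG), reproducing the alarm asymmetry
#' (high sensitivity, low specificity of POS for toxicity).
#'
#' @param labels data.frame with columns mol_id, label.
#' @param cfg a \code{\link{simConfig}}.
#' @return data.frame: mol_id, outcome ("toxic"/"non_toxic").
#' @export
simulatePhototox <- function(labels, cfg = simConfig()) {
  set.seed(subSeed(cfg$seed, 3L))
  p <- ifelse(labels$label == "POS", cfg$p_tox_pos, cfg$p_tox_neg)
  data.frame(mol_id = labels$mol_id,
             outcome = ifelse(stats::runif(nrow(labels)) < p,
                              "toxic", "non_toxic"),
             stringsAsFactors = FALSE)
}

#' Generate a full synthetic study
#'
#' Molecules, peak lists, POS/NEG labels and phototoxicity outcomes in one
#' call; optionally writes curated.smi, peaks.csv, tox.csv and truth.json
#' to a directory.
#'
#' @param cfg a \code{\link{simConfig}}.
#' @param dir optional output directory.
#' @return list: molecules, spectra, labels, truth, outcomes.
#' @export
simulateStudy <- function(cfg = simConfig(), dir = NULL) {
  mols <- simulateMolecules(cfg)
  sp <- simulateSpectra(mols, cfg)
  labels <- labelSpectra(sp$spectra)
  outcomes <- simulatePhototox(labels, cfg)
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(paste(mols$smiles, mols$mol_id, sep = "\t"),
               file.path(dir, "curated.smi"))
    utils::write.csv(peakTable(sp$spectra), file.path(dir, "peaks.csv"),
                     row.names = FALSE)
    utils::write.csv(outcomes, file.path(dir, "tox.csv"),
                     row.names = FALSE)
    jsonlite::write_json(sp$truth, file.path(dir, "truth.json"),
                         dataframe = "rows")
  }
  list(molecules = mols, spectra = sp$spectra, labels = labels,
       truth = sp$truth, outcomes = outcomes)
}
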