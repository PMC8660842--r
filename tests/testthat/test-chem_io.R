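# Structure parsing, standardization, eligibility filtering, dedup.

writeSmiFile <- function(entries) {
  tf <- tempfile(fileext = ".smi")
  writeLines(entries, tf)
  tf
}

test_that("parsing keeps valid entries, skips malformed ones, computes MW", {
  tf <- writeSmiFile(c("c1ccccc1\tbenzene", "[Na+].[Cl-]\tsalt",
                       "C1CC\tbroken", "COc1ccccc1\tanisole"))
  expect_message(ms <- parseStructures(tf), "skipped")
  d <- molData(ms)
  expect_equal(ms@nSkipped, 1L)
  expect_setequal(d$mol_id, c("benzene", "salt", "anisole"))
  expect_equal(d$mol_weight[d$mol_id == "benzene"], 78.1, tolerance = 0.01)
  expect_equal(d$n_fragments[d$mol_id == "salt"], 2L)
  expect_equal(d$n_fragments[d$mol_id == "benzene"], 1L)
})

test_that("unreadable or entry-free input is a fatal error", {
  expect_error(parseStructures(tempfile()), "does not exist")
  tf <- writeSmiFile(c("C1CC", "xx$%"))
  expect_error(suppressMessages(parseStructures(tf)), "zero parseable")
})

test_that("standardization unifies tautomers, kekule forms and nitro conventions", {
  tf <- writeSmiFile(c("c1cnc[nH]1\tt1", "C1=CN=CN1\tt2",
                       "C1=CC=CC=C1\tkek", "c1ccccc1\tarom",
                       "O=[N+]([O-])c1ccccc1CCC\tn1",
                       "O=N(=O)c1ccccc1CCC\tn2"))
  ms <- standardizeMolecules(parseStructures(tf))
  cs <- setNames(molData(ms)$canonical_smiles, molData(ms)$mol_id)
  expect_identical(cs[["t1"]], cs[["t2"]])
  expect_identical(cs[["kek"]], cs[["arom"]])
  expect_identical(cs[["n1"]], cs[["n2"]])
})

test_that("standardization is idempotent on a diverse fixture", {
  tf <- writeSmiFile(paste(fixtureSmiles(), names(fixtureSmiles()),
                           sep = "\t"))
  once <- standardizeMolecules(parseStructures(tf))
  twice <- standardizeMolecules(once)
  expect_identical(molData(once)$canonical_smiles,
                   molData(twice)$canonical_smiles)
  expect_identical(molData(once)$inchi_key_nostereo,
                   molData(twice)$inchi_key_nostereo)
})

test_that("eligibility filter partitions with one primary reason each", {
  tf <- writeSmiFile(c("c1ccccc1\tlight", "[Na+].[Cl-]\tsalt",
                       "CC[O-]\tanion", "COc1ccccc1\tanisole",
                       "C1CCC(CC1)[Fe]C1CCCCC1\tferro"))
  ms <- standardizeMolecules(parseStructures(tf))
  fl <- filterEligible(ms)
  expect_equal(nrow(molData(fl$kept)) + nrow(fl$rejected), nrow(molData(ms)))
  rej <- setNames(fl$rejected$reason, fl$rejected$mol_id)
  expect_identical(rej[["light"]], "mw_low")     # MW 78 < 98
  expect_identical(rej[["anion"]], "charged")
  expect_identical(rej[["ferro"]], "metal")
  expect_true("anisole" %in% molIds(fl$kept))    # MW 108, neutral, 1 frag
  expect_true(all(table(fl$rejected$mol_id) == 1))  # exactly one reason
})

test_that("MW bounds are configurable and respected", {
  tf <- writeSmiFile(c("c1ccccc1\tbenzene", "COc1ccccc1\tanisole"))
  ms <- standardizeMolecules(parseStructures(tf))
  fl <- filterEligible(ms, eligibilityRule(mw_min = 50, mw_max = 100))
  expect_true("benzene" %in% molIds(fl$kept))
  expect_identical(fl$rejected$reason[fl$rejected$mol_id == "anisole"],
                   "mw_high")
})

test_that("dedup collapses stereoisomers and unions their spectra", {
  tf <- writeSmiFile(c("CC(O)CCCCCCCC\tplain", "C[C@H](O)CCCCCCCC\tR",
                       "C[C@@H](O)CCCCCCCC\tS", "c1ccc2ccccc2c1\tnap"))
  ms <- standardizeMolecules(parseStructures(tf))
  peaks <- data.frame(mol_id = c("plain", "R", "S", "nap"),
                      wavelength_nm = c(210, 220, 230, 310),
                      mec = c(100, 200, 300, 5000))
  sp <- spectrumSet(peaks)
  dd <- deduplicateMolecules(ms, sp)
  expect_equal(nrow(molData(dd$molecules)), 2L)
  expect_true("plain" %in% molIds(dd$molecules))  # first occurrence wins
  pk <- peakTable(dd$spectra)
  merged <- pk[pk$mol_id == "plain", ]
  expect_setequal(merged$wavelength_nm, c(210, 220, 230))  # union of peaks
})

test_that("dedup output is invariant under input permutation", {
  tf <- writeSmiFile(paste(fixtureSmiles(), names(fixtureSmiles()),
                           sep = "\t"))
  ms <- standardizeMolecules(parseStructures(tf))
  keys1 <- sort(molData(deduplicateMolecules(ms))$inchi_key_nostereo)
  perm <- ms
  set.seed(3)
  perm@molData <- perm@molData[sample(nrow(perm@molData)), ]
  keys2 <- sort(molData(deduplicateMolecules(perm))$inchi_key_nostereo)
  expect_identical(keys1, keys2)
})

test_that("SDF input parses to the same structures as SMILES input", {
  smi <- c("COc1ccccc1", "c1ccc2ccccc2c1")
  sdftext <- paste0(vapply(smi, function(s)
    suppressWarnings(ChemmineOB::convertFormat(
      "SMI", "SDF", paste0(s, "\n"))), character(1)), collapse = "")
  tf <- tempfile(fileext = ".sdf")
  writeLines(sdftext, tf)
  ms <- parseStructures(tf, format = "sdf")
  tf2 <- writeSmiFile(smi)
  ms2 <- parseStructures(tf2)
  expect_setequal(molData(ms)$inchi_key_nostereo,
                  molData(ms2)$inchi_key_nostereo)
})

test_that("curation audit covers every molecule exactly once", {
  tf <- writeSmiFile(c("c1ccccc1\tb", "COc1ccccc1\ta"))
  ms <- standardizeMolecules(parseStructures(tf))
  fl <- filterEligible(ms)
  out <- tempfile(fileext = ".csv")
  aud <- writeCurationAudit(fl$kept, fl$rejected, out)
  expect_true(file.exists(out))
  expect_setequal(aud$mol_id, c("a", "b"))
  expect_identical(aud$status[aud$mol_id == "b"], "rejected")
})
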