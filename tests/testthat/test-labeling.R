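# POS/NEG labelling, sub-bands, NEG region flags, quality flags, splits.

pk <- function(wl, mec) data.frame(wavelength_nm = wl, mec = mec)

test_that("the class rule is inclusive on all three edges", {
  expect_identical(labelSpectrum(pk(290, 1000))$label, "POS")
  expect_identical(labelSpectrum(pk(700, 1000))$label, "POS")
  expect_identical(labelSpectrum(pk(289.999, 1e6))$label, "NEG")
  expect_identical(labelSpectrum(pk(700.001, 1e6))$label, "NEG")
  expect_identical(labelSpectrum(pk(400, 999.999))$label, "NEG")
  expect_identical(labelSpectrum(pk(400, 1000))$label, "POS")
})

test_that("the rule applies peak-by-peak, not to peak-list aggregates", {
  # neither peak satisfies both conditions although each satisfies one
  expect_identical(labelSpectrum(pk(c(350, 260), c(500, 50000)))$label,
                   "NEG")
  expect_identical(labelSpectrum(pk(c(350, 260), c(1200, 50)))$label,
                   "POS")
})

test_that("empty lists and missing MECs never qualify", {
  r <- labelSpectrum(pk(numeric(0), numeric(0)))
  expect_identical(r$label, "NEG")
  expect_true("empty_list" %in% splitFlagsT(r$quality_flags))
  r2 <- labelSpectrum(pk(400, NA_real_))
  expect_identical(r2$label, "NEG")
  expect_true("missing_mec" %in% splitFlagsT(r2$quality_flags))
})

test_that("POS sub-bands are half-open with 5000 in the middle band", {
  expect_identical(posSubcategory(pk(400, 12000)), "mec_ge_10k")
  expect_identical(posSubcategory(pk(400, 10000)), "mec_ge_10k")
  expect_identical(posSubcategory(pk(400, 5000)), "mec_5k_10k")
  expect_identical(posSubcategory(pk(400, 4999.9)), "mec_1k_5k")
  expect_identical(posSubcategory(pk(400, 1000)), "mec_1k_5k")
  # band comes from the in-window peak with the highest MEC
  expect_identical(posSubcategory(pk(c(300, 400, 250), c(1100, 9000, 5e4))),
                   "mec_5k_10k")
  expect_error(posSubcategory(pk(260, 5e4)), "POS")
})

test_that("NEG flags assign one region per peak and collect as a set", {
  expect_setequal(negPeakFlags(pk(260, 800)), "below290_lowMEC")
  expect_setequal(negPeakFlags(pk(c(260, 320), c(800, 850))),
                  c("below290_lowMEC", "inwindow_le900"))
  expect_setequal(negPeakFlags(pk(710, 2000)), "above700_highMEC")
  expect_setequal(negPeakFlags(pk(c(260, 265), c(50000, 30000))),
                  "below290_highMEC")
  expect_setequal(negPeakFlags(pk(320, 950)), "inwindow_gt900")
})

test_that("quality flags follow the documented windows and never relabel", {
  r <- labelSpectrum(pk(c(310, 265), c(4.2, 3.8)))
  expect_identical(r$label, "NEG")
  expect_setequal(splitFlagsT(r$quality_flags),
                  c("suspect_log_mec", "near_lower_endpoint"))
  expect_identical(labelSpectrum(pk(500, 30000))$quality_flags, "")
  expect_setequal(splitFlagsT(labelSpectrum(pk(295, 891))$quality_flags),
                  c("near_lower_endpoint", "near_mec_threshold"))
  # a POS record can still carry advisory flags
  r2 <- labelSpectrum(pk(300, 1400))
  expect_identical(r2$label, "POS")
  expect_setequal(splitFlagsT(r2$quality_flags),
                  c("near_lower_endpoint", "near_mec_threshold"))
})

test_that("POS bands partition POS and flagged NEG records get >= 1 flag", {
  tab <- randomPeakTable(400, seed = 9)
  labs <- labelSpectra(spectrumSet(tab))
  pos <- labs[labs$label == "POS", ]
  expect_true(all(pos$pos_band %in%
                  c("mec_1k_5k", "mec_5k_10k", "mec_ge_10k")))
  expect_true(all(labs$pos_band[labs$label == "NEG"] == "none"))
  neg <- labs[labs$label == "NEG", ]
  has_measured_peak <- vapply(neg$mol_id, function(id)
    any(!is.na(tab$mec[tab$mol_id == id])), logical(1))
  expect_true(all(nzchar(neg$neg_flags[has_measured_peak])))
})

test_that("adding a peak can only move NEG toward POS", {
  tab <- randomPeakTable(500, seed = 21)
  before <- labelSpectra(spectrumSet(tab))
  set.seed(22)
  extra <- data.frame(mol_id = unique(tab$mol_id),
                      wavelength_nm = runif(500, 150, 800),
                      mec = 10^runif(500, 0, 5.5))
  after <- labelSpectra(spectrumSet(rbind(tab, extra)))
  flipped_down <- before$label == "POS" & after$label == "NEG"
  expect_false(any(flipped_down))
})

test_that("dataset splitting is disjoint, seeded and size-checked", {
  labs <- data.frame(mol_id = sprintf("m%03d", 1:100),
                     label = rep(c("POS", "NEG"), 50))
  sp <- splitDataset(labs, c(80, 10, 10), seed = 7)
  expect_length(unique(c(sp$train, sp$test1, sp$test2)), 100)
  expect_length(sp$test1, 10)
  sp2 <- splitDataset(labs, c(80, 10, 10), seed = 7)
  expect_identical(sp, sp2)
  expect_error(splitDataset(labs, c(80, 10, 20), seed = 7), "exceed")
  sp3 <- splitDataset(labs, c(98, 1, 1), seed = 1)
  expect_length(sp3$test2, 1)
  cc <- attr(sp, "class_counts")
  expect_equal(sum(cc$train) + sum(cc$test1) + sum(cc$test2), 100)
})

test_that("peak-table CSV round-trips through readPeakTable", {
  tab <- randomPeakTable(20, seed = 5)
  tf <- tempfile(fileext = ".csv")
  write.csv(tab, tf, row.names = FALSE)
  sp <- readPeakTable(tf)
  expect_equal(nrow(peakTable(sp)), nrow(tab))
  expect_error(readPeakTable({
    tf2 <- tempfile(fileext = ".csv")
    write.csv(data.frame(a = 1), tf2, row.names = FALSE)
    tf2
  }), "columns")
})
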