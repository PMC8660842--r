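#' Labeling configuration
#'
#' The photoreactive-potential window and molar-extinction threshold from
#' the ICH S10-based class definition: a molecule is POS when at least one
#' listed absorption maximum lies in [290, 700] nm with MEC >= 1000
#' L/mol/cm (all three bounds inclusive).
#'
#' @param window_low,window_high wavelength window in nm.
#' @param mec_threshold MEC threshold in L/mol/cm.
#' @return a labelConfig list.
#' @export
labelConfig <- function(window_low = 290, window_high = 700,
                        mec_threshold = 1000) {
  stopifnot(window_low < window_high, mec_threshold > 0)
  structure(list(window_low = window_low, window_high = window_high,
                 mec_threshold = mec_threshold), class = "labelConfig")
}

#' Construct a SpectrumSet
#'
#' @param peaks data.frame with columns mol_id, wavelength_nm, mec and
#'   optionally solvent, source_id; one row per listed absorption maximum;
#'   mec may be NA.
#' @param mol_ids optional full molecule universe (ids with empty peak
#'   lists included); defaults to the ids present in \code{peaks}.
#' @return a \linkS4class{SpectrumSet}.
#' @export
spectrumSet <- function(peaks, mol_ids = NULL) {
  if (nrow(peaks) > 0L) {
    if (!"solvent" %in% names(peaks)) peaks$solvent <- NA_character_
    if (!"source_id" %in% names(peaks)) peaks$source_id <- NA_character_
    peaks$mol_id <- as.character(peaks$mol_id)
    peaks$wavelength_nm <- as.numeric(peaks$wavelength_nm)
    peaks$mec <- as.numeric(peaks$mec)
  }
  if (is.null(mol_ids)) mol_ids <- unique(as.character(peaks$mol_id))
  new("SpectrumSet", peaks = peaks, molIds = as.character(mol_ids))
}

#' Read a peak-list CSV into a SpectrumSet
#'
#' Expects columns mol_id, wavelength_nm, mec (blank = missing), and
#' optionally solvent and source_id.
#'
#' @param path CSV path.
#' @param mol_ids optional molecule universe.
#' @return a \linkS4class{SpectrumSet}.
#' @export
readPeakTable <- function(path, mol_ids = NULL) {
  pk <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("mol_id", "wavelength_nm", "mec")
  if (!all(need %in% names(pk)))
    stop("peak CSV must have columns ", paste(need, collapse = ", "))
  spectrumSet(pk, mol_ids = mol_ids)
}

# Vectorized per-peak region assignment used by both the labeler and the
# NEG-flag computation.
.peakRegions <- function(pk, cfg) {
  inw <- pk$wavelength_nm >= cfg$window_low &
         pk$wavelength_nm <= cfg$window_high
  hi <- !is.na(pk$mec) & pk$mec >= cfg$mec_threshold
  list(in_window = inw, high_mec = hi,
       qualifying = inw & hi)
}

#' Label spectra with the POS/NEG photoreactive-potential class
#'
#' Applies the class rule peak-by-peak: POS iff some listed maximum has
#' wavelength in [window_low, window_high] (inclusive) and a present MEC >=
#' mec_threshold; NEG otherwise (including empty peak lists). Also returns
#' the POS sub-band of the highest-MEC in-window peak, per-peak NEG region
#' flags, and advisory data-quality flags (see Details).
#'
#' Sub-bands are half-open: [1000, 5000), [5000, 10000), [10000, Inf), so a
#' maximum of exactly 5000 falls in the middle band. NEG region flags
#' classify every listed peak with a present MEC by wavelength region
#' (below/inside/above the window) and MEC level (the in-window NEG split
#' is at 900 L/mol/cm). Quality flags mark peak lists whose present MECs
#' all lie in [3, 5] (suggesting log-unit values), peaks near the lower
#' window endpoint ([281, 317] nm), in-window MECs near the threshold
#' ([661, 1500]), missing MECs, and empty lists. Quality flags never affect
#' the label.
#'
#' @param spectra a \linkS4class{SpectrumSet}.
#' @param cfg a \code{\link{labelConfig}}.
#' @return data.frame with columns mol_id, label ("POS"/"NEG"), pos_band
#'   ("mec_1k_5k", "mec_5k_10k", "mec_ge_10k" or "none"), neg_flags and
#'   quality_flags (semicolon-joined strings, possibly empty).
#' @export
labelSpectra <- function(spectra, cfg = labelConfig()) {
  stopifnot(is(spectra, "SpectrumSet"), inherits(cfg, "labelConfig"))
  ids <- molIds(spectra)
  pk <- peakTable(spectra)
  out <- data.frame(mol_id = ids, label = "NEG", pos_band = "none",
                    neg_flags = "", quality_flags = "",
                    stringsAsFactors = FALSE)
  has_peaks <- ids %in% pk$mol_id
  out$quality_flags[!has_peaks] <- "empty_list"
  if (nrow(pk) == 0L) return(out)

  reg <- .peakRegions(pk, cfg)
  qual_by_mol <- tapply(reg$qualifying, pk$mol_id, any)
  pos_ids <- names(qual_by_mol)[qual_by_mol]
  out$label[out$mol_id %in% pos_ids] <- "POS"

  # POS sub-band: peak with the highest MEC inside the window
  inw_present <- reg$in_window & !is.na(pk$mec)
  if (any(inw_present)) {
    mx <- tapply(pk$mec[inw_present], pk$mol_id[inw_present], max)
    band <- ifelse(mx >= 10000, "mec_ge_10k",
            ifelse(mx >= 5000, "mec_5k_10k",
            ifelse(mx >= cfg$mec_threshold, "mec_1k_5k", "none")))
    idx <- match(names(mx), out$mol_id)
    sel <- out$label[idx] == "POS"
    out$pos_band[idx[sel]] <- band[sel]
  }

  # NEG per-peak region flags (peaks with a present MEC only)
  neg_ids <- out$mol_id[out$label == "NEG"]
  np <- !is.na(pk$mec) & pk$mol_id %in% neg_ids
  if (any(np)) {
    wl <- pk$wavelength_nm[np]; mec <- pk$mec[np]
    flag <- ifelse(wl < cfg$window_low & mec < cfg$mec_threshold, "below290_lowMEC",
            ifelse(wl < cfg$window_low, "below290_highMEC",
            ifelse(wl > cfg$window_high & mec < cfg$mec_threshold, "above700_lowMEC",
            ifelse(wl > cfg$window_high, "above700_highMEC",
            ifelse(mec <= 900, "inwindow_le900", "inwindow_gt900")))))
    agg <- tapply(flag, pk$mol_id[np],
                  function(f) joinFlags(sort(unique(f))))
    out$neg_flags[match(names(agg), out$mol_id)] <- unname(agg)
  }

  # advisory data-quality flags
  qf <- vapply(split(seq_len(nrow(pk)), pk$mol_id), function(rows) {
    wl <- pk$wavelength_nm[rows]; mec <- pk$mec[rows]
    present <- !is.na(mec)
    inw <- wl >= cfg$window_low & wl <= cfg$window_high
    f <- character(0)
    if (any(present) && all(mec[present] >= 3 & mec[present] <= 5))
      f <- c(f, "suspect_log_mec")
    if (any(wl >= 281 & wl <= 317)) f <- c(f, "near_lower_endpoint")
    if (any(inw & present & mec >= 661 & mec <= 1500))
      f <- c(f, "near_mec_threshold")
    if (any(!present)) f <- c(f, "missing_mec")
    joinFlags(sort(f))
  }, character(1))
  out$quality_flags[match(names(qf), out$mol_id)] <- unname(qf)
  out
}

#' Label a single spectrum record
#'
#' @param peaks data.frame with columns wavelength_nm, mec for one molecule
#'   (zero rows = empty list).
#' @param cfg a \code{\link{labelConfig}}.
#' @return one-row data.frame as from \code{\link{labelSpectra}}.
#' @export
labelSpectrum <- function(peaks, cfg = labelConfig()) {
  if (nrow(peaks) > 0L) peaks$mol_id <- "x"
  labelSpectra(spectrumSet(peaks, mol_ids = "x"), cfg)
}

#' POS sub-category of a single record
#'
#' Band of the highest-MEC in-window peak, half-open bands
#' [1000,5000), [5000,10000), [10000,Inf).
#'
#' @inheritParams labelSpectrum
#' @return one of "mec_1k_5k", "mec_5k_10k", "mec_ge_10k".
#' @export
posSubcategory <- function(peaks, cfg = labelConfig()) {
  lab <- labelSpectrum(peaks, cfg)
  if (lab$label != "POS")
    stop("posSubcategory() requires a POS-labelled record")
  lab$pos_band
}

#' NEG per-peak region flags of a single record
#'
#' @inheritParams labelSpectrum
#' @return character vector of region flags (one per occupied region).
#' @export
negPeakFlags <- function(peaks, cfg = labelConfig()) {
  lab <- labelSpectrum(peaks, cfg)
  if (lab$label != "NEG") stop("negPeakFlags() requires a NEG-labelled record")
  splitFlags(lab$neg_flags)
}

#' Data-quality flags of a single record
#'
#' @inheritParams labelSpectrum
#' @return character vector of quality flags.
#' @export
qualityFlags <- function(peaks, cfg = labelConfig()) {
  splitFlags(labelSpectrum(peaks, cfg)$quality_flags)
}

#' Randomly split labelled molecules into train / test I / test II
#'
#' Uniform random, seed-reproducible, disjoint partition. Class counts per
#' split are attached as the "class_counts" attribute.
#'
#' @param labels data.frame with columns mol_id and label.
#' @param sizes integer vector (train, test1, test2); must sum to at most
#'   \code{nrow(labels)}.
#' @param seed integer seed.
#' @return list with character-vector elements train, test1, test2.
#' @export
splitDataset <- function(labels, sizes, seed) {
  stopifnot(length(sizes) == 3L)
  n <- nrow(labels)
  if (sum(sizes) > n)
    stop("requested split sizes (", sum(sizes),
         ") exceed the number of labelled molecules (", n, ")")
  set.seed(as.integer(seed))
  ord <- sample.int(n)
  take <- function(from, len) labels$mol_id[ord[seq(from, length.out = len)]]
  res <- list(train = take(1, sizes[1]),
              test1 = take(1 + sizes[1], sizes[2]),
              test2 = take(1 + sizes[1] + sizes[2], sizes[3]))
  counts <- lapply(res, function(ids)
    table(factor(labels$label[match(ids, labels$mol_id)],
                 levels = c("POS", "NEG"))))
  attr(res, "class_counts") <- counts
  res
}
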