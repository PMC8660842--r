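# End-to-end orchestration: simulate/curate -> label -> featurize ->
# train -> evaluate -> triage -> phototox as declared stages of a single
# YAML/JSON config, with a run manifest (config hash, seeds, file
# digests) written next to the artifacts. Reruns with an identical config
# and inputs reproduce identical outputs: every stochastic stage takes
# its seed from the config, never from the clock.

.readPipelineConfig <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::read_json(config, simplifyVector = TRUE)
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON file")
  if (is.null(config$out_dir)) stop("config needs an out_dir")
  if (is.null(config$seed)) stop("config needs a seed (no clock seeding)")
  if (is.null(config$stages) || length(config$stages) == 0L)
    stop("config needs a nonempty stages list")
  known <- c("simulate", "curate", "label", "featurize", "train",
             "evaluate", "triage", "phototox")
  bad <- setdiff(unlist(config$stages), known)
  if (length(bad)) stop("unknown stages: ", paste(bad, collapse = ", "))
  config
}

.fileDigests <- function(paths) {
  paths <- paths[file.exists(paths)]
  if (length(paths) == 0L) return(list())
  as.list(tools::md5sum(paths))
}

#' Run the classification pipeline from a config
#'
#' Executes the declared stages in order against one output directory.
#' Supported stages: \code{simulate} (synthetic study), \code{curate}
#' (parse/standardize/filter/dedup an input SMILES file), \code{label},
#' \code{featurize}, \code{train} (+ held-out evaluation when a split is
#' configured), \code{evaluate}, \code{triage}, \code{phototox}. A failing
#' stage halts the run with the stage named. A JSON run manifest (stage
#' sequence, seed, config and artifact digests) is written last.
#'
#' @param config list, or path to a YAML/JSON file, with at least
#'   \code{out_dir}, \code{seed} and \code{stages}; stage-specific blocks
#'   (\code{simulate}, \code{train}, ...) override defaults.
#' @return the manifest list, invisibly; artifacts are files in
#'   \code{out_dir}.
#' @export
runPipeline <- function(config) {
  cfg <- .readPipelineConfig(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- as.integer(cfg$seed)
  state <- list()
  artifacts <- character(0)
  for (stage in unlist(cfg$stages)) {
    res <- tryCatch(switch(stage,
      simulate = {
        sc <- do.call(simConfig, c(cfg$simulate,
                                   if (is.null(cfg$simulate$seed))
                                     list(seed = seed)))
        study <- simulateStudy(sc, dir = out_dir)
        state$molecules <- stats::setNames(study$molecules$smiles,
                                           study$molecules$mol_id)
        state$spectra <- study$spectra
        state$labels <- study$labels
        state$outcomes <- study$outcomes
        c("curated.smi", "peaks.csv", "tox.csv", "truth.json")
      },
      curate = {
        if (is.null(cfg$curate$input))
          stop("curate stage needs an input SMILES file")
        if (!file.exists(cfg$curate$input))
          stop("curate input not found: ", cfg$curate$input)
        ms <- parseStructures(cfg$curate$input,
                              format = cfg$curate$format %||% "smiles")
        ms <- standardizeMolecules(ms)
        fl <- filterEligible(ms, do.call(eligibilityRule,
                                         cfg$curate$rule %||% list()))
        dd <- deduplicateMolecules(fl$kept, state$spectra)
        if (is(dd, "MoleculeSet")) dd <- list(molecules = dd)
        state$molecules <- stats::setNames(
          molData(dd$molecules)$canonical_smiles, molIds(dd$molecules))
        if (!is.null(dd$spectra)) state$spectra <- dd$spectra
        writeCurationAudit(dd$molecules, fl$rejected,
                           file.path(out_dir, "curation_audit.csv"))
        writeLines(paste(unname(state$molecules),
                         names(state$molecules), sep = "\t"),
                   file.path(out_dir, "curated.smi"))
        c("curation_audit.csv", "curated.smi")
      },
      label = {
        if (is.null(state$spectra)) {
          if (is.null(cfg$label$peaks))
            stop("label stage needs peaks (file) or a simulate stage")
          if (!file.exists(cfg$label$peaks))
            stop("peaks file not found: ", cfg$label$peaks)
          state$spectra <- readPeakTable(cfg$label$peaks)
        }
        lc <- do.call(labelConfig, cfg$label$config %||% list())
        state$labels <- labelSpectra(state$spectra, lc)
        utils::write.csv(state$labels, file.path(out_dir, "labels.csv"),
                         row.names = FALSE)
        "labels.csv"
      },
      featurize = {
        if (is.null(state$molecules)) stop("no molecules to featurize")
        sets <- unlist(cfg$featurize$sets %||% "morgan")
        mats <- lapply(sets, function(s)
          computeFingerprints(state$molecules, s))
        state$features <- combineFeatureMatrices(mats)
        utils::write.csv(
          data.frame(mol_id = molIds(state$features),
                     featureValues(state$features),
                     check.names = FALSE),
          file.path(out_dir, "features.csv"), row.names = FALSE)
        jsonlite::write_json(
          list(sets = sets, n_columns = ncol(featureValues(state$features)),
               dropped = droppedMolecules(state$features)),
          file.path(out_dir, "features_meta.json"), auto_unbox = TRUE)
        c("features.csv", "features_meta.json")
      },
      train = {
        if (is.null(state$features) || is.null(state$labels))
          stop("train stage needs featurize and label results")
        ids <- intersect(molIds(state$features), state$labels$mol_id)
        sizes <- cfg$train$split %||%
          c(floor(0.8 * length(ids)), floor(0.1 * length(ids)),
            floor(0.1 * length(ids)))
        sizes <- as.integer(unlist(sizes))
        sp <- splitDataset(
          state$labels[match(ids, state$labels$mol_id), ], sizes,
          seed = seed)
        rc <- rfConfig(n_trees = cfg$train$n_trees %||% 500L,
                       mtry = cfg$train$mtry %||% "sqrt", seed = seed)
        Xall <- featureValues(state$features)
        lab <- function(v) state$labels$label[match(v, state$labels$mol_id)]
        state$model <- trainForest(Xall[sp$train, , drop = FALSE],
                                   lab(sp$train), rc)
        state$split <- sp
        preds <- predictSpectrumClass(state$model,
                                      Xall[sp$test1, , drop = FALSE])
        state$preds <- preds
        utils::write.csv(preds, file.path(out_dir, "predictions.csv"),
                         row.names = FALSE)
        "predictions.csv"
      },
      evaluate = {
        if (is.null(state$preds)) stop("evaluate stage needs train results")
        truth <- state$labels$label[match(state$preds$mol_id,
                                          state$labels$mol_id)]
        rep <- evaluatePredictions(truth, state$preds$predicted,
                                   state$preds$prob_pos)
        m <- evalMetrics(rep)
        state$eval <- rep
        jsonlite::write_json(
          list(counts = as.list(evalCounts(rep)),
               se = m[["se"]], sp = m[["sp"]], q = m[["q"]],
               mcc = m[["mcc"]], auc = rep@auc,
               oob_accuracy = oobAccuracy(state$model)),
          file.path(out_dir, "eval.json"), auto_unbox = TRUE,
          digits = NA)
        "eval.json"
      },
      triage = {
        if (is.null(state$preds)) stop("triage stage needs train results")
        ent <- highConfidenceErrors(
          state$preds, state$labels,
          p_threshold = cfg$triage$threshold %||% 0.8)
        Xall <- featureValues(state$features)
        fam <- new("FeatureMatrix", values = Xall,
                   provenance = provenance(state$features),
                   dropped = character(0))
        trainfp <- new("FeatureMatrix",
                       values = Xall[state$split$train, , drop = FALSE],
                       provenance = provenance(state$features),
                       dropped = character(0))
        tri <- explainErrors(ent, state$labels, fam, trainfp,
                             state$labels)
        utils::write.csv(tri, file.path(out_dir, "triage.csv"),
                         row.names = FALSE)
        "triage.csv"
      },
      phototox = {
        if (is.null(state$outcomes)) {
          if (is.null(cfg$phototox$outcomes))
            stop("phototox stage needs outcomes (file) or simulate stage")
          state$outcomes <- utils::read.csv(cfg$phototox$outcomes,
                                            stringsAsFactors = FALSE)
        }
        cohort <- state$outcomes
        classes <- if (!is.null(state$preds) &&
                       all(cohort$mol_id %in% state$preds$mol_id))
          state$preds else state$labels
        ct <- phototoxCrossTab(classes, cohort)
        jsonlite::write_json(
          list(counts = as.list(as.data.frame(ct@counts)),
               se_tox = ct@seTox, sp_tox = ct@spTox,
               concordant = ct@counts[1, 1] + ct@counts[2, 2]),
          file.path(out_dir, "crosstab.json"), auto_unbox = TRUE,
          digits = NA)
        "crosstab.json"
      }),
      error = function(e)
        stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
             call. = FALSE))
    artifacts <- c(artifacts, res)
  }
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE)
  cfg_file <- file.path(out_dir, "config_used.json")
  writeLines(cfg_json, cfg_file)
  manifest <- list(
    stages = unlist(cfg$stages), seed = seed,
    config_digest = unname(tools::md5sum(cfg_file)),
    artifacts = .fileDigests(file.path(out_dir, unique(artifacts))),
    r_version = as.character(getRversion()),
    package_version = as.character(utils::packageVersion("SpectraForest")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
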