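## End-to-end orchestration: simulate -> ingest -> network -> link ->
## ticf -> enrich -> predict -> ablate, with resumable file artifacts and
## a JSON summary.

#' Default pipeline configuration
#'
#' All stage parameters in one validated list. Randomness is funnelled
#' through the single master `seed`: the simulator uses `seed`, model
#' fitting and cross-validation partitions use `seed + 1`, validation
#' subsampling `seed + 2`.
#'
#' @param seed master seed.
#' @param ablate also run the ablation grid (default TRUE).
#' @return a named list (class `PipelineConfig`).
#' @export
defaultPipelineConfig <- function(seed = 7L, ablate = TRUE) {
  structure(list(
    seed = as.integer(seed),
    simulate = TRUE,
    synthetic = list(),          # overrides for syntheticConfig()
    aberration = list(zAbsCutoff = 2.0, cnGain = 0.5, cnLoss = -0.5),
    scoring = list(baseInternal = 1.0, baseLinked = 0.5,
                   frequencyBonus = 0.05, trustedThreshold = 10L),
    ticf = list(k = 5L, widths = c(1L, 3L, 3L)),
    folds = 5L,
    seedPatient = NULL,          # NULL: defaultSeedPatient()
    ablate = isTRUE(ablate)),
    class = "PipelineConfig")
}

validatePipelineConfig <- function(config) {
  need <- c("seed", "simulate", "synthetic", "aberration", "scoring",
            "ticf", "folds", "ablate")
  missing <- setdiff(need, names(config))
  if (length(missing))
    stop("pipeline config lacks field(s): ", paste(missing, collapse = ", "))
  stopifnot(is.numeric(config$seed), is.numeric(config$folds),
            config$folds >= 2, is.list(config$aberration),
            is.list(config$scoring), is.list(config$ticf))
  config
}

#' Read a pipeline configuration
#'
#' @param x a YAML file path, a list of overrides, or NULL for defaults.
#' @return validated `PipelineConfig`.
#' @export
readPipelineConfig <- function(x = NULL) {
  cfg <- defaultPipelineConfig()
  over <- if (is.null(x)) list()
          else if (is.character(x)) yaml::read_yaml(x)
          else as.list(x)
  for (nm in names(over)) {
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      utils::modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
  }
  validatePipelineConfig(cfg)
}

stageDone <- function(paths) all(file.exists(paths))

runStage <- function(name, outputs, force, fun) {
  if (!force && stageDone(outputs)) {
    message(sprintf("[%s] artifacts present, skipping (use force to redo)",
                    name))
    return(invisible(FALSE))
  }
  message(sprintf("[%s] running", name))
  tryCatch(fun(), error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE))
  invisible(TRUE)
}

reportToList <- function(report) {
  m <- cvMetrics(report)
  out <- list()
  for (fam in unique(m$model)) {
    out[[fam]] <- lapply(split(m[m$model == fam, ],
                               m$split[m$model == fam]), function(r)
      stats::setNames(lapply(seq_len(nrow(r)), function(i)
        list(mean = r$mean[i], sd = r$sd[i])), r$metric))
  }
  out
}

#' Run the full integration and prediction pipeline
#'
#' Executes the stages in dependency order, persisting each stage's
#' artifacts under `outDir` and skipping stages whose artifacts already
#' exist unless `force` is set. Inputs are either simulated
#' (`config$simulate`) or taken from `inputFiles` (a list per study with
#' elements `clinical`, `expression`, `cnv` and an `edks` TSV path).
#'
#' @param config see [readPipelineConfig()].
#' @param outDir run directory.
#' @param inputFiles real input files when `config$simulate` is FALSE.
#' @param force recompute existing artifacts.
#' @return the summary list (also written to `outDir/summary.json`).
#' @export
runPipeline <- function(config = NULL, outDir, inputFiles = NULL,
                        force = FALSE) {
  config <- if (inherits(config, "PipelineConfig"))
    validatePipelineConfig(config) else readPipelineConfig(config)
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  fixDir <- file.path(outDir, "fixtures")
  storeDir <- file.path(outDir, "store")
  paths <- list(manifest = file.path(fixDir, "manifest.json"),
                edks = file.path(fixDir, "edks.tsv"),
                network = file.path(outDir, "network.tsv"),
                ticf = file.path(outDir, "ticf.tsv"),
                cohort = file.path(outDir, "cohort.json"),
                report = file.path(outDir, "report.json"),
                ablation = file.path(outDir, "ablation.json"),
                summary = file.path(outDir, "summary.json"))

  ## --- simulate ---------------------------------------------------------
  if (isTRUE(config$simulate)) {
    simCfg <- do.call(syntheticConfig,
                      utils::modifyList(list(seed = config$seed),
                                        config$synthetic))
    runStage("simulate", c(paths$manifest, paths$edks), force, function() {
      manifest <- generateCohort(simCfg, fixDir)
      generateEdksFixture(simCfg, manifest, paths$edks)
    })
    manifest <- jsonlite::read_json(paths$manifest)
    inputFiles <- lapply(manifest$files, function(f)
      list(clinical = file.path(fixDir, f$clinical),
           expression = file.path(fixDir, f$expression),
           cnv = file.path(fixDir, f$cnv)))
    edksPath <- paths$edks
  } else {
    if (is.null(inputFiles))
      stop("inputFiles required when config$simulate is FALSE")
    edksPath <- inputFiles$edks
    inputFiles <- inputFiles[setdiff(names(inputFiles), "edks")]
  }

  ## --- ingest -----------------------------------------------------------
  storePaths <- file.path(storeDir, paste0(DATA_TYPES, ".ndjson"))
  runStage("ingest", storePaths, force, function() {
    for (dt in DATA_TYPES) {
      files <- unlist(lapply(names(inputFiles), function(st)
        stats::setNames(inputFiles[[st]][[dt]], st)))
      files <- files[!vapply(files, is.null, logical(1L))]
      ingestStudyFiles(files, dt, storeDir)
    }
  })
  documents <- unlist(lapply(storePaths, loadDocuments), recursive = FALSE)

  aberration <- do.call(aberrationConfig, config$aberration)
  scoring <- do.call(scoringConfig, config$scoring)

  ## --- network + link ---------------------------------------------------
  runStage("network", paths$network, force, function() {
    net <- buildInternalNetwork(documents, aberration, scoring)
    net <- addLinkedRelations(net, edksFixtureProvider(edksPath), scoring)
    net <- pruneUntrusted(markTrusted(net, scoring))
    exportNetwork(net, paths$network, "tsv")
  })
  network <- importNetwork(paths$network, "tsv")

  ## --- ticf -------------------------------------------------------------
  runStage("ticf", paths$ticf, force, function() {
    ticf <- buildTICFTable(documents, k = config$ticf$k,
                           widths = config$ticf$widths)
    utils::write.table(ticfValues(ticf), paths$ticf, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  })
  ticf <- buildTICFTable(documents, k = config$ticf$k,
                         widths = config$ticf$widths)

  ## --- enrich + predict -------------------------------------------------
  seedPatient <- if (is.null(config$seedPatient)) defaultSeedPatient(ticf)
                 else config$seedPatient
  runStage("enrich", paths$cohort, force, function() {
    cohort <- enrichCohort(seedPatient, network, ticf, documents)
    jsonlite::write_json(
      list(seed = cohort@seed, ring0 = cohort@ring0, ring1 = cohort@ring1,
           ring2 = cohort@ring2, proteins = cohort@proteinsUsed$protein),
      paths$cohort, auto_unbox = TRUE, digits = NA)
  })
  cohort <- enrichCohort(seedPatient, network, ticf, documents)

  specs <- defaultModelSpecs(seed = config$seed + 1L)
  runStage("predict", paths$report, force, function() {
    y <- survivalTargets(cohort)
    obs <- !is.na(y)
    report <- crossValidate(featureMatrix(cohort)[obs, , drop = FALSE],
                            y[obs], specs = specs, k = config$folds,
                            seed = config$seed + 1L)
    jsonlite::write_json(reportToList(report), paths$report,
                         auto_unbox = TRUE, digits = NA)
  })

  ## --- ablate -----------------------------------------------------------
  if (isTRUE(config$ablate)) {
    runStage("ablate", paths$ablation, force, function() {
      ab <- runAblation(network, ticf, documents, seedPatient = seedPatient,
                        specs = specs, k = config$folds,
                        seed = config$seed + 1L)
      jsonlite::write_json(
        lapply(ab, function(x) list(
          n = x$report@n,
          cohortSize = length(ringPatients(x$cohort)),
          meanHeldOutR2 = meanHeldOutMetric(x$report),
          metrics = reportToList(x$report))),
        paths$ablation, auto_unbox = TRUE, digits = NA)
    })
  }

  ## --- summary ----------------------------------------------------------
  e <- networkEdges(network)
  report <- jsonlite::read_json(paths$report)
  summary <- list(
    seed = config$seed,
    recordsIngested = length(documents),
    patients = length(patientNodes(network)),
    proteins = length(proteinNodes(network)),
    relations = nrow(e),
    trustedRelations = sum(e$trusted),
    ticfPatients = nrow(ticfValues(ticf)),
    seedPatient = seedPatient,
    cohort = list(ring0 = length(cohort@ring0),
                  ring1 = length(cohort@ring1),
                  ring2 = length(cohort@ring2)),
    heldOutR2 = stats::setNames(lapply(names(report), function(f)
      report[[f]]$test$r2$mean), names(report)),
    config = list(folds = config$folds,
                  trustedThreshold = scoring@trustedThreshold,
                  zAbsCutoff = aberration@zAbsCutoff,
                  cnGain = aberration@cnGain, cnLoss = aberration@cnLoss,
                  k = config$ticf$k))
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(summary)
}
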