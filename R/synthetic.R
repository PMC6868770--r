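## Synthetic two-study cohort generator with known ground truth: study
## dialects (delimiters, field aliases), clinical covariates, planted
## protein modules in expression / copy-number layers, a parametric
## survival model, and an EDKS relation fixture.

#' Synthetic cohort configuration
#'
#' Defaults emulate a two-study setting: a smaller RNA-Seq-flavoured
#' study and a larger microarray-flavoured study, written in different
#' delimiter and field-name dialects so that horizontal integration is
#' genuinely exercised. Survival months follow
#' `max(0, min(cap, alpha - betaStage*stage - betaSize*size -
#' betaAge*age + eps))`, `eps ~ N(0, noiseSd^2)` — a stage-dominant
#' prognosis with minor size and age effects. Tumor size is sampled
#' conditional on stage (larger tumors at higher stages). Module carriers
#' are sampled conditional on the TICF group targeted by each module, so
#' network enrichment pulls in patients with correlated survival.
#' Expression background is bounded (Uniform(-1, 1)) with planted
#' aberrations at high magnitude, so cohort z-score calling recovers the
#' planted sets exactly; copy-number background stays inside the
#' gain/loss cutoffs with planted carriers outside them.
#'
#' @param nPatients integer vector, patients per study (default 150, 400).
#' @param studyNames study labels.
#' @param stageProbs stage 1-4 distribution.
#' @param ageRange age range in years.
#' @param alpha,betaStage,betaSize,betaAge,noiseSd,capMonths survival
#'   model parameters (months).
#' @param nProteins number of protein symbols.
#' @param nModules,moduleSize planted co-aberration modules.
#' @param carrierRate fraction of all patients carrying each module.
#' @param groupConcentration fraction of a module's carriers drawn from
#'   its target TICF group.
#' @param nPrivateAberrations per-patient random private aberrations.
#' @param ticfCompleteFraction fraction of patients with all three TICF
#'   components (default 0.7: not every patient has a TICF).
#' @param survivalKnownFraction fraction of patients with a recorded
#'   survival target.
#' @param decoyDensity EDKS decoy relations per protein.
#' @param k TICF stratification groups.
#' @param seed master seed.
#' @return a validated configuration list (class `SyntheticConfig`).
#' @export
syntheticConfig <- function(nPatients = c(150L, 400L),
                            studyNames = c("NB", "BC"),
                            stageProbs = c(0.15, 0.30, 0.35, 0.20),
                            ageRange = c(20L, 85L),
                            alpha = 190, betaStage = 26, betaSize = 0.08,
                            betaAge = 0.06, noiseSd = 12, capMonths = 240,
                            nProteins = 120L, nModules = 6L,
                            moduleSize = 5L, carrierRate = 0.06,
                            groupConcentration = 0.95,
                            nPrivateAberrations = 1L,
                            ticfCompleteFraction = 0.7,
                            survivalKnownFraction = 0.92,
                            decoyDensity = 0.1, k = 5L, seed = 7L) {
  cfg <- list(nPatients = as.integer(nPatients), studyNames = studyNames,
              stageProbs = stageProbs, ageRange = as.integer(ageRange),
              alpha = alpha, betaStage = betaStage, betaSize = betaSize,
              betaAge = betaAge, noiseSd = noiseSd, capMonths = capMonths,
              nProteins = as.integer(nProteins),
              nModules = as.integer(nModules),
              moduleSize = as.integer(moduleSize),
              carrierRate = carrierRate,
              groupConcentration = groupConcentration,
              nPrivateAberrations = as.integer(nPrivateAberrations),
              ticfCompleteFraction = ticfCompleteFraction,
              survivalKnownFraction = survivalKnownFraction,
              decoyDensity = decoyDensity, k = as.integer(k),
              seed = as.integer(seed))
  stopifnot(length(cfg$nPatients) == length(cfg$studyNames),
            all(cfg$nPatients > 0L),
            abs(sum(cfg$stageProbs) - 1) < 1e-9,
            all(c(cfg$carrierRate, cfg$groupConcentration,
                  cfg$ticfCompleteFraction, cfg$survivalKnownFraction)
                >= 0),
            all(c(cfg$carrierRate, cfg$groupConcentration,
                  cfg$ticfCompleteFraction, cfg$survivalKnownFraction)
                <= 1),
            cfg$nModules * cfg$moduleSize <= cfg$nProteins,
            cfg$noiseSd >= 0, cfg$decoyDensity >= 0)
  if (round(cfg$carrierRate * sum(cfg$nPatients)) > sum(cfg$nPatients))
    stop("infeasible config: module larger than the cohort")
  class(cfg) <- "SyntheticConfig"
  cfg
}

## study dialects: delimiter + clinical field names + stage notation
studyDialect <- function(i) {
  if (i %% 2L == 1L)
    list(delimiter = ",", technology = "RNA-Seq",
         clinicalFields = c(id = "id", sample = "sample_id",
                            stage = "stage", size = "tumor_size",
                            age = "age", survival = "survival_months"),
         romanStage = FALSE)
  else
    list(delimiter = "\t", technology = "microarray",
         clinicalFields = c(id = "ID", sample = "SampleID",
                            stage = "tumor_stage", size = "size_mm",
                            age = "age_at_diagnosis", survival = "os_months"),
         romanStage = TRUE)
}

formatStage <- function(stage, roman) {
  if (roman) c("I", "II", "III", "IV")[stage] else as.character(stage)
}

resample <- function(x, size) x[sample.int(length(x), size)]

writeDelimited <- function(path, headerLines, attributeRow, rows, delim) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(headerLines, con)
  writeLines(paste(attributeRow, collapse = delim), con)
  writeLines(vapply(rows, paste, character(1L), collapse = delim), con)
  invisible(path)
}

#' Generate a synthetic two-study cohort on disk
#'
#' Writes, per study, a clinical table, an expression matrix and a
#' copy-number table in the study's dialect, joined by sample id, plus a
#' JSON manifest recording every ground truth (clinical values, survival
#' parameters, module membership, per-patient aberration sets, TICF
#' groups, file layout). Identical configurations produce byte-identical
#' files.
#'
#' @param cfg a [syntheticConfig()].
#' @param outDir output directory (created if needed).
#' @return the manifest, invisibly also written to
#'   `file.path(outDir, "manifest.json")`.
#' @export
generateCohort <- function(cfg, outDir) {
  stopifnot(inherits(cfg, "SyntheticConfig"))
  if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
  set.seed(cfg$seed)
  nTotal <- sum(cfg$nPatients)
  study <- rep(cfg$studyNames, cfg$nPatients)
  sampleId <- unlist(lapply(seq_along(cfg$studyNames), function(i)
    sprintf("%s%03d", cfg$studyNames[i], seq_len(cfg$nPatients[i]))))

  ## clinical ground truth; tumor size grows with stage
  stage <- sample.int(4L, nTotal, replace = TRUE, prob = cfg$stageProbs)
  sizeLo <- 5 + 18 * (stage - 1)
  sizeHi <- 30 + 22 * (stage - 1)
  size <- as.integer(round(stats::runif(nTotal, sizeLo, sizeHi)))
  age <- as.integer(round(stats::runif(nTotal, cfg$ageRange[1L],
                                       cfg$ageRange[2L])))
  survival <- round(pmin(cfg$capMonths, pmax(0,
    cfg$alpha - cfg$betaStage * stage - cfg$betaSize * size -
      cfg$betaAge * age + stats::rnorm(nTotal, 0, cfg$noiseSd))), 2)

  ticfComplete <- stats::runif(nTotal) < cfg$ticfCompleteFraction
  hiddenComponent <- sample.int(3L, nTotal, replace = TRUE)
  survivalKnown <- stats::runif(nTotal) < cfg$survivalKnownFraction

  ## TICF groups over the complete patients (module targeting)
  group <- rep(NA_integer_, nTotal)
  compIdx <- which(ticfComplete)
  composite <- buildTICF(stage[compIdx], size[compIdx], age[compIdx])
  nz <- normalizeValues(composite)
  group[compIdx] <- stratifyPatients(nz$normalized, sampleId[compIdx],
                                     k = cfg$k)

  ## planted modules: proteins, carriers concentrated in a target group
  proteins <- sprintf("HGX%03d", seq_len(cfg$nProteins))
  nCarriers <- max(2L, round(cfg$carrierRate * nTotal))
  modules <- list()
  for (j in seq_len(cfg$nModules)) {
    prots <- proteins[((j - 1L) * cfg$moduleSize + 1L):(j * cfg$moduleSize)]
    targetGroup <- ((j - 1L) %% cfg$k) + 1L
    inGroup <- which(!is.na(group) & group == targetGroup)
    nIn <- min(length(inGroup), round(cfg$groupConcentration * nCarriers))
    carriers <- c(resample(inGroup, nIn),
                  resample(setdiff(seq_len(nTotal), inGroup),
                           nCarriers - nIn))
    modules[[j]] <- list(
      id = j, proteins = prots,
      layer = if (j %% 2L == 1L) "expression" else "cnv",
      cnSign = if (j %% 4L == 2L) 1 else -1,
      targetGroup = targetGroup,
      carriers = sort(sampleId[carriers]))
  }

  ## private (rare, untrusted) expression aberrations, drawn from the
  ## non-module proteins so they stay below the trusted-support threshold
  decoyProteins <- proteins[seq.int(cfg$nModules * cfg$moduleSize + 1L,
                                    length.out = cfg$nProteins -
                                      cfg$nModules * cfg$moduleSize)]
  if (!length(decoyProteins)) decoyProteins <- proteins
  privateProt <- replicate(nTotal,
    resample(decoyProteins, cfg$nPrivateAberrations), simplify = FALSE)

  exprCarrierSets <- stats::setNames(
    lapply(seq_len(nTotal), function(i) sort(unique(privateProt[[i]]))),
    sampleId)
  cnvCarrierSets <- stats::setNames(
    replicate(nTotal, character(), simplify = FALSE), sampleId)
  cnvSign <- list()
  for (m in modules) {
    for (s in m$carriers) {
      if (m$layer == "expression")
        exprCarrierSets[[s]] <- sort(unique(c(exprCarrierSets[[s]],
                                              m$proteins)))
      else {
        cnvCarrierSets[[s]] <- sort(unique(c(cnvCarrierSets[[s]],
                                             m$proteins)))
        for (p in m$proteins) cnvSign[[p]] <- m$cnSign
      }
    }
  }

  ## molecular matrices: bounded background, high-magnitude aberrations
  exprMat <- matrix(round(stats::runif(cfg$nProteins * nTotal, -1, 1), 4),
                    nrow = cfg$nProteins,
                    dimnames = list(proteins, sampleId))
  for (s in sampleId) {
    ab <- exprCarrierSets[[s]]
    if (length(ab))
      exprMat[ab, s] <- round(6 + stats::runif(length(ab), 0, 0.5), 4)
  }
  cnvMat <- matrix(round(stats::runif(cfg$nProteins * nTotal, -0.3, 0.3), 4),
                   nrow = cfg$nProteins,
                   dimnames = list(proteins, sampleId))
  for (s in sampleId) {
    ab <- cnvCarrierSets[[s]]
    if (length(ab)) {
      sign <- vapply(ab, function(p) cnvSign[[p]], numeric(1L))
      cnvMat[ab, s] <- round(sign * (1 + stats::runif(length(ab), 0, 0.2)), 4)
    }
  }

  ## write per-study files in their dialects
  files <- list()
  for (i in seq_along(cfg$studyNames)) {
    nm <- cfg$studyNames[i]
    dia <- studyDialect(i)
    inStudy <- which(study == nm)
    fcl <- dia$clinicalFields
    clinPath <- file.path(outDir, sprintf("%s_clinical.txt", nm))
    exprId <- sprintf("EXP-%s-001", nm)
    cnvId <- sprintf("CNV-%s-001", nm)
    rows <- lapply(inStudy, function(ix) {
      st <- if (ticfComplete[ix] || hiddenComponent[ix] != 1L)
        formatStage(stage[ix], dia$romanStage) else ""
      sz <- if (ticfComplete[ix] || hiddenComponent[ix] != 2L)
        as.character(size[ix]) else ""
      ag <- if (ticfComplete[ix] || hiddenComponent[ix] != 3L)
        as.character(age[ix]) else ""
      sv <- if (survivalKnown[ix]) sprintf("%.2f", survival[ix]) else ""
      c(sprintf("REC-%s", sampleId[ix]), sampleId[ix], st, sz, ag, sv)
    })
    writeDelimited(clinPath,
                   c(sprintf("#technology=%s", dia$technology),
                     sprintf("#ref=%s,%s", exprId, cnvId)),
                   unname(fcl[c("id", "sample", "stage", "size", "age",
                                "survival")]),
                   rows, dia$delimiter)

    molPaths <- c(expression = file.path(outDir,
                                         sprintf("%s_expression.txt", nm)),
                  cnv = file.path(outDir, sprintf("%s_cnv.txt", nm)))
    for (dt in c("expression", "cnv")) {
      mat <- if (dt == "expression") exprMat else cnvMat
      writeDelimited(molPaths[[dt]],
                     c(sprintf("#technology=%s", dia$technology),
                       sprintf("#ref=%s", if (dt == "expression") exprId
                               else cnvId)),
                     c("hugo_symbol", sampleId[inStudy]),
                     lapply(proteins, function(p)
                       c(p, sprintf("%.4f", mat[p, sampleId[inStudy]]))),
                     dia$delimiter)
    }
    ## paths relative to outDir so manifests are location-independent
    files[[nm]] <- list(clinical = basename(clinPath),
                        expression = basename(molPaths[["expression"]]),
                        cnv = basename(molPaths[["cnv"]]),
                        delimiter = dia$delimiter,
                        technology = dia$technology,
                        referencedFileIds = c(exprId, cnvId),
                        clinicalFields = as.list(fcl))
  }

  manifest <- list(
    config = unclass(cfg),
    patients = stats::setNames(as.list(sampleId), NULL),
    study = stats::setNames(as.list(study), sampleId),
    clinicalTruth = lapply(stats::setNames(seq_len(nTotal), sampleId),
      function(ix) list(stage = stage[ix], size = size[ix], age = age[ix],
                        survival = survival[ix],
                        ticfComplete = ticfComplete[ix],
                        survivalKnown = survivalKnown[ix],
                        group = if (is.na(group[ix])) NULL else group[ix])),
    modules = modules,
    exprAberrations = exprCarrierSets,
    cnvAberrations = cnvCarrierSets,
    files = files)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  manifest
}

#' Generate the EDKS relation fixture
#'
#' Writes the protein-protein relation TSV standing in for external
#' knowledge sources: high-score relations linking the proteins of
#' paired planted modules (module 1 with 2, 3 with 4, ...) plus
#' low-score random decoy relations at `decoyDensity` per protein.
#' Relations are stored once with canonically ordered pairs.
#'
#' @param cfg the [syntheticConfig()] used for the cohort.
#' @param manifest manifest returned by [generateCohort()].
#' @param path output TSV path.
#' @return data.frame of the written relations (module links flagged).
#' @export
generateEdksFixture <- function(cfg, manifest, path) {
  set.seed(cfg$seed + 1L)
  modules <- manifest$modules
  rows <- list()
  j <- 1L
  while (j + 1L <= length(modules)) {
    a <- unlist(modules[[j]]$proteins)
    b <- unlist(modules[[j + 1L]]$proteins)
    m <- min(length(a), length(b))
    for (i in seq_len(m)) {
      pa <- min(a[i], b[i]); pb <- max(a[i], b[i])
      rows[[paste(pa, pb)]] <- data.frame(
        protein_a = pa, protein_b = pb,
        score = round(stats::runif(1L, 0.7, 0.95), 3),
        provider = "synthetic_edks", isModuleLink = TRUE,
        stringsAsFactors = FALSE)
    }
    j <- j + 2L
  }
  proteins <- sprintf("HGX%03d", seq_len(cfg$nProteins))
  nDecoys <- round(cfg$decoyDensity * cfg$nProteins)
  made <- 0L
  while (made < nDecoys) {
    pr <- sample(proteins, 2L)
    pa <- min(pr); pb <- max(pr)
    key <- paste(pa, pb)
    if (!is.null(rows[[key]])) next
    rows[[key]] <- data.frame(protein_a = pa, protein_b = pb,
                              score = round(stats::runif(1L, 0.05, 0.3), 3),
                              provider = "synthetic_edks",
                              isModuleLink = FALSE, stringsAsFactors = FALSE)
    made <- made + 1L
  }
  rel <- do.call(rbind, rows)
  rel <- rel[order(rel$protein_a, rel$protein_b), , drop = FALSE]
  rownames(rel) <- NULL
  utils::write.table(rel[, c("protein_a", "protein_b", "score", "provider")],
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  rel
}
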