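## In-code fixtures shared across the suite.

rec <- function(id, sample, type, fields) {
  rawRecord(id, sample, type, fields, sourceFile = "inline",
            sourceStudy = "S1")
}

clinicalDoc <- function(sample, stage = NA, size = NA, age = NA,
                        survival = NA, study = "S1") {
  f <- list()
  if (!is.na(stage)) f$stage <- as.character(stage)
  if (!is.na(size)) f$size <- as.character(size)
  if (!is.na(age)) f$age <- as.character(age)
  if (!is.na(survival)) f$survival_months <- as.character(survival)
  list(record_id = paste0("R-", sample), sample_id = sample,
       data_type = "clinical", source_file = "inline",
       source_study = study, fields = f)
}

cnvDoc <- function(sample, values, study = "S1") {
  list(record_id = paste0("C-", sample), sample_id = sample,
       data_type = "cnv", source_file = "inline", source_study = study,
       fields = as.list(values))
}

exprDoc <- function(sample, values, study = "S1") {
  list(record_id = paste0("E-", sample), sample_id = sample,
       data_type = "expression", source_file = "inline",
       source_study = study, fields = as.list(values))
}

## A small cohort where carriersOf lists the patients whose CNV marks each
## protein; support thresholds are exercised by the test via scoringConfig.
toyNetwork <- function(carriersOf, allPatients = NULL,
                       trustedThreshold = 1L) {
  patients <- sort(unique(c(unlist(carriersOf), allPatients)))
  docs <- c(lapply(patients, function(p) clinicalDoc(p, 2, 20, 50, 60)),
            lapply(patients, function(p) {
              prots <- names(carriersOf)[vapply(carriersOf, function(cs)
                p %in% cs, logical(1L))]
              cnvDoc(p, stats::setNames(as.list(rep(1, length(prots))),
                                        prots))
            }))
  buildInternalNetwork(docs,
                       scoring = scoringConfig(trustedThreshold =
                                                 trustedThreshold))
}

## independent brute-force two-hop enrichment traversal (test oracle)
bruteRings <- function(net, ring0) {
  e <- networkEdges(net)
  pp <- e[e$kind %in% c("patient_protein_expr", "patient_protein_cnv"), ]
  trustedOf <- function(pats)
    sort(unique(pp$target[pp$trusted & pp$source %in% pats]))
  carriersOf <- function(prots)
    sort(unique(pp$source[pp$target %in% prots]))
  ring1 <- setdiff(carriersOf(trustedOf(ring0)), ring0)
  prots01 <- trustedOf(c(ring0, ring1))
  ll <- e[e$kind == "protein_protein_linked" & e$trusted, ]
  partners <- setdiff(
    unique(c(ll$target[ll$source %in% prots01],
             ll$source[ll$target %in% prots01])), prots01)
  ring2 <- setdiff(carriersOf(partners), c(ring0, ring1))
  list(ring1 = sort(ring1), ring2 = sort(ring2))
}

## small synthetic configuration for fast end-to-end tests
testSyntheticConfig <- function(...) {
  ## 200 patients keep every per-study carrier fraction far below the
  ## z-score saturation bound while 0.06 * 200 = 12 carriers still clear
  ## the strict trusted-support threshold of 10
  args <- utils::modifyList(
    list(nPatients = c(80L, 120L), nProteins = 30L,
         nModules = 4L, moduleSize = 3L, carrierRate = 0.06,
         groupConcentration = 0.9, nPrivateAberrations = 1L,
         decoyDensity = 0.2, seed = 11L),
    list(...))
  do.call(syntheticConfig, args)
}

## generate a cohort + document store + network + ticf in one call
buildTestPipeline <- function(cfg = testSyntheticConfig(),
                              scoring = scoringConfig(),
                              dir = withr::local_tempdir(
                                .local_envir = parent.frame())) {
  manifest <- generateCohort(cfg, dir)
  edksPath <- file.path(dir, "edks.tsv")
  generateEdksFixture(cfg, manifest, edksPath)
  docs <- list()
  for (dt in c("clinical", "expression", "cnv")) {
    files <- vapply(names(manifest$files), function(st)
      file.path(dir, manifest$files[[st]][[dt]]), character(1L))
    docs <- c(docs, suppressMessages(
      ingestStudyFiles(files, dt, file.path(dir, "store")))$documents)
  }
  net <- suppressMessages(buildInternalNetwork(docs, scoring = scoring))
  net <- addLinkedRelations(net, edksFixtureProvider(edksPath), scoring)
  net <- pruneUntrusted(markTrusted(net, scoring))
  ticf <- suppressMessages(buildTICFTable(docs, k = cfg$k))
  list(cfg = cfg, manifest = manifest, documents = docs, network = net,
       ticf = ticf, dir = dir, edksPath = edksPath)
}
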