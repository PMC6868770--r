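#' @import methods
NULL

DATA_TYPES <- c("clinical", "expression", "cnv")

RELATION_KINDS <- c("patient_protein_expr", "patient_protein_cnv",
                    "protein_protein_linked", "patient_patient_shared")

EDGE_COLUMNS <- c("source", "target", "kind", "origin",
                  "frequency", "score", "trusted")

#' Semi-structure of a heterogeneous record collection
#'
#' A `SemiStructure` aggregates, per data type, the field names observed
#' across records together with their occurrence counts. It is built
#' incrementally, record by record, and acts as a flexible schema for the
#' document store: a record validated against it keeps only fields the
#' collection has seen.
#'
#' @slot dataType one of `"clinical"`, `"expression"`, `"cnv"`.
#' @slot fieldStats named integer vector, field name -> occurrence count.
#' @slot recordCount number of records folded in.
#'
#' @seealso [foldRecord()], [applySchema()]
#' @export
setClass("SemiStructure",
         representation(dataType = "character",
                        fieldStats = "integer",
                        recordCount = "integer"))

setValidity("SemiStructure", function(object) {
  msg <- character()
  if (length(object@dataType) != 1L || !object@dataType %in% DATA_TYPES)
    msg <- c(msg, sprintf("dataType must be one of %s",
                          paste(DATA_TYPES, collapse = ", ")))
  if (length(object@recordCount) != 1L || object@recordCount < 0L)
    msg <- c(msg, "recordCount must be a single non-negative integer")
  if (length(object@fieldStats)) {
    if (is.null(names(object@fieldStats)) || anyNA(names(object@fieldStats)) ||
        any(names(object@fieldStats) == ""))
      msg <- c(msg, "fieldStats must be named")
    if (anyDuplicated(names(object@fieldStats)))
      msg <- c(msg, "fieldStats names must be unique")
    if (any(object@fieldStats < 1L))
      msg <- c(msg, "every field count must be >= 1")
    if (any(object@fieldStats > object@recordCount))
      msg <- c(msg, "no field count may exceed recordCount")
  }
  if (length(object@fieldStats) == 0L && object@recordCount > 0L)
    msg <- c(msg, "fieldStats may be empty only when recordCount is 0")
  if (length(msg)) msg else TRUE
})

#' Create an empty semi-structure
#'
#' @param dataType one of `"clinical"`, `"expression"`, `"cnv"`.
#' @return A [SemiStructure-class] with zero records.
#' @examples
#' semiStructure("clinical")
#' @export
semiStructure <- function(dataType) {
  new("SemiStructure", dataType = dataType,
      fieldStats = integer(), recordCount = 0L)
}

#' File header metadata
#'
#' Metadata parsed from the commented header block of a delimited study
#' file: the generating technology, the declared attribute names (taken
#' from the attribute row) and any referenced file identifiers (clinical
#' files reference their molecular files this way).
#'
#' @slot technology platform string, possibly empty.
#' @slot attributeNames column names from the attribute row.
#' @slot referencedFileIds identifiers of files referenced by the header.
#' @slot nDeclaredAttributes declared (or inferred) attribute count.
#' @export
setClass("FileHeaderMeta",
         representation(technology = "character",
                        attributeNames = "character",
                        referencedFileIds = "character",
                        nDeclaredAttributes = "integer"))

setValidity("FileHeaderMeta", function(object) {
  if (length(object@nDeclaredAttributes) != 1L ||
      object@nDeclaredAttributes < 0L)
    "nDeclaredAttributes must be a single integer >= 0"
  else TRUE
})

#' Aberration-calling thresholds
#'
#' Cutoffs used to turn molecular profiles into per-patient aberrant
#' protein calls: expression values are aberrant when the cohort z-score
#' magnitude reaches `zAbsCutoff`; copy-number values when they reach
#' `cnGain` or fall to `cnLoss`.
#'
#' @slot zAbsCutoff absolute cohort z-score cutoff for expression (default 2).
#' @slot cnGain copy-number gain cutoff (default +0.5, log-ratio scale).
#' @slot cnLoss copy-number loss cutoff (default -0.5).
#' @export
setClass("AberrationConfig",
         representation(zAbsCutoff = "numeric",
                        cnGain = "numeric",
                        cnLoss = "numeric"))

setValidity("AberrationConfig", function(object) {
  msg <- character()
  if (object@zAbsCutoff <= 0) msg <- c(msg, "zAbsCutoff must be positive")
  if (object@cnLoss >= object@cnGain)
    msg <- c(msg, "cnLoss must be below cnGain")
  if (length(msg)) msg else TRUE
})

#' @rdname AberrationConfig-class
#' @param zAbsCutoff,cnGain,cnLoss see slot documentation.
#' @return An `AberrationConfig`.
#' @export
aberrationConfig <- function(zAbsCutoff = 2.0, cnGain = 0.5, cnLoss = -0.5) {
  new("AberrationConfig", zAbsCutoff = zAbsCutoff,
      cnGain = cnGain, cnLoss = cnLoss)
}

#' Relation scoring configuration
#'
#' Parameters of the relation scoring scheme. Internal relations (from raw
#' data) start at `baseInternal`; linked relations (from external knowledge
#' sources) start at `baseLinked` scaled by the provider score, so internal
#' relations always rank at least as high at equal support. Every extra
#' distinct supporting patient beyond the first adds `frequencyBonus`.
#' Relations supported by strictly more than `trustedThreshold` distinct
#' patients are trusted; only trusted relations drive enrichment.
#'
#' @slot baseInternal base score of internal relations (default 1).
#' @slot baseLinked base score of linked relations (default 0.5).
#' @slot frequencyBonus per-extra-patient score increment (default 0.05).
#' @slot trustedThreshold strict distinct-patient support threshold
#'   (default 10: trusted means support > 10).
#' @export
setClass("ScoringConfig",
         representation(baseInternal = "numeric",
                        baseLinked = "numeric",
                        frequencyBonus = "numeric",
                        trustedThreshold = "integer"))

setValidity("ScoringConfig", function(object) {
  msg <- character()
  if (object@baseLinked <= 0 || object@baseInternal <= object@baseLinked)
    msg <- c(msg, "need baseInternal > baseLinked > 0")
  if (object@frequencyBonus < 0)
    msg <- c(msg, "frequencyBonus must be non-negative")
  if (object@trustedThreshold < 1L)
    msg <- c(msg, "trustedThreshold must be >= 1")
  if (length(msg)) msg else TRUE
})

#' @rdname ScoringConfig-class
#' @param baseInternal,baseLinked,frequencyBonus,trustedThreshold see slots.
#' @return A `ScoringConfig`.
#' @export
scoringConfig <- function(baseInternal = 1.0, baseLinked = 0.5,
                          frequencyBonus = 0.05, trustedThreshold = 10L) {
  new("ScoringConfig", baseInternal = baseInternal, baseLinked = baseLinked,
      frequencyBonus = frequencyBonus,
      trustedThreshold = as.integer(trustedThreshold))
}

#' Integrated patient-protein relation network
#'
#' The vertical-integration container: patient and protein nodes plus a
#' deduplicated table of typed, scored, origin-tagged relations. The
#' internal layer holds patient-protein edges from aberration calls and
#' patient-patient edges through shared trusted proteins; the linked layer
#' holds protein-protein edges imported from external knowledge sources.
#'
#' @slot patients patient node keys (sample ids).
#' @slot proteins protein node keys (Hugo symbols, uppercase).
#' @slot edges data.frame with columns source, target, kind, origin,
#'   frequency, score, trusted; unique on (source, target, kind).
#' @slot trustedThreshold strict support threshold used for trusted flags.
#' @export
setClass("IntegratedNetwork",
         representation(patients = "character",
                        proteins = "character",
                        edges = "data.frame",
                        trustedThreshold = "integer"))

setValidity("IntegratedNetwork", function(object) {
  e <- object@edges
  msg <- character()
  if (!identical(sort(colnames(e)), sort(EDGE_COLUMNS)))
    return(sprintf("edges must have columns %s",
                   paste(EDGE_COLUMNS, collapse = ", ")))
  if (nrow(e)) {
    if (!all(e$kind %in% RELATION_KINDS))
      msg <- c(msg, "unknown relation kind")
    if (any(e$origin == "linked" & e$kind != "protein_protein_linked"))
      msg <- c(msg, "origin 'linked' allowed only for protein_protein_linked")
    if (any(e$frequency < 1L))
      msg <- c(msg, "edge frequency must be >= 1")
    if (any(e$trusted & e$frequency <= object@trustedThreshold))
      msg <- c(msg, "trusted edges must have frequency > trustedThreshold")
    if (anyDuplicated(paste(e$source, e$target, e$kind, sep = "\r")))
      msg <- c(msg, "duplicate (source, target, kind) edge")
    pp <- e$kind %in% c("patient_protein_expr", "patient_protein_cnv")
    if (any(pp & (!e$source %in% object@patients |
                  !e$target %in% object@proteins)))
      msg <- c(msg, "patient_protein edges must run patient -> protein")
    ll <- e$kind == "protein_protein_linked"
    if (any(ll & (!e$source %in% object@proteins |
                  !e$target %in% object@proteins)))
      msg <- c(msg, "protein_protein_linked edges must join protein nodes")
    ss <- e$kind == "patient_patient_shared"
    if (any(ss & (!e$source %in% object@patients |
                  !e$target %in% object@patients)))
      msg <- c(msg, "patient_patient_shared edges must join patient nodes")
  }
  if (length(msg)) msg else TRUE
})

emptyEdgeTable <- function() {
  data.frame(source = character(), target = character(),
             kind = character(), origin = character(),
             frequency = integer(), score = numeric(),
             trusted = logical(), stringsAsFactors = FALSE)
}

#' Column-normalization state
#'
#' Mean and standard deviation stored at normalization time so that later
#' patients can be transformed consistently. A degenerate (constant) input
#' is flagged and mapped to zeros instead of dividing by zero.
#'
#' @slot mean,sd population mean and standard deviation.
#' @slot degenerate TRUE when the input was constant (sd = 0).
#' @export
setClass("NormalizationState",
         representation(mean = "numeric", sd = "numeric",
                        degenerate = "logical"))

setValidity("NormalizationState", function(object) {
  if (!object@degenerate && object@sd <= 0)
    "sd must be positive unless the input was degenerate"
  else TRUE
})

#' Per-cohort TICF table
#'
#' The Tumor Integrated Clinical Feature (TICF) of every patient for whom
#' tumor stage, tumor size (mm) and age at diagnosis (years) are all
#' available, with the normalized composite and the stratification group.
#'
#' @slot table data.frame with columns sampleId, stage, size, age,
#'   composite, normalized, group (one row per TICF-defined patient).
#' @slot state [NormalizationState-class] of the composite column.
#' @slot widths digit widths of (stage, size, age) in the composite.
#' @slot k number of stratification groups.
#' @export
setClass("TICFTable",
         representation(table = "data.frame",
                        state = "NormalizationState",
                        widths = "integer",
                        k = "integer"))

setValidity("TICFTable", function(object) {
  need <- c("sampleId", "stage", "size", "age",
            "composite", "normalized", "group")
  msg <- character()
  if (!all(need %in% colnames(object@table)))
    return(sprintf("table must have columns %s", paste(need, collapse = ", ")))
  if (anyDuplicated(object@table$sampleId))
    msg <- c(msg, "duplicate sampleId in TICF table")
  if (length(object@widths) != 3L || any(object@widths < 1L))
    msg <- c(msg, "widths must be three positive integers")
  if (length(msg)) msg else TRUE
})

#' Enriched per-patient cohort
#'
#' The dataset assembled around one studied (seed) patient: the seed's
#' TICF group (ring 0), patients reached through shared trusted proteins
#' (ring 1), patients reached through one hop of trusted linked
#' protein-protein relations (ring 2), the proteins used along the way
#' with their origin, and the resulting z-normalized feature matrix with
#' survival-month targets (NA where unknown).
#'
#' @slot seed the studied patient's sample id.
#' @slot ring0,ring1,ring2 pairwise-disjoint patient sets.
#' @slot proteinsUsed data.frame(protein, origin).
#' @slot featureMatrix numeric matrix, one row per cohort patient.
#' @slot targets named numeric vector of survival months (NA allowed).
#' @export
setClass("EnrichedCohort",
         representation(seed = "character",
                        ring0 = "character",
                        ring1 = "character",
                        ring2 = "character",
                        proteinsUsed = "data.frame",
                        featureMatrix = "matrix",
                        targets = "numeric"))

setValidity("EnrichedCohort", function(object) {
  msg <- character()
  if (!object@seed %in% object@ring0)
    msg <- c(msg, "seed must belong to ring0")
  if (length(intersect(object@ring0, object@ring1)) ||
      length(intersect(object@ring0, object@ring2)) ||
      length(intersect(object@ring1, object@ring2)))
    msg <- c(msg, "rings must be pairwise disjoint")
  n <- length(object@ring0) + length(object@ring1) + length(object@ring2)
  if (nrow(object@featureMatrix) != n)
    msg <- c(msg, "featureMatrix must have one row per cohort patient")
  if (length(object@targets) != n)
    msg <- c(msg, "targets must have one entry per cohort patient")
  if (length(msg)) msg else TRUE
})

#' Model specification for survival regression
#'
#' @slot family one of `"svr_rbf"`, `"svr_linear"`, `"svr_poly"`, `"dtr"`.
#' @slot hyperparameters named list (C, epsilon, gamma, degree, maxDepth
#'   as applicable to the family).
#' @slot seed RNG seed used when fitting.
#' @export
setClass("ModelSpec",
         representation(family = "character",
                        hyperparameters = "list",
                        seed = "integer"))

MODEL_FAMILIES <- c("svr_rbf", "svr_linear", "svr_poly", "dtr")

setValidity("ModelSpec", function(object) {
  if (length(object@family) != 1L || !object@family %in% MODEL_FAMILIES)
    sprintf("family must be one of %s", paste(MODEL_FAMILIES, collapse = ", "))
  else TRUE
})

#' Cross-validation report
#'
#' Mean and standard deviation over folds of four regression metrics
#' (r2, explained_variance, neg_mean_absolute_error,
#' neg_median_absolute_error), per model family, on the held-out fold and
#' separately on the training folds.
#'
#' @slot metrics data.frame(model, metric, split, mean, sd).
#' @slot k number of folds.
#' @slot n number of rows cross-validated.
#' @slot seed partition seed.
#' @slot folds named integer vector: fold assignment per row.
#' @export
setClass("CVReport",
         representation(metrics = "data.frame",
                        k = "integer",
                        n = "integer",
                        seed = "integer",
                        folds = "integer"))

setValidity("CVReport", function(object) {
  m <- object@metrics
  msg <- character()
  need <- c("model", "metric", "split", "mean", "sd")
  if (!all(need %in% colnames(m)))
    return(sprintf("metrics must have columns %s", paste(need, collapse = ", ")))
  tol <- 1e-8
  if (any(m$mean[m$metric %in% c("r2", "explained_variance")] > 1 + tol))
    msg <- c(msg, "r2 and explained variance cannot exceed 1")
  if (any(m$mean[grepl("^neg_", m$metric)] > tol))
    msg <- c(msg, "negative error metrics must be <= 0")
  if (any(m$sd < -tol)) msg <- c(msg, "metric SDs must be >= 0")
  if (length(msg)) msg else TRUE
})
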