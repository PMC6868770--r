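## External domain knowledge sources (EDKS): pluggable protein-protein
## relatedness providers, the relation scoring scheme, trusted-relation
## flags and pruning.

#' Offline EDKS fixture provider
#'
#' Reads a TSV relation table (`protein_a  protein_b  score  provider`)
#' standing in for GO/UniProt/Ensembl lookups. Relations are symmetric:
#' they are stored with a canonically ordered pair and can be queried from
#' either side. Self-relations are removed and duplicates collapse to
#' their maximum score.
#'
#' @slot relations data.frame(protein_a, protein_b, score, provider) with
#'   protein_a < protein_b.
#' @slot name provider label.
#' @export
setClass("EdksFixtureProvider",
         representation(relations = "data.frame", name = "character"))

#' @rdname EdksFixtureProvider-class
#' @param path TSV file with columns protein_a, protein_b, score, provider
#'   (header optional; extra columns ignored).
#' @param name provider label.
#' @return An `EdksFixtureProvider`.
#' @export
edksFixtureProvider <- function(path, name = "fixture") {
  first <- readLines(path, n = 1L, warn = FALSE)
  hasHeader <- grepl("protein_a", first, fixed = TRUE)
  tab <- utils::read.table(path, header = hasHeader, sep = "\t",
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "#")
  if (!hasHeader) {
    stopifnot(ncol(tab) >= 3L)
    colnames(tab)[1:3] <- c("protein_a", "protein_b", "score")
    if (ncol(tab) >= 4L) colnames(tab)[4L] <- "provider"
  }
  if (!"provider" %in% colnames(tab)) tab$provider <- name
  a <- toupper(trimws(tab$protein_a))
  b <- toupper(trimws(tab$protein_b))
  keep <- a != b
  rel <- data.frame(protein_a = pmin(a, b)[keep],
                    protein_b = pmax(a, b)[keep],
                    score = as.numeric(tab$score)[keep],
                    provider = as.character(tab$provider)[keep],
                    stringsAsFactors = FALSE)
  if (any(rel$score < 0 | rel$score > 1))
    stop("provider scores must lie in [0, 1]")
  ## duplicates collapse to the strongest reported association
  ord <- order(rel$protein_a, rel$protein_b, -rel$score)
  rel <- rel[ord, , drop = FALSE]
  rel <- rel[!duplicated(rel[, c("protein_a", "protein_b")]), , drop = FALSE]
  rownames(rel) <- NULL
  new("EdksFixtureProvider", relations = rel, name = name)
}

#' Query proteins related to a Hugo symbol
#'
#' @param provider an EDKS provider (offline fixture, or any class
#'   implementing this generic, e.g. an online REST client).
#' @param hugoSymbol query symbol (case-insensitive).
#' @return data.frame(partner, score, provider); empty for unknown symbols.
#' @export
setGeneric("fetchRelatedProteins", function(provider, hugoSymbol)
  standardGeneric("fetchRelatedProteins"))

#' @rdname fetchRelatedProteins
#' @export
setMethod("fetchRelatedProteins", "EdksFixtureProvider",
          function(provider, hugoSymbol) {
  q <- toupper(hugoSymbol)
  rel <- provider@relations
  hit <- rel$protein_a == q | rel$protein_b == q
  partner <- ifelse(rel$protein_a[hit] == q, rel$protein_b[hit],
                    rel$protein_a[hit])
  out <- data.frame(partner = partner, score = rel$score[hit],
                    provider = rel$provider[hit], stringsAsFactors = FALSE)
  out[order(out$partner), , drop = FALSE]
})

#' Online EDKS REST provider
#'
#' Minimal client for a JSON endpoint returning
#' `[{"partner": ..., "score": ...}, ...]` for
#' `GET <baseUrl>/<symbol>`. I/O failures are retried up to `maxRetries`
#' times with exponential backoff. Intended for interactive enrichment
#' against live services; the test suite and pipeline default to the
#' offline fixture provider.
#'
#' @slot baseUrl endpoint prefix.
#' @slot name provider label.
#' @slot maxRetries retry budget per query.
#' @export
setClass("EdksRestProvider",
         representation(baseUrl = "character", name = "character",
                        maxRetries = "integer"))

#' @rdname EdksRestProvider-class
#' @param baseUrl,name,maxRetries see slots.
#' @export
edksRestProvider <- function(baseUrl, name = "rest", maxRetries = 3L) {
  new("EdksRestProvider", baseUrl = sub("/$", "", baseUrl), name = name,
      maxRetries = as.integer(maxRetries))
}

#' @rdname fetchRelatedProteins
#' @export
setMethod("fetchRelatedProteins", "EdksRestProvider",
          function(provider, hugoSymbol) {
  q <- toupper(hugoSymbol)
  url <- paste0(provider@baseUrl, "/", utils::URLencode(q))
  for (attempt in seq_len(provider@maxRetries)) {
    res <- tryCatch(jsonlite::fromJSON(url), error = function(e) e)
    if (!inherits(res, "error")) {
      if (!length(res)) return(data.frame(partner = character(),
                                          score = numeric(),
                                          provider = character()))
      out <- data.frame(partner = toupper(res$partner),
                        score = as.numeric(res$score),
                        provider = provider@name, stringsAsFactors = FALSE)
      out <- out[out$partner != q, , drop = FALSE]
      return(out[!duplicated(out$partner), , drop = FALSE])
    }
    if (attempt == provider@maxRetries)
      stop("EDKS provider failure after ", attempt, " attempts: ",
           conditionMessage(res))
    Sys.sleep(2^(attempt - 1L) * 0.5)
  }
})

#' Score a relation
#'
#' Internal relations score `baseInternal + frequencyBonus * (f - 1)`;
#' linked relations score `baseLinked * providerScore +
#' frequencyBonus * (f - 1)`, where `f` is the number of distinct
#' supporting patients. The score is strictly increasing in `f` and an
#' internal relation never scores below a linked one at equal support.
#'
#' @param origin `"internal"` or `"linked"`.
#' @param frequency distinct-patient support, >= 1 (vectorized).
#' @param providerScore association score in \[0, 1\] (linked only).
#' @param cfg a [ScoringConfig-class].
#' @return numeric score(s).
#' @examples
#' scoreRelation("internal", 1)            # 1.0
#' scoreRelation("linked", 1, 1.0)         # 0.5
#' scoreRelation("internal", 11)           # 1.5
#' @export
scoreRelation <- function(origin = c("internal", "linked"), frequency,
                          providerScore = 1.0, cfg = scoringConfig()) {
  origin <- match.arg(origin)
  if (any(frequency < 1)) stop("frequency must be >= 1")
  base <- if (origin == "internal") cfg@baseInternal
          else cfg@baseLinked * providerScore
  base + cfg@frequencyBonus * (frequency - 1)
}

linkedEdgeSupport <- function(network, a, b) {
  length(unique(c(patientsByProtein(network, a),
                  patientsByProtein(network, b))))
}

#' Enrich a network with linked protein-protein relations
#'
#' Queries the EDKS provider for every protein node of the internal
#' layer and adds the returned relations as `protein_protein_linked`
#' edges (canonically ordered pairs, deduplicated). The support of a
#' linked relation is the number of distinct patients carrying either
#' endpoint internally; its score follows [scoreRelation()] and trusted
#' flags follow the strict support threshold.
#'
#' @param network an [IntegratedNetwork-class] with its internal layer.
#' @param provider an EDKS provider.
#' @param cfg a [ScoringConfig-class].
#' @return The network with the linked layer added.
#' @export
addLinkedRelations <- function(network, provider, cfg = scoringConfig()) {
  seen <- character()
  rows <- list()
  for (p in network@proteins) {
    rel <- fetchRelatedProteins(provider, p)
    if (!nrow(rel)) next
    for (i in seq_len(nrow(rel))) {
      a <- min(p, rel$partner[i]); b <- max(p, rel$partner[i])
      key <- paste(a, b, sep = "\r")
      if (key %in% seen) next
      seen <- c(seen, key)
      support <- linkedEdgeSupport(network, a, b)
      rows[[key]] <- data.frame(
        source = a, target = b, kind = "protein_protein_linked",
        origin = "linked", frequency = max(1L, support),
        score = scoreRelation("linked", max(1L, support), rel$score[i], cfg),
        trusted = support > cfg@trustedThreshold,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows)) {
    linked <- do.call(rbind, rows)
    rownames(linked) <- NULL
    network@edges <- rbind(network@edges, linked[, EDGE_COLUMNS])
    network@proteins <- sort(unique(c(network@proteins, linked$source,
                                      linked$target)))
  }
  validObject(network)
  network
}

#' Set trusted flags on every relation
#'
#' A relation is trusted exactly when its distinct-patient support
#' (frequency) strictly exceeds the threshold ("more than" is read
#' strictly: support 10 at threshold 10 is not trusted, 11 is).
#' Idempotent.
#'
#' @param network an [IntegratedNetwork-class].
#' @param cfg a [ScoringConfig-class]; its `trustedThreshold` is applied.
#' @return The network with trusted flags recomputed.
#' @export
markTrusted <- function(network, cfg = scoringConfig()) {
  network@edges$trusted <- network@edges$frequency > cfg@trustedThreshold
  network@trustedThreshold <- cfg@trustedThreshold
  network
}

#' Prune untrusted linked relations
#'
#' Removes linked protein-protein edges that are not trusted. Internal
#' patient-protein edges are never removed (raw data are never
#' discarded); untrusted internal edges are simply ignored by the
#' enrichment traversal. Idempotent.
#'
#' @param network an [IntegratedNetwork-class] with trusted flags set.
#' @return The pruned network.
#' @export
pruneUntrusted <- function(network) {
  e <- network@edges
  drop <- e$kind == "protein_protein_linked" & !e$trusted
  network@edges <- e[!drop, , drop = FALSE]
  rownames(network@edges) <- NULL
  network
}
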