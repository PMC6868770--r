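## Vertical integration: aberration calls over molecular documents,
## patient-protein relation edges, patient-patient links through shared
## trusted proteins, and GraphML/TSV persistence.

#' Per-study cohort statistics for expression z-scoring
#'
#' Expression aberrations are defined relative to the cohort the profile
#' was measured in, so mean and standard deviation are computed per
#' protein within each source study.
#'
#' @param documents expression documents (from [applySchema()]).
#' @return named list, one entry per study, each with named numeric
#'   vectors `mean` and `sd` (sample SD) per protein.
#' @export
cohortExpressionStats <- function(documents) {
  documents <- Filter(function(d) identical(d$data_type, "expression"),
                      documents)
  byStudy <- split(documents, vapply(documents, function(d)
    as.character(d$source_study), character(1L)))
  lapply(byStudy, function(docs) {
    vals <- list()
    for (d in docs) {
      for (p in names(d$fields)) {
        v <- suppressWarnings(as.numeric(d$fields[[p]]))
        if (!is.na(v)) vals[[p]] <- c(vals[[p]], v)
      }
    }
    list(mean = vapply(vals, mean, numeric(1L)),
         sd = vapply(vals, stats::sd, numeric(1L)))
  })
}

#' Call aberrant proteins for one molecular document
#'
#' Expression: a protein is aberrant when its cohort z-score magnitude
#' reaches `config@zAbsCutoff` (a zero-variance protein is never
#' aberrant). Copy number: aberrant when the value reaches `config@cnGain`
#' or falls to `config@cnLoss`. Non-numeric values are skipped with a
#' warning.
#'
#' @param document an expression or cnv document.
#' @param config an [AberrationConfig-class].
#' @param stats for expression documents, the per-study statistics from
#'   [cohortExpressionStats()].
#' @return sorted character vector of aberrant Hugo symbols.
#' @export
callAberrantProteins <- function(document, config = aberrationConfig(),
                                 stats = NULL) {
  fields <- document$fields
  if (!length(fields)) return(character())
  vals <- suppressWarnings(vapply(fields, function(v)
    as.numeric(v[[1L]]), numeric(1L)))
  bad <- is.na(vals)
  if (any(bad))
    warning(sprintf("skipping %d non-numeric value(s) in record %s",
                    sum(bad), document$record_id))
  vals <- vals[!bad]
  proteins <- toupper(names(vals))
  if (identical(document$data_type, "expression")) {
    st <- stats[[as.character(document$source_study)]]
    if (is.null(st))
      stop("no cohort statistics for study ", document$source_study)
    mu <- st$mean[proteins]
    sdv <- st$sd[proteins]
    ok <- !is.na(sdv) & sdv > 0
    z <- rep(0, length(vals))
    z[ok] <- (vals[ok] - mu[ok]) / sdv[ok]
    sort(unique(proteins[abs(z) >= config@zAbsCutoff]))
  } else if (identical(document$data_type, "cnv")) {
    sort(unique(proteins[vals >= config@cnGain | vals <= config@cnLoss]))
  } else {
    stop("aberration calling applies to expression or cnv documents")
  }
}

#' Build the internal patient-protein relation layer
#'
#' Creates one patient node per distinct sample id across all documents,
#' one patient-to-protein edge per aberration call (kind follows the data
#' type), assigns every protein edge a frequency equal to the number of
#' distinct patients carrying that protein, scores and flags trusted
#' edges, and adds patient-patient edges between patients sharing at
#' least one trusted protein (weighted by the number of shared trusted
#' proteins). Molecular records whose sample id has no clinical record
#' are kept as orphan patient nodes (reported via message).
#'
#' @param documents all documents (clinical + molecular).
#' @param config an [AberrationConfig-class].
#' @param scoring a [ScoringConfig-class].
#' @return An [IntegratedNetwork-class].
#' @export
buildInternalNetwork <- function(documents, config = aberrationConfig(),
                                 scoring = scoringConfig()) {
  types <- vapply(documents, function(d) as.character(d$data_type),
                  character(1L))
  samples <- vapply(documents, function(d) as.character(d$sample_id),
                    character(1L))
  patients <- sort(unique(samples))
  clinicalSamples <- unique(samples[types == "clinical"])
  orphans <- setdiff(unique(samples[types != "clinical"]), clinicalSamples)
  if (length(orphans))
    message(sprintf(
      "%d molecular sample(s) without a clinical record kept as orphan patient nodes",
      length(orphans)))

  exprStats <- cohortExpressionStats(documents[types == "expression"])
  src <- character(); tgt <- character(); kind <- character()
  for (i in which(types %in% c("expression", "cnv"))) {
    d <- documents[[i]]
    ab <- callAberrantProteins(d, config, stats = exprStats)
    if (length(ab)) {
      src <- c(src, rep(as.character(d$sample_id), length(ab)))
      tgt <- c(tgt, ab)
      kind <- c(kind, rep(if (types[i] == "expression") "patient_protein_expr"
                          else "patient_protein_cnv", length(ab)))
    }
  }
  edges <- emptyEdgeTable()
  if (length(src)) {
    e <- unique(data.frame(source = src, target = tgt, kind = kind,
                           stringsAsFactors = FALSE))
    ## frequency: distinct patients carrying the protein (any molecular kind)
    support <- tapply(e$source, e$target, function(s) length(unique(s)))
    freq <- as.integer(support[e$target])
    e$origin <- "internal"
    e$frequency <- freq
    e$score <- scoreRelation("internal", freq, cfg = scoring)
    e$trusted <- freq > scoring@trustedThreshold
    edges <- e[, EDGE_COLUMNS]

    ## patient-patient links through shared trusted proteins
    trustedProteins <- names(support)[support > scoring@trustedThreshold]
    if (length(trustedProteins)) {
      pairKeys <- character()
      for (p in trustedProteins) {
        carriers <- sort(unique(e$source[e$target == p]))
        if (length(carriers) >= 2L) {
          cmb <- utils::combn(carriers, 2L)
          pairKeys <- c(pairKeys, paste(cmb[1L, ], cmb[2L, ], sep = "\r"))
        }
      }
      if (length(pairKeys)) {
        counts <- table(pairKeys)
        parts <- strsplit(names(counts), "\r", fixed = TRUE)
        shared <- data.frame(
          source = vapply(parts, `[[`, character(1L), 1L),
          target = vapply(parts, `[[`, character(1L), 2L),
          kind = "patient_patient_shared", origin = "internal",
          frequency = as.integer(counts),
          score = as.numeric(counts),
          trusted = as.integer(counts) > scoring@trustedThreshold,
          stringsAsFactors = FALSE)
        edges <- rbind(edges, shared[, EDGE_COLUMNS])
      }
    }
  }
  rownames(edges) <- NULL
  new("IntegratedNetwork",
      patients = patients,
      proteins = sort(unique(edges$target[edges$kind %in%
        c("patient_protein_expr", "patient_protein_cnv")])),
      edges = edges,
      trustedThreshold = scoring@trustedThreshold)
}

#' Patients carrying a protein
#'
#' All patients with an internal patient-protein edge to the given
#' protein; an absent protein yields the empty set.
#'
#' @param network an [IntegratedNetwork-class].
#' @param protein Hugo symbol (case-insensitive).
#' @return character vector of patient keys.
#' @export
patientsByProtein <- function(network, protein) {
  protein <- toupper(protein)
  e <- network@edges
  sel <- e$kind %in% c("patient_protein_expr", "patient_protein_cnv") &
    e$target == protein
  sort(unique(e$source[sel]))
}

trustedProteinsOf <- function(network, patients) {
  e <- network@edges
  sel <- e$kind %in% c("patient_protein_expr", "patient_protein_cnv") &
    e$trusted & e$source %in% patients
  sort(unique(e$target[sel]))
}

#' Export / import an integrated network
#'
#' Two formats are supported: `"graphml"` (via igraph; node type and all
#' edge attributes preserved) and `"tsv"` (canonical edge list sorted by
#' source, target, kind, with node sets carried in `#`-prefixed header
#' lines so isolated nodes survive the round trip). Import of an exported
#' file reproduces the edge multiset exactly.
#'
#' @param network an [IntegratedNetwork-class].
#' @param path output file.
#' @param format `"graphml"` or `"tsv"`.
#' @return `exportNetwork` returns `path` invisibly; `importNetwork`
#'   returns the reconstructed [IntegratedNetwork-class].
#' @export
exportNetwork <- function(network, path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  e <- network@edges
  ord <- order(e$source, e$target, e$kind)
  e <- e[ord, , drop = FALSE]
  if (format == "tsv") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(
      sprintf("#trusted_threshold=%d", network@trustedThreshold),
      sprintf("#patients=%s", paste(network@patients, collapse = ",")),
      sprintf("#proteins=%s", paste(network@proteins, collapse = ","))), con)
    utils::write.table(e, con, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    nodes <- data.frame(
      name = c(network@patients, network@proteins),
      type = c(rep("patient", length(network@patients)),
               rep("protein", length(network@proteins))),
      stringsAsFactors = FALSE)
    extra <- setdiff(unique(c(e$source, e$target)), nodes$name)
    if (length(extra))
      nodes <- rbind(nodes, data.frame(name = extra, type = "protein"))
    g <- igraph::graph_from_data_frame(
      transform(e, trusted = as.integer(trusted)),
      directed = TRUE, vertices = nodes)
    g <- igraph::set_graph_attr(g, "trusted_threshold",
                                network@trustedThreshold)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' @rdname exportNetwork
#' @export
importNetwork <- function(path, format = c("tsv", "graphml")) {
  format <- match.arg(format)
  if (format == "tsv") {
    lines <- readLines(path, warn = FALSE)
    meta <- lines[startsWith(lines, "#")]
    getMeta <- function(key) {
      ln <- meta[startsWith(meta, paste0("#", key, "="))]
      if (!length(ln)) return(character())
      val <- sub("^#[^=]*=", "", ln[1L])
      if (!nzchar(val)) character()
      else strsplit(val, ",", fixed = TRUE)[[1L]]
    }
    thr <- as.integer(getMeta("trusted_threshold"))
    body <- lines[!startsWith(lines, "#")]
    e <- if (length(body) > 1L)
      utils::read.table(text = body, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE,
                        colClasses = c("character", "character", "character",
                                       "character", "integer", "numeric",
                                       "logical"))
    else emptyEdgeTable()
    new("IntegratedNetwork", patients = getMeta("patients"),
        proteins = getMeta("proteins"), edges = e[, EDGE_COLUMNS],
        trustedThreshold = if (length(thr)) thr else 10L)
  } else {
    g <- igraph::read_graph(path, format = "graphml")
    vs <- igraph::vertex_attr(g)
    e <- igraph::as_data_frame(g, what = "edges")
    colnames(e)[1:2] <- c("source", "target")
    if (nrow(e)) {
      e$frequency <- as.integer(e$frequency)
      e$trusted <- as.logical(as.integer(e$trusted))
      e <- e[, EDGE_COLUMNS]
    } else e <- emptyEdgeTable()
    new("IntegratedNetwork",
        patients = sort(as.character(vs$name[vs$type == "patient"])),
        proteins = sort(as.character(vs$name[vs$type == "protein"])),
        edges = e,
        trustedThreshold =
          as.integer(igraph::graph_attr(g, "trusted_threshold")))
  }
}
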