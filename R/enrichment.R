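## Per-patient cohort enrichment: the studied patient's TICF group
## (ring 0), internal expansion through shared trusted proteins (ring 1),
## one hop of trusted linked relations (ring 2), and the deduplicated,
## renormalized feature matrix.

#' Ring 0: the seed patient's TICF group
#'
#' @param seed the studied patient's sample id.
#' @param ticf a [TICFTable-class].
#' @return sorted character vector of the seed's group members (seed
#'   included).
#' @export
seedGroup <- function(seed, ticf) {
  tab <- ticf@table
  gi <- tab$group[match(seed, tab$sampleId)]
  if (is.na(gi))
    stop("patient '", seed,
         "' has no defined TICF and cannot seed an enrichment")
  sort(tab$sampleId[tab$group == gi])
}

#' Ring 1: patients reached through shared trusted proteins
#'
#' Collects the trusted proteins carried by the ring-0 patients and
#' returns every other patient carrying any of them.
#'
#' @param ring0 ring-0 patient set.
#' @param network an [IntegratedNetwork-class] with trusted flags set.
#' @return sorted character vector, disjoint from `ring0`.
#' @export
expandInternal <- function(ring0, network) {
  prots <- trustedProteinsOf(network, ring0)
  if (!length(prots)) return(character())
  carriers <- unique(unlist(lapply(prots, patientsByProtein,
                                   network = network)))
  sort(setdiff(carriers, ring0))
}

#' Ring 2: patients reached through trusted linked relations
#'
#' Takes the trusted proteins of the cohort so far, follows trusted
#' linked protein-protein edges (the scoring mechanism has already
#' pruned redundant linked relations) one hop to partner proteins, and
#' returns the partners' carrier patients outside the cohort.
#'
#' @param ring01 union of rings 0 and 1.
#' @param network an [IntegratedNetwork-class] with the linked layer.
#' @return list with `ring2` (sorted, disjoint from `ring01`) and
#'   `linkedProteins` (the partner proteins traversed).
#' @export
expandLinked <- function(ring01, network) {
  prots <- trustedProteinsOf(network, ring01)
  e <- network@edges
  ll <- e$kind == "protein_protein_linked" & e$trusted &
    (e$source %in% prots | e$target %in% prots)
  partners <- setdiff(unique(c(e$source[ll], e$target[ll])), prots)
  if (!length(partners)) return(list(ring2 = character(),
                                     linkedProteins = character()))
  carriers <- unique(unlist(lapply(partners, patientsByProtein,
                                   network = network)))
  list(ring2 = sort(setdiff(carriers, ring01)),
       linkedProteins = sort(partners))
}

#' Assemble the enriched feature matrix and survival targets
#'
#' Builds per-patient numeric features for a cohort: the normalized TICF
#' (or, alternatively, the separate stage/size/age columns) plus one
#' binary carrier indicator per protein, then z-normalizes every column
#' (constant columns map to zeros). Patients reached through the rings
#' without a defined TICF stay in the matrix with the clinical columns
#' imputed to 0, i.e. the post-normalization cohort mean. Targets are
#' survival months; NA where unknown.
#'
#' @param patients cohort sample ids (unique).
#' @param ticf a [TICFTable-class].
#' @param network an [IntegratedNetwork-class].
#' @param documents all documents (for survival targets).
#' @param proteins proteins to encode as indicator columns.
#' @param clinicalFeatures `"composite"` (the TICF column),
#'   `"separate"` (stage, size, age columns) or `"none"`.
#' @return list with `featureMatrix` (rows in `patients` order) and
#'   `targets` (named numeric).
#' @export
assembleFeatures <- function(patients, ticf, network, documents,
                             proteins = character(),
                             clinicalFeatures = c("composite", "separate",
                                                  "none")) {
  clinicalFeatures <- match.arg(clinicalFeatures)
  stopifnot(!anyDuplicated(patients))
  tab <- ticf@table
  idx <- match(patients, tab$sampleId)

  cols <- list()
  if (clinicalFeatures == "composite") {
    cols$ticf <- ifelse(is.na(idx), NA_real_, tab$normalized[idx])
  } else if (clinicalFeatures == "separate") {
    cols$stage <- ifelse(is.na(idx), NA_real_, as.numeric(tab$stage[idx]))
    cols$size <- ifelse(is.na(idx), NA_real_, as.numeric(tab$size[idx]))
    cols$age <- ifelse(is.na(idx), NA_real_, as.numeric(tab$age[idx]))
  }
  for (p in proteins) {
    carriers <- patientsByProtein(network, p)
    cols[[paste0("prot_", p)]] <- as.numeric(patients %in% carriers)
  }
  if (!length(cols))
    stop("no features requested: need clinical features or proteins")
  mat <- vapply(cols, function(col) {
    obs <- !is.na(col)
    if (!any(obs)) return(numeric(length(col)))
    ## impute at the observed mean, then z-normalize the whole column:
    ## imputed entries land exactly at the post-normalization mean (0)
    col[!obs] <- mean(col[obs])
    normalizeValues(col)$normalized
  }, numeric(length(patients)))
  if (length(patients) == 1L) mat <- matrix(mat, nrow = 1L,
                                            dimnames = list(NULL, names(cols)))
  rownames(mat) <- patients

  cl <- clinicalVariables(documents)
  targets <- stats::setNames(cl$survivalMonths[match(patients, cl$sampleId)],
                             patients)
  if (sum(!is.na(targets)) < 2L)
    stop("insufficient cohort: fewer than 2 patients carry a survival target")
  list(featureMatrix = mat, targets = targets)
}

#' Enrich the cohort of a studied patient
#'
#' Runs the full per-patient enrichment: ring 0 (TICF group), ring 1
#' (internal expansion), ring 2 (linked expansion), and feature
#' assembly. With `expand = FALSE` the cohort is ring 0 only and no
#' protein indicators are used (the no-network configuration).
#'
#' @param seed the studied patient's sample id.
#' @param network an [IntegratedNetwork-class] (trusted flags set, linked
#'   layer pruned).
#' @param ticf a [TICFTable-class].
#' @param documents all documents.
#' @param clinicalFeatures passed to [assembleFeatures()].
#' @param expand run the network expansion (default TRUE).
#' @return An [EnrichedCohort-class].
#' @export
enrichCohort <- function(seed, network, ticf, documents,
                         clinicalFeatures = "composite", expand = TRUE) {
  ring0 <- seedGroup(seed, ticf)
  if (expand) {
    ring1 <- expandInternal(ring0, network)
    lk <- expandLinked(c(ring0, ring1), network)
    ring2 <- lk$ring2
    internalProts <- trustedProteinsOf(network, c(ring0, ring1))
    proteinsUsed <- data.frame(
      protein = c(internalProts, lk$linkedProteins),
      origin = c(rep("internal", length(internalProts)),
                 rep("linked", length(lk$linkedProteins))),
      stringsAsFactors = FALSE)
  } else {
    ring1 <- character()
    ring2 <- character()
    proteinsUsed <- data.frame(protein = character(), origin = character(),
                               stringsAsFactors = FALSE)
  }
  patients <- c(ring0, ring1, ring2)
  fm <- assembleFeatures(patients, ticf, network, documents,
                         proteins = proteinsUsed$protein,
                         clinicalFeatures = clinicalFeatures)
  new("EnrichedCohort", seed = seed, ring0 = ring0, ring1 = ring1,
      ring2 = ring2, proteinsUsed = proteinsUsed,
      featureMatrix = fm$featureMatrix, targets = fm$targets)
}
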