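#' @rdname SemiStructure-class
#' @param object a `SemiStructure`.
#' @export
setGeneric("fieldStats", function(object) standardGeneric("fieldStats"))

#' @rdname SemiStructure-class
#' @export
setGeneric("recordCount", function(object) standardGeneric("recordCount"))

#' @rdname SemiStructure-class
#' @export
setGeneric("dataType", function(object) standardGeneric("dataType"))

#' @rdname IntegratedNetwork-class
#' @param object an `IntegratedNetwork`.
#' @export
setGeneric("patientNodes", function(object) standardGeneric("patientNodes"))

#' @rdname IntegratedNetwork-class
#' @export
setGeneric("proteinNodes", function(object) standardGeneric("proteinNodes"))

#' @rdname IntegratedNetwork-class
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))

#' @rdname IntegratedNetwork-class
#' @export
setGeneric("trustedThreshold",
           function(object) standardGeneric("trustedThreshold"))

#' @rdname TICFTable-class
#' @param object a `TICFTable`.
#' @export
setGeneric("ticfValues", function(object) standardGeneric("ticfValues"))

#' @rdname TICFTable-class
#' @export
setGeneric("normalizationState",
           function(object) standardGeneric("normalizationState"))

#' @rdname EnrichedCohort-class
#' @param object an `EnrichedCohort`.
#' @param ring which ring to return: 0, 1, 2 or `"all"`.
#' @export
setGeneric("ringPatients",
           function(object, ring = "all") standardGeneric("ringPatients"))

#' @rdname EnrichedCohort-class
#' @export
setGeneric("featureMatrix", function(object) standardGeneric("featureMatrix"))

#' @rdname EnrichedCohort-class
#' @export
setGeneric("survivalTargets",
           function(object) standardGeneric("survivalTargets"))

#' @rdname CVReport-class
#' @param object a `CVReport`.
#' @export
setGeneric("cvMetrics", function(object) standardGeneric("cvMetrics"))

#' @rdname CVReport-class
#' @export
setGeneric("foldAssignment", function(object) standardGeneric("foldAssignment"))

setMethod("fieldStats", "SemiStructure", function(object) object@fieldStats)
setMethod("recordCount", "SemiStructure", function(object) object@recordCount)
setMethod("dataType", "SemiStructure", function(object) object@dataType)

setMethod("patientNodes", "IntegratedNetwork", function(object) object@patients)
setMethod("proteinNodes", "IntegratedNetwork", function(object) object@proteins)
setMethod("networkEdges", "IntegratedNetwork", function(object) object@edges)
setMethod("trustedThreshold", "IntegratedNetwork",
          function(object) object@trustedThreshold)

setMethod("ticfValues", "TICFTable", function(object) object@table)
setMethod("normalizationState", "TICFTable", function(object) object@state)

setMethod("ringPatients", "EnrichedCohort", function(object, ring = "all") {
  switch(as.character(ring),
         "0" = object@ring0,
         "1" = object@ring1,
         "2" = object@ring2,
         "all" = c(object@ring0, object@ring1, object@ring2),
         stop("ring must be 0, 1, 2 or 'all'"))
})
setMethod("featureMatrix", "EnrichedCohort",
          function(object) object@featureMatrix)
setMethod("survivalTargets", "EnrichedCohort", function(object) object@targets)

setMethod("cvMetrics", "CVReport", function(object) object@metrics)
setMethod("foldAssignment", "CVReport", function(object) object@folds)

setMethod("show", "SemiStructure", function(object) {
  cat(sprintf("SemiStructure of data type '%s': %d records, %d fields\n",
              object@dataType, object@recordCount, length(object@fieldStats)))
  if (length(object@fieldStats)) {
    top <- sort(object@fieldStats, decreasing = TRUE)
    top <- top[seq_len(min(6L, length(top)))]
    cat("  top fields:",
        paste(sprintf("%s(%d)", names(top), top), collapse = " "), "\n")
  }
})

setMethod("show", "IntegratedNetwork", function(object) {
  e <- object@edges
  cat(sprintf("IntegratedNetwork: %d patients, %d proteins, %d relations\n",
              length(object@patients), length(object@proteins), nrow(e)))
  if (nrow(e)) {
    tab <- table(e$kind)
    for (k in names(tab))
      cat(sprintf("  %-24s %6d  (%d trusted)\n", k, tab[[k]],
                  sum(e$trusted[e$kind == k])))
  }
  cat(sprintf("  trusted threshold: support > %d distinct patients\n",
              object@trustedThreshold))
})

setMethod("show", "TICFTable", function(object) {
  cat(sprintf("TICFTable: %d patients with a defined TICF, %d groups\n",
              nrow(object@table), object@k))
  if (object@state@degenerate)
    cat("  normalization degenerate (constant composite)\n")
})

setMethod("show", "EnrichedCohort", function(object) {
  cat(sprintf(
    "EnrichedCohort for seed '%s': ring0 %d, ring1 %d, ring2 %d patients\n",
    object@seed, length(object@ring0), length(object@ring1),
    length(object@ring2)))
  cat(sprintf("  %d proteins used, %d features, %d/%d patients with targets\n",
              nrow(object@proteinsUsed), ncol(object@featureMatrix),
              sum(!is.na(object@targets)), length(object@targets)))
})

setMethod("show", "CVReport", function(object) {
  cat(sprintf("CVReport: %d-fold cross-validation on %d rows (seed %d)\n",
              object@k, object@n, object@seed))
  m <- object@metrics[object@metrics$split == "test", ]
  for (fam in unique(m$model)) {
    r <- m[m$model == fam, ]
    cat(sprintf("  %-11s %s\n", fam,
                paste(sprintf("%s %.3f±%.3f", r$metric, r$mean, r$sd),
                      collapse = "  ")))
  }
})
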