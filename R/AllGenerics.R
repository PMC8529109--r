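#' @rdname LinkedProfile-class
#' @param object,x a `LinkedProfile`.
#' @export
setGeneric("profileRecords", function(object) standardGeneric("profileRecords"))

#' @rdname LinkedProfile-class
#' @export
setGeneric("sampleIds", function(object) standardGeneric("sampleIds"))

#' @rdname LinkedProfile-class
#' @export
setGeneric("taxonomyMap", function(object) standardGeneric("taxonomyMap"))

#' @rdname LinkedProfile-class
#' @export
setGeneric("functionMap", function(object) standardGeneric("functionMap"))

#' @rdname AbundanceTable-class
#' @param object an `AbundanceTable`.
#' @export
setGeneric("tableKind", function(object) standardGeneric("tableKind"))

#' @rdname AbundanceTable-class
#' @export
setGeneric("tableLevel", function(object) standardGeneric("tableLevel"))

#' @rdname AbundanceTable-class
#' @export
setGeneric("isRelative", function(object) standardGeneric("isRelative"))

#' @rdname PermanovaResult-class
#' @param object a result object.
#' @export
setGeneric("pseudoF", function(object) standardGeneric("pseudoF"))

#' @rdname PermanovaResult-class
#' @export
setGeneric("pValue", function(object) standardGeneric("pValue"))

#' @rdname PermanovaResult-class
#' @export
setGeneric("varianceExplained", function(object) standardGeneric("varianceExplained"))

#' @rdname PcoaResult-class
#' @param object a `PcoaResult`.
#' @export
setGeneric("pcoaScores", function(object) standardGeneric("pcoaScores"))

#' @rdname NetworkResult-class
#' @param object a `NetworkResult`.
#' @export
setGeneric("networkIndexes", function(object) standardGeneric("networkIndexes"))

#' @rdname NetworkResult-class
#' @export
setGeneric("networkEdges", function(object) standardGeneric("networkEdges"))

#' @rdname NetworkResult-class
#' @export
setGeneric("networkNodes", function(object) standardGeneric("networkNodes"))

setMethod("profileRecords", "LinkedProfile", function(object) object@records)
setMethod("sampleIds", "LinkedProfile", function(object) object@samples)
setMethod("taxonomyMap", "LinkedProfile", function(object) object@taxonomyMap)
setMethod("functionMap", "LinkedProfile", function(object) object@functionMap)

setMethod("tableKind", "AbundanceTable", function(object) object@kind)
setMethod("tableLevel", "AbundanceTable", function(object) object@level)
setMethod("isRelative", "AbundanceTable", function(object) object@relative)

setMethod("pseudoF", "PermanovaResult", function(object) object@pseudoF)
setMethod("pValue", "PermanovaResult", function(object) object@p)
setMethod("varianceExplained", "PermanovaResult", function(object) object@R2)
setMethod("pValue", "CorrelationResult", function(object) object@p)

setMethod("pcoaScores", "PcoaResult", function(object) object@coordinates)

setMethod("networkIndexes", "NetworkResult", function(object) object@indexes)
setMethod("networkEdges", "NetworkResult", function(object) object@edges)
setMethod("networkNodes", "NetworkResult", function(object) object@nodes)

setMethod("show", "LinkedProfile", function(object) {
  rec <- object@records
  cat("LinkedProfile:", length(object@samples), "samples,",
      length(unique(rec$genus)), "genera in",
      length(unique(rec$phylum)), "phyla,",
      nrow(object@functionMap), "functions\n")
  cat("  records:", nrow(rec), " total hits:",
      format(sum(rec$hits), big.mark = ","), "\n")
})

setMethod("show", "AbundanceTable", function(object) {
  cat(sprintf("AbundanceTable (%s/%s, %s): %d samples x %d features\n",
              object@kind, object@level,
              if (object@relative) "relative abundance" else "counts",
              nrow(object), ncol(object)))
})

setMethod("show", "LossLevel", function(object) {
  cat(sprintf("LossLevel '%s': %d phyla retained\n",
              object@name, length(object@retainedPhyla)))
})

setMethod("show", "PermanovaResult", function(object) {
  cat(sprintf(
    "PERMANOVA: pseudo-F = %.4g on df (%d, %d), R2 = %.4f, p = %.4g (%d permutations)\n",
    object@pseudoF, object@dfBetween, object@dfWithin,
    object@R2, object@p, object@nPermutations))
})

setMethod("show", "CorrelationResult", function(object) {
  cat(sprintf("Pearson correlation: r = %.4f (r2 = %.4f), p = %.4g, n = %d\n",
              object@r, object@r2, object@p, object@n))
})

setMethod("show", "PcoaResult", function(object) {
  k <- min(2L, ncol(object@coordinates))
  cat(sprintf("PCoA: %d samples, %d axes returned; PCo1..%d explain %s%%\n",
              nrow(object@coordinates), ncol(object@coordinates), k,
              paste(sprintf("%.1f", object@percentVariation[seq_len(k)]),
                    collapse = " / ")))
})

setMethod("show", "NetworkResult", function(object) {
  ix <- object@indexes
  cat(sprintf(
    "Co-occurrence network (S_t = %.2f): %d nodes, %d links (%.1f%% negative)\n",
    object@st, ix[["total_nodes"]], ix[["total_links"]],
    ix[["pct_negative_links"]]))
  cat(sprintf(
    "  avg connectivity %.3f | clustering %.3f | geodesic %.3f | modularity %.3f | %d component(s)\n",
    ix[["avg_connectivity"]], ix[["avg_clustering_coefficient"]],
    ix[["avg_geodesic_distance"]], ix[["modularity"]], object@nComponents))
})

setMethod("show", "LossSeriesReport", function(object) {
  cat("Loss-series report over", length(object@tables), "levels\n")
  print(object@summary, row.names = FALSE)
})

setMethod("show", "SyntheticConfig", function(object) {
  cat(sprintf(
    "SyntheticConfig: %d samples, %d phyla x %d genera, %d functions\n",
    object@nSamples, object@nPhyla, object@generaPerPhylum, object@nFunctions))
  cat(sprintf(
    "  redundancy %.2f | phylum decay %.2f | depth %g | dispersion %.2f | seed %d\n",
    object@redundancy, object@phylumDecay, object@depth, object@dispersion,
    object@seed))
})
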