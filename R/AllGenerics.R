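#' @include AllClasses.R
NULL

#' Accessors for seedcoex objects
#'
#' Small accessor layer over the package's S4 containers; user code should use
#' these rather than reaching into slots.
#'
#' @param x an object of the documented class.
#' @param ... unused.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("geneUniverse", function(x) standardGeneric("geneUniverse"))
#' @rdname accessors
#' @export
setMethod("geneUniverse", "Compendium", function(x) x@geneUniverse)
#' @rdname accessors
#' @export
setMethod("geneUniverse", "SimTruth", function(x) names(x@moduleMembership))

#' @rdname accessors
#' @export
setGeneric("datasets", function(x) standardGeneric("datasets"))
#' @rdname accessors
#' @export
setMethod("datasets", "Compendium", function(x) x@datasets)

#' @rdname accessors
#' @export
setGeneric("nDatasets", function(x) standardGeneric("nDatasets"))
#' @rdname accessors
#' @export
setMethod("nDatasets", "Compendium", function(x) length(x@datasets))

#' @rdname accessors
#' @export
setGeneric("seedId", function(x) standardGeneric("seedId"))
#' @rdname accessors
#' @export
setMethod("seedId", "CorrelateList", function(x) x@seedId)

#' @rdname accessors
#' @export
setGeneric("entries", function(x) standardGeneric("entries"))
#' @rdname accessors
#' @export
setMethod("entries", "CorrelateList", function(x) x@entries)
#' @rdname accessors
#' @export
setMethod("entries", "RankedMasterList", function(x) x@entries)

#' @rdname accessors
#' @export
setGeneric("eligible", function(x) standardGeneric("eligible"))
#' @rdname accessors
#' @export
setMethod("eligible", "CorrelateList", function(x) x@eligible)

#' @rdname accessors
#' @export
setGeneric("networkNodes", function(x) standardGeneric("networkNodes"))
#' @rdname accessors
#' @export
setMethod("networkNodes", "SeedNetwork", function(x) x@nodes)

#' @rdname accessors
#' @export
setGeneric("networkEdges", function(x) standardGeneric("networkEdges"))
#' @rdname accessors
#' @export
setMethod("networkEdges", "SeedNetwork", function(x) x@edges)

#' @rdname accessors
#' @export
setGeneric("maxES", function(x) standardGeneric("maxES"))
#' @rdname accessors
#' @export
setMethod("maxES", "EnrichmentProfile", function(x) x@maxES)

#' @rdname accessors
#' @export
setGeneric("maxPosition", function(x) standardGeneric("maxPosition"))
#' @rdname accessors
#' @export
setMethod("maxPosition", "EnrichmentProfile", function(x) x@maxPosition)

#' @rdname accessors
#' @export
setGeneric("leadingEdge", function(x) standardGeneric("leadingEdge"))
#' @rdname accessors
#' @export
setMethod("leadingEdge", "EnrichmentProfile", function(x) x@leadingEdge)

#' @rdname accessors
#' @export
setGeneric("runningSum", function(x) standardGeneric("runningSum"))
#' @rdname accessors
#' @export
setMethod("runningSum", "EnrichmentProfile", function(x) x@runningSum)

#' @rdname accessors
#' @export
setGeneric("stepSizes", function(x) standardGeneric("stepSizes"))
#' @rdname accessors
#' @export
setMethod("stepSizes", "EnrichmentProfile",
          function(x) c(up = x@upStep, down = x@downStep))

#' @rdname accessors
#' @export
setGeneric("permP", function(x) standardGeneric("permP"))
#' @rdname accessors
#' @export
setMethod("permP", "EnrichmentProfile", function(x) x@permP)

#' @rdname accessors
#' @export
setGeneric("nullMaxES", function(x) standardGeneric("nullMaxES"))
#' @rdname accessors
#' @export
setMethod("nullMaxES", "EnrichmentProfile", function(x) x@nullMaxES)

#' seed50: smallest top fraction of a ranked list holding half the seeds
#'
#' For an [EnrichmentProfile-class] the stored value is returned; for a
#' [RankedMasterList-class] (plus a seed set) it is computed. See
#' [runningSumEnrichment()].
#'
#' @param x profile or ranked list.
#' @param ... for the ranked-list method, `seedSet`.
#' @return percent of the list length, in (0, 100].
#' @export
setGeneric("seed50", function(x, ...) standardGeneric("seed50"))
#' @rdname seed50
#' @export
setMethod("seed50", "EnrichmentProfile", function(x, ...) x@seed50Percent)

#' @rdname accessors
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))
#' @rdname accessors
#' @export
setMethod("pValue", "ContingencyResult", function(x) x@pValue)

#' @rdname accessors
#' @export
setGeneric("statistic", function(x) standardGeneric("statistic"))
#' @rdname accessors
#' @export
setMethod("statistic", "ContingencyResult", function(x) x@statistic)

#' @rdname accessors
#' @export
setGeneric("oddsRatio", function(x) standardGeneric("oddsRatio"))
#' @rdname accessors
#' @export
setMethod("oddsRatio", "ContingencyResult", function(x) x@oddsRatio)

#' @rdname accessors
#' @export
setGeneric("contingencyTable", function(x) standardGeneric("contingencyTable"))
#' @rdname accessors
#' @export
setMethod("contingencyTable", "ContingencyResult", function(x) x@table)

#' @rdname accessors
#' @export
setGeneric("moduleMembership", function(x) standardGeneric("moduleMembership"))
#' @rdname accessors
#' @export
setMethod("moduleMembership", "SimTruth", function(x) x@moduleMembership)

#' @rdname accessors
#' @export
setGeneric("seedSet", function(x) standardGeneric("seedSet"))
#' @rdname accessors
#' @export
setMethod("seedSet", "SimTruth", function(x) x@seedSet)

#' @rdname accessors
#' @export
setGeneric("regulatorResponsiveSet", function(x) standardGeneric("regulatorResponsiveSet"))
#' @rdname accessors
#' @export
setMethod("regulatorResponsiveSet", "SimTruth", function(x) x@regulatorResponsiveSet)

#' @rdname accessors
#' @export
setGeneric("ppiEdges", function(x) standardGeneric("ppiEdges"))
#' @rdname accessors
#' @export
setMethod("ppiEdges", "SimTruth", function(x) x@ppiEdges)

#' @rdname accessors
#' @export
setGeneric("pathwayAnnotations", function(x) standardGeneric("pathwayAnnotations"))
#' @rdname accessors
#' @export
setMethod("pathwayAnnotations", "SimTruth", function(x) x@pathwayAnnotations)

#' @rdname accessors
#' @export
setGeneric("compartments", function(x) standardGeneric("compartments"))
#' @rdname accessors
#' @export
setMethod("compartments", "CompartmentPanel", function(x) x@compartments)

#' @rdname accessors
#' @export
setGeneric("panelOrdering", function(x) standardGeneric("panelOrdering"))
#' @rdname accessors
#' @export
setMethod("panelOrdering", "CompartmentPanel", function(x) x@ordering)

#' @rdname accessors
#' @export
setGeneric("panelSkipped", function(x) standardGeneric("panelSkipped"))
#' @rdname accessors
#' @export
setMethod("panelSkipped", "CompartmentPanel", function(x) x@skipped)

setMethod("show", "Compendium", function(object) {
  ns <- vapply(object@datasets, ncol, integer(1))
  cat(sprintf("Compendium: %d datasets, %d universe genes, %d samples total\n",
              length(object@datasets), length(object@geneUniverse), sum(ns)))
})

setMethod("show", "CorrelateList", function(object) {
  cat(sprintf("CorrelateList for seed '%s' (r >= %.3g): %d correlates%s\n",
              object@seedId, object@rThreshold, nrow(object@entries),
              if (object@eligible) "" else " [ineligible seed]"))
})

setMethod("show", "SeedNetwork", function(object) {
  cat(sprintf("SeedNetwork: %d nodes, %d edges (r >= %.3g)\n",
              length(object@nodes), nrow(object@edges), object@rThreshold))
})

setMethod("show", "RankedMasterList", function(object) {
  e <- object@entries
  cat(sprintf("RankedMasterList: %d transcripts, occurrence counts %d..%d\n",
              nrow(e), if (nrow(e)) min(e$occurrence_count) else 0L,
              if (nrow(e)) max(e$occurrence_count) else 0L))
})

setMethod("show", "EnrichmentProfile", function(object) {
  cat(sprintf("EnrichmentProfile: N=%d, G=%d, steps (%.4g, %.4g)\n",
              object@N, object@G, object@upStep, object@downStep))
  cat(sprintf("  max ES %.4g at position %d; leading edge %d genes; seed50 = %.3g%%\n",
              object@maxES, object@maxPosition, length(object@leadingEdge),
              object@seed50Percent))
  if (object@B > 0L)
    cat(sprintf("  permutation p = %.4g (B = %d)\n", object@permP, object@B))
})

setMethod("show", "ContingencyResult", function(object) {
  cat(sprintf("ContingencyResult (%s): p = %.4g, odds ratio = %.4g\n",
              object@method, object@pValue, object@oddsRatio))
  print(object@table)
})

setMethod("show", "SimTruth", function(object) {
  mm <- object@moduleMembership
  cat(sprintf(
    "SimTruth: %d genes (%d in modules), %d seeds, %d responsive, %d PPI edges, %d terms\n",
    length(mm), sum(!is.na(mm)), length(object@seedSet),
    length(object@regulatorResponsiveSet), nrow(object@ppiEdges),
    length(object@pathwayAnnotations)))
})

setMethod("show", "CompartmentPanel", function(object) {
  cat(sprintf("CompartmentPanel: %d compartments (%d skipped)\n",
              length(object@compartments), length(object@skipped)))
  for (nm in object@ordering) {
    pr <- object@compartments[[nm]]$profile
    cat(sprintf("  %s: seed50 = %.3g%%, max ES = %.4g\n",
                nm, pr@seed50Percent, pr@maxES))
  }
})
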