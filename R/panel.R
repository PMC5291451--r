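#' @include AllClasses.R AllGenerics.R
NULL

#' Run the ranked-enrichment procedure for several compartment seed sets
#'
#' For each named seed set: correlate lists are computed over the shared
#' compendium, merged into an occurrence-ranked master list, and scored with
#' the running-sum enrichment plus its permutation null. Compartments with
#' fewer than two eligible seeds are skipped (reported, not fatal). The panel
#' is ordered by ascending seed50, so the most intra-correlated compartment
#' comes first.
#'
#' @param compendium a [Compendium-class].
#' @param seedSets named list of gene-id vectors.
#' @param rThreshold,minSharedDatasets,minPresenceFraction correlation-engine
#'   settings (see [correlateList()]).
#' @param B permutation replicates per compartment.
#' @param rngSeed integer seed; compartment c uses `rngSeed + index(c)` so
#'   results do not depend on processing order.
#' @return a [CompartmentPanel-class].
#' @export
runPanel <- function(compendium, seedSets, rThreshold = 0.5,
                     minSharedDatasets = 3L, minPresenceFraction = 0.25,
                     B = 1000L, rngSeed = 1L) {
  stopifnot(is(compendium, "Compendium"), length(seedSets) >= 1L,
            !is.null(names(seedSets)))
  comps <- list()
  skipped <- character(0)
  nm <- names(seedSets)
  for (i in seq_along(seedSets)) {
    seeds <- intersect(seedSets[[i]], geneUniverse(compendium))
    cls <- correlateLists(compendium, seeds, rThreshold = rThreshold,
                          minSharedDatasets = minSharedDatasets,
                          minPresenceFraction = minPresenceFraction)
    nEligible <- sum(vapply(cls, eligible, logical(1)))
    if (nEligible < 2L) {
      skipped <- c(skipped, nm[i])
      next
    }
    ranked <- rankedMasterList(cls)
    prof <- permutationNull(ranked, seedSets[[i]], B = B,
                            rngSeed = rngSeed + i)
    comps[[nm[i]]] <- list(seeds = seedSets[[i]], profile = prof)
  }
  s50 <- vapply(comps, function(cp) cp$profile@seed50Percent, numeric(1))
  ordering <- names(comps)[order(s50, names(comps))]
  new("CompartmentPanel", compartments = comps, ordering = ordering,
      skipped = skipped)
}

#' Summarise a compartment panel
#'
#' @param panel a [CompartmentPanel-class].
#' @return data.frame (one row per compartment, in panel order) with N, G,
#'   max ES, permutation p and seed50.
#' @export
panelSummary <- function(panel) {
  stopifnot(is(panel, "CompartmentPanel"))
  rows <- lapply(panelOrdering(panel), function(nm) {
    pr <- compartments(panel)[[nm]]$profile
    data.frame(compartment = nm, N = pr@N, G = pr@G, max_es = pr@maxES,
               perm_p = pr@permP, seed50_percent = pr@seed50Percent,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(compartment = character(0), N = integer(0),
                      G = integer(0), max_es = numeric(0), perm_p = numeric(0),
                      seed50_percent = numeric(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Running-sum enrichment of an arbitrary transcript class
#'
#' Identical machinery to [runningSumEnrichment()] with any gene class taking
#' the role of the seed designation (e.g. ribosomal-protein transcripts),
#' including the permutation null.
#'
#' @inheritParams permutationNull
#' @param classSet gene ids of the class to score.
#' @return an [EnrichmentProfile-class] with permutation fields set.
#' @export
classEnrichment <- function(ranked, classSet, B = 1000L, rngSeed = 1L) {
  permutationNull(ranked, classSet, B = B, rngSeed = rngSeed)
}
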