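#' @include AllClasses.R AllGenerics.R
NULL

# Per-dataset Pearson correlations of one seed against every other gene,
# combined across datasets by a Fisher z-transform weighted mean.
#
# For each dataset where the seed is present and non-constant, the Pearson r
# between the seed and every present, non-constant gene is computed within
# that dataset; per-dataset values are mapped to z = atanh(r), averaged with
# weights (samples - 3) -- the reciprocal variance of z under normality --
# and mapped back with tanh. Datasets contributing zero weight (exactly 3
# samples) fall back to an unweighted mean of z.
#
# Returns combined r, per-gene supporting-dataset counts, and the number of
# datasets in which the seed itself was usable ("presence").
.seedCorrelations <- function(compendium, seedId) {
  uni <- geneUniverse(compendium)
  U <- length(uni)
  zw <- zs <- w <- numeric(U)
  support <- integer(U)
  presence <- 0L
  for (X in datasets(compendium)) {
    if (!(seedId %in% rownames(X))) next
    x <- X[seedId, ]
    if (stats::sd(x) == 0 || anyNA(x)) next
    presence <- presence + 1L
    n <- ncol(X)
    rs <- suppressWarnings(as.vector(stats::cor(x, t(X))))
    ok <- is.finite(rs)
    if (!any(ok)) next
    i <- match(rownames(X)[ok], uni)
    z <- atanh(.clampR(rs[ok]))
    support[i] <- support[i] + 1L
    zs[i] <- zs[i] + z
    zw[i] <- zw[i] + z * (n - 3)
    w[i] <- w[i] + (n - 3)
  }
  r <- rep(NA_real_, U)
  pos <- w > 0
  r[pos] <- tanh(zw[pos] / w[pos])
  fall <- !pos & support > 0L
  r[fall] <- tanh(zs[fall] / support[fall])
  names(r) <- names(support) <- uni
  list(r = r, support = support, presence = presence)
}

#' Combined Pearson correlation of a gene pair across the compendium
#'
#' Pearson r is computed within every dataset where both genes are present
#' and non-constant, and the per-dataset values are combined via a Fisher
#' z-transform mean weighted by (samples - 3). The estimate is undefined when
#' fewer than `minSharedDatasets` datasets qualify.
#'
#' @param compendium a [Compendium-class].
#' @param geneA,geneB gene ids in the universe.
#' @param minSharedDatasets minimum number of qualifying datasets (>= 1).
#' @return list with `r` (combined correlation, NA when undefined),
#'   `nDatasets` (qualifying datasets), `defined`, and `reason` (one of
#'   "ok", "insufficient_datasets", "constant_gene").
#' @examples
#' sim <- simulateCompendium(simParams(2, 10, 20,
#'   data.frame(module_id = "m1", size = 5, loading_mean = 1, loading_sd = 0),
#'   noiseSd = 0.2, rngSeed = 1))
#' pairwiseCorrelation(sim$compendium, "g00001", "g00002")
#' @export
pairwiseCorrelation <- function(compendium, geneA, geneB, minSharedDatasets = 3L) {
  stopifnot(is(compendium, "Compendium"))
  minSharedDatasets <- .assertCount(minSharedDatasets, "minSharedDatasets")
  uni <- geneUniverse(compendium)
  if (!geneA %in% uni) stop(sprintf("gene '%s' not in universe", geneA))
  if (!geneB %in% uni) stop(sprintf("gene '%s' not in universe", geneB))
  rvals <- numeric(0)
  ns <- integer(0)
  sharedAny <- FALSE
  for (X in datasets(compendium)) {
    rn <- rownames(X)
    if (!(geneA %in% rn && geneB %in% rn)) next
    sharedAny <- TRUE
    a <- X[geneA, ]; b <- X[geneB, ]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) next
    rvals <- c(rvals, stats::cor(a, b))
    ns <- c(ns, ncol(X))
  }
  if (length(rvals) < minSharedDatasets) {
    reason <- if (sharedAny && length(rvals) == 0L) "constant_gene"
              else "insufficient_datasets"
    return(list(r = NA_real_, nDatasets = length(rvals), defined = FALSE,
                reason = reason))
  }
  z <- atanh(.clampR(rvals))
  w <- ns - 3
  r <- if (sum(w) > 0) tanh(sum(z * w) / sum(w)) else tanh(mean(z))
  list(r = r, nDatasets = length(rvals), defined = TRUE, reason = "ok")
}

#' Correlate list: all transcripts co-expressed with a seed
#'
#' Queries the compendium with one seed transcript and returns every gene
#' whose combined correlation ([pairwiseCorrelation()]) reaches `rThreshold`,
#' sorted by decreasing r (ties by gene id). The threshold applies to signed
#' r, so only positive correlates are returned. A seed present (and
#' non-constant) in fewer than `minPresenceFraction` of datasets is
#' ineligible and yields an empty list, mirroring query transcripts that are
#' too sparsely represented to produce a correlate table.
#'
#' @inheritParams pairwiseCorrelation
#' @param seedId the query gene.
#' @param rThreshold correlation threshold (default 0.5).
#' @param minPresenceFraction minimum fraction of datasets in which the seed
#'   must be present and non-constant (default 0.25).
#' @return a [CorrelateList-class].
#' @export
correlateList <- function(compendium, seedId, rThreshold = 0.5,
                          minSharedDatasets = 3L, minPresenceFraction = 0.25) {
  stopifnot(is(compendium, "Compendium"))
  uni <- geneUniverse(compendium)
  if (!seedId %in% uni) stop(sprintf("seed '%s' not in universe", seedId))
  minSharedDatasets <- .assertCount(minSharedDatasets, "minSharedDatasets")
  minPresenceFraction <- .assertFraction(minPresenceFraction, "minPresenceFraction")
  cc <- .seedCorrelations(compendium, seedId)
  emptyEntries <- data.frame(gene_id = character(0), r = numeric(0),
                             n_datasets_supporting = integer(0),
                             stringsAsFactors = FALSE)
  if (cc$presence < 1L ||
      cc$presence / nDatasets(compendium) < minPresenceFraction)
    return(new("CorrelateList", seedId = seedId, entries = emptyEntries,
               rThreshold = rThreshold, eligible = FALSE))
  keep <- !is.na(cc$r) & cc$support >= minSharedDatasets &
    cc$r >= rThreshold & names(cc$r) != seedId
  e <- data.frame(gene_id = names(cc$r)[keep], r = unname(cc$r[keep]),
                  n_datasets_supporting = unname(cc$support[keep]),
                  stringsAsFactors = FALSE)
  e <- e[order(-e$r, e$gene_id), , drop = FALSE]
  rownames(e) <- NULL
  new("CorrelateList", seedId = seedId, entries = e,
      rThreshold = rThreshold, eligible = TRUE)
}

#' Correlate lists for a set of seeds
#'
#' Convenience wrapper applying [correlateList()] to each seed; returns a
#' named list.
#'
#' @inheritParams correlateList
#' @param seedIds character vector of query genes.
#' @export
correlateLists <- function(compendium, seedIds, rThreshold = 0.5,
                           minSharedDatasets = 3L, minPresenceFraction = 0.25) {
  out <- lapply(seedIds, correlateList, compendium = compendium,
                rThreshold = rThreshold, minSharedDatasets = minSharedDatasets,
                minPresenceFraction = minPresenceFraction)
  names(out) <- seedIds
  out
}
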