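# Fixture builders shared across test files. Everything is generated in code;
# sizes are kept small so each builder runs in milliseconds.

# compendium with one strong planted module plus background noise genes
strongModuleSim <- function(nGenes = 100, moduleSize = 10, loadingMean = 1,
                            loadingSd = 0, noiseSd = 0.2, nDatasets = 3,
                            samples = 20, dropout = 0, seedFrac = 1,
                            rngSeed = 1) {
  simulateCompendium(simParams(
    nDatasets = nDatasets, samplesPerDataset = samples, nGenes = nGenes,
    moduleSpecs = data.frame(module_id = "m1", size = moduleSize,
                             loading_mean = loadingMean, loading_sd = loadingSd),
    noiseSd = noiseSd, seedOverlapFraction = seedFrac,
    dropoutFraction = dropout, rngSeed = rngSeed))
}

# hand-built compendium from explicit matrices
compendiumFromMatrices <- function(...) {
  mats <- list(...)
  if (is.null(names(mats)) || any(!nzchar(names(mats))))
    names(mats) <- sprintf("ds%02d", seq_along(mats))
  uni <- sort(unique(unlist(lapply(mats, rownames))))
  new("Compendium", datasets = mats, geneUniverse = uni)
}

# hand-built correlate list (bypasses the correlation engine)
makeCorrelateList <- function(seed, genes, r = NULL, threshold = 0.5,
                              eligible = TRUE, support = 3L) {
  if (is.null(r)) r <- rep(0.9, length(genes))
  e <- data.frame(gene_id = genes, r = r,
                  n_datasets_supporting = rep(as.integer(support), length(genes)),
                  stringsAsFactors = FALSE)
  e <- e[order(-e$r, e$gene_id), , drop = FALSE]
  rownames(e) <- NULL
  if (!eligible) e <- e[0, , drop = FALSE]
  new("CorrelateList", seedId = seed, entries = e, rThreshold = threshold,
      eligible = eligible)
}

# ranked list with a prescribed gene order (counts descending by construction)
makeRankedList <- function(genes) {
  n <- length(genes)
  new("RankedMasterList",
      entries = data.frame(gene_id = genes,
                           occurrence_count = seq(n, 1L),
                           max_r = rep(1, n), stringsAsFactors = FALSE))
}

# exhaustive hypergeometric oracle: one-sided (greater) Fisher p on a 2x2
# table by enumerating every table with the observed margins
bruteFisherGreater <- function(a, b, c, d) {
  rowTot <- a + b
  colTot <- a + c
  n <- a + b + c + d
  xs <- max(0, rowTot + colTot - n):min(rowTot, colTot)
  probs <- vapply(xs, function(x)
    choose(colTot, x) * choose(n - colTot, rowTot - x) / choose(n, rowTot),
    numeric(1))
  sum(probs[xs >= a])
}
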