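#' @include AllClasses.R AllGenerics.R
NULL

#' Simulation parameters for a synthetic expression compendium
#'
#' Describes a compendium with planted co-regulated gene modules. Each module
#' m is driven by one latent factor per dataset: for dataset d, gene g, sample
#' s, \deqn{X[g,s] = \sum_m L[g,m] F_d[m,s] + \epsilon,} with
#' `F_d[m,] ~ N(0,1)` drawn independently per dataset (co-regulation recurs in
#' every dataset but the factor realisations do not carry over), loadings
#' `L[g,m] ~ N(loading_mean, loading_sd)` nonzero only for genes in module m,
#' and `eps ~ N(0, noise_sd)`. A fraction of each dataset's genes is dropped
#' to emulate platform differences, and a fraction of the first module is
#' designated the seed set.
#'
#' @param nDatasets number of datasets.
#' @param samplesPerDataset scalar or length-`nDatasets` vector of sample counts.
#' @param nGenes size of the gene universe.
#' @param moduleSpecs data.frame with columns `module_id`, `size`,
#'   `loading_mean`, `loading_sd`; module sizes must sum to at most `nGenes`
#'   and each gene belongs to at most one module.
#' @param noiseSd independent noise standard deviation (> 0).
#' @param seedOverlapFraction fraction of the first module designated as seeds.
#' @param dropoutFraction probability a gene is absent from a given dataset.
#' @param rngSeed integer seed; identical seeds give byte-identical output.
#' @return validated list of class `simParams`.
#' @examples
#' sp <- simParams(nDatasets = 2, samplesPerDataset = 10, nGenes = 50,
#'                 moduleSpecs = data.frame(module_id = "m1", size = 10,
#'                                          loading_mean = 1, loading_sd = 0),
#'                 noiseSd = 0.5, rngSeed = 1)
#' @export
simParams <- function(nDatasets, samplesPerDataset, nGenes, moduleSpecs,
                      noiseSd = 1, seedOverlapFraction = 1,
                      dropoutFraction = 0, rngSeed = 1L) {
  nDatasets <- .assertCount(nDatasets, "nDatasets")
  nGenes <- .assertCount(nGenes, "nGenes")
  if (length(samplesPerDataset) == 1L)
    samplesPerDataset <- rep(samplesPerDataset, nDatasets)
  if (length(samplesPerDataset) != nDatasets)
    stop("samplesPerDataset must be scalar or of length nDatasets")
  samplesPerDataset <- vapply(samplesPerDataset, .assertCount,
                              integer(1), name = "samplesPerDataset", min = 3L)
  need <- c("module_id", "size", "loading_mean", "loading_sd")
  if (!is.data.frame(moduleSpecs) || !all(need %in% names(moduleSpecs)))
    stop("moduleSpecs must be a data.frame with module_id, size, loading_mean, loading_sd")
  if (anyDuplicated(moduleSpecs$module_id)) stop("duplicated module_id")
  if (any(moduleSpecs$size < 1)) stop("module sizes must be positive")
  if (any(moduleSpecs$loading_sd < 0)) stop("loading_sd must be >= 0")
  if (sum(moduleSpecs$size) > nGenes)
    stop("module sizes exceed nGenes")
  if (!is.numeric(noiseSd) || length(noiseSd) != 1L || is.na(noiseSd) || noiseSd <= 0)
    stop("noiseSd must be > 0")
  seedOverlapFraction <- .assertFraction(seedOverlapFraction, "seedOverlapFraction")
  dropoutFraction <- .assertFraction(dropoutFraction, "dropoutFraction", maxOpen = TRUE)
  structure(list(nDatasets = nDatasets, samplesPerDataset = samplesPerDataset,
                 nGenes = nGenes, moduleSpecs = moduleSpecs, noiseSd = noiseSd,
                 seedOverlapFraction = seedOverlapFraction,
                 dropoutFraction = dropoutFraction,
                 rngSeed = as.integer(rngSeed)),
            class = "simParams")
}

#' Simulate a synthetic expression compendium with planted modules
#'
#' Generates the compendium described by [simParams()] together with its
#' ground truth. Module genes occupy the first positions of the universe, in
#' `moduleSpecs` order; seeds are sampled from the first module. The PPI edge
#' list and annotation sets of the returned truth are empty until filled by
#' [simulatePPI()] and [simulateAnnotations()].
#'
#' @param params a `simParams` object.
#' @return list with elements `compendium` ([Compendium-class]) and
#'   `truth` ([SimTruth-class]).
#' @seealso [simulatePPI()], [simulateAnnotations()]
#' @export
simulateCompendium <- function(params) {
  stopifnot(inherits(params, "simParams"))
  ms <- params$moduleSpecs
  nGenes <- params$nGenes
  genes <- sprintf("g%05d", seq_len(nGenes))
  membership <- rep(NA_character_, nGenes)
  names(membership) <- genes
  nMod <- nrow(ms)
  L <- matrix(0, nGenes, nMod)
  pos <- 0L
  modIdx <- vector("list", nMod)
  withRNG(params$rngSeed, {
    for (m in seq_len(nMod)) {
      idx <- pos + seq_len(ms$size[m])
      modIdx[[m]] <- idx
      membership[idx] <- as.character(ms$module_id[m])
      L[idx, m] <- stats::rnorm(length(idx), ms$loading_mean[m], ms$loading_sd[m])
      pos <- pos + ms$size[m]
    }
    firstMod <- genes[modIdx[[1L]]]
    nSeed <- max(1L, round(params$seedOverlapFraction * length(firstMod)))
    seeds <- sort(sample(firstMod, nSeed))
    dats <- vector("list", params$nDatasets)
    names(dats) <- sprintf("ds%03d", seq_len(params$nDatasets))
    for (d in seq_len(params$nDatasets)) {
      S <- params$samplesPerDataset[d]
      present <- stats::runif(nGenes) >= params$dropoutFraction
      if (!any(present)) present[1L] <- TRUE
      F <- matrix(stats::rnorm(nMod * S), nMod, S)
      X <- L %*% F + matrix(stats::rnorm(nGenes * S, 0, params$noiseSd), nGenes, S)
      dimnames(X) <- list(genes, sprintf("s%03d", seq_len(S)))
      dats[[d]] <- X[present, , drop = FALSE]
    }
    comp <- new("Compendium", datasets = dats, geneUniverse = genes)
    truth <- new("SimTruth", moduleMembership = membership, seedSet = seeds,
                 regulatorResponsiveSet = character(0),
                 ppiEdges = data.frame(protein_a = character(0),
                                       protein_b = character(0),
                                       stringsAsFactors = FALSE),
                 pathwayAnnotations = list(), rngSeed = params$rngSeed)
    list(compendium = comp, truth = truth)
  })
}

# canonical unordered pair representation: protein_a < protein_b
.canonPairs <- function(a, b) {
  data.frame(protein_a = pmin(a, b), protein_b = pmax(a, b),
             stringsAsFactors = FALSE)
}

#' Simulate a protein-protein interaction edge list with planted structure
#'
#' Within-module gene pairs are included with probability `pWithin`, all other
#' pairs with probability `pBetween`, emulating a repository of physical
#' interactions enriched inside the planted module. Pairs are unordered,
#' deduplicated, with no self-pairs.
#'
#' @param truth a [SimTruth-class].
#' @param pWithin,pBetween inclusion probabilities, `0 <= pBetween <= pWithin <= 1`.
#' @param rngSeed integer seed.
#' @param universe optional subset of genes to draw edges over (defaults to
#'   the whole universe).
#' @return the truth with its `ppiEdges` slot populated.
#' @export
simulatePPI <- function(truth, pWithin, pBetween, rngSeed,
                        universe = geneUniverse(truth)) {
  stopifnot(is(truth, "SimTruth"))
  pWithin <- .assertFraction(pWithin, "pWithin")
  pBetween <- .assertFraction(pBetween, "pBetween")
  if (pBetween > pWithin) stop("need pBetween <= pWithin")
  genes <- sort(universe)
  if (!all(genes %in% geneUniverse(truth))) stop("universe outside truth genes")
  mm <- truth@moduleMembership[genes]
  withRNG(rngSeed, {
    within <- list()
    for (mod in unique(stats::na.omit(mm))) {
      members <- genes[!is.na(mm) & mm == mod]
      if (length(members) >= 2L) {
        cmb <- utils::combn(members, 2L)
        keep <- stats::runif(ncol(cmb)) < pWithin
        if (any(keep))
          within[[mod]] <- .canonPairs(cmb[1L, keep], cmb[2L, keep])
      }
    }
    within <- if (length(within)) do.call(rbind, within) else
      .canonPairs(character(0), character(0))
    n <- length(genes)
    totalPairs <- choose(n, 2)
    nWithinPairs <- sum(vapply(unique(stats::na.omit(mm)), function(mod)
      choose(sum(!is.na(mm) & mm == mod), 2), numeric(1)))
    nBetweenPairs <- totalPairs - nWithinPairs
    between <- .canonPairs(character(0), character(0))
    if (nBetweenPairs > 0 && pBetween > 0) {
      m <- stats::rbinom(1L, nBetweenPairs, pBetween)
      if (m > 0) {
        seen <- character(0)
        rows <- vector("list", 0L)
        while (length(seen) < m) {
          k <- max(2L * (m - length(seen)), 16L)
          i <- sample.int(n, k, replace = TRUE)
          j <- sample.int(n, k, replace = TRUE)
          ok <- i != j
          a <- pmin(genes[i[ok]], genes[j[ok]])
          b <- pmax(genes[i[ok]], genes[j[ok]])
          sameMod <- !is.na(mm[a]) & !is.na(mm[b]) & mm[a] == mm[b]
          key <- paste(a, b)
          new <- !sameMod & !duplicated(key) & !(key %in% seen)
          if (any(new)) {
            take <- which(new)[seq_len(min(sum(new), m - length(seen)))]
            rows[[length(rows) + 1L]] <- .canonPairs(a[take], b[take])
            seen <- c(seen, key[take])
          }
        }
        between <- do.call(rbind, rows)
      }
    }
    edges <- rbind(within, between)
    edges <- edges[!duplicated(paste(edges$protein_a, edges$protein_b)), ,
                   drop = FALSE]
    edges <- edges[order(edges$protein_a, edges$protein_b), , drop = FALSE]
    rownames(edges) <- NULL
    initialize(truth, ppiEdges = edges)
  })
}

#' Plant regulator-responsive flags and pathway-term annotations
#'
#' Populates the truth's regulator-responsive set and pathway annotations by
#' independent Bernoulli draws at a within-module rate versus a background
#' rate, emulating a perturbation-response gene list and pathway term
#' assignments concentrated in the planted module.
#'
#' @param truth a [SimTruth-class].
#' @param responsiveFractionModule,responsiveFractionBackground probabilities
#'   a module / background gene is flagged responsive.
#' @param terms data.frame with columns `term_id`, `module_fraction`,
#'   `background_fraction` and optionally `module_id` (default: the seed
#'   module); unknown module ids are an error. Several rows may share a
#'   `term_id` (one per module); their draws are unioned.
#' @param rngSeed integer seed.
#' @return the augmented truth.
#' @export
simulateAnnotations <- function(truth, responsiveFractionModule,
                                responsiveFractionBackground,
                                terms = NULL, rngSeed) {
  stopifnot(is(truth, "SimTruth"))
  pm <- .assertFraction(responsiveFractionModule, "responsiveFractionModule")
  pb <- .assertFraction(responsiveFractionBackground, "responsiveFractionBackground")
  mm <- truth@moduleMembership
  genes <- names(mm)
  seedModule <- unique(stats::na.omit(mm[truth@seedSet]))
  if (length(seedModule) == 0L) seedModule <- unique(stats::na.omit(mm))[1L]
  seedModule <- seedModule[1L]
  withRNG(rngSeed, {
    inMod <- !is.na(mm) & mm == seedModule
    p <- ifelse(inMod, pm, pb)
    responsive <- genes[stats::runif(length(genes)) < p]
    ann <- list()
    if (!is.null(terms)) {
      need <- c("term_id", "module_fraction", "background_fraction")
      if (!is.data.frame(terms) || !all(need %in% names(terms)))
        stop("terms must have term_id, module_fraction, background_fraction")
      for (i in seq_len(nrow(terms))) {
        mod <- if ("module_id" %in% names(terms) && !is.na(terms$module_id[i]))
          as.character(terms$module_id[i]) else seedModule
        if (!mod %in% mm[!is.na(mm)]) stop(sprintf("unknown module_id '%s'", mod))
        inM <- !is.na(mm) & mm == mod
        pi <- ifelse(inM, .assertFraction(terms$module_fraction[i], "module_fraction"),
                     .assertFraction(terms$background_fraction[i], "background_fraction"))
        tid <- as.character(terms$term_id[i])
        # several rows may target one term (different modules): union the draws
        ann[[tid]] <- sort(union(ann[[tid]], genes[stats::runif(length(genes)) < pi]))
      }
    }
    initialize(truth, regulatorResponsiveSet = responsive,
               pathwayAnnotations = ann)
  })
}
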