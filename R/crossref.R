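#' @include AllClasses.R AllGenerics.R
NULL

#' Per-seed above-chance membership test
#'
#' Compares the fraction of a seed's correlate list drawn from a reference
#' transcript universe (e.g. the mitochondrial protein-encoding set) with the
#' fraction expected by chance, `|seedUniverse| / genomeSize`. Significance is
#' a one-sided Fisher exact test on (in/out list) x (member/non-member of the
#' reference set) over the genome; the seed is "above chance" when the
#' observed fraction exceeds the expectation and p < `alpha`.
#'
#' @param clist a [CorrelateList-class] (eligible).
#' @param seedUniverse the reference gene set.
#' @param genomeSize number of genes in the genome (default 23000).
#' @param alpha significance level (default 1e-4).
#' @return list with `observedFraction`, `expectedFraction`, `result`
#'   (a [ContingencyResult-class]), and `aboveChance`.
#' @export
perSeedChanceTest <- function(clist, seedUniverse, genomeSize = 23000L,
                              alpha = 1e-4) {
  stopifnot(is(clist, "CorrelateList"))
  genomeSize <- .assertCount(genomeSize, "genomeSize")
  U <- length(unique(seedUniverse))
  if (genomeSize < U) stop("genomeSize smaller than the reference set")
  expected <- U / genomeSize
  e <- entries(clist)
  nl <- nrow(e)
  if (!eligible(clist) || nl == 0L) {
    tab <- matrix(c(0L, 0L, U, genomeSize - U), 2L, 2L, byrow = TRUE)
    res <- new("ContingencyResult", table = tab, statistic = NA_real_,
               pValue = 1, method = "fisher_one_sided_greater",
               oddsRatio = NA_real_)
    return(list(observedFraction = 0, expectedFraction = expected,
                result = res, aboveChance = FALSE))
  }
  m <- sum(e$gene_id %in% seedUniverse)
  tab <- c(m, nl - m, U - m, genomeSize - nl - (U - m))
  res <- fisherExact2x2(tab)
  obs <- m / nl
  list(observedFraction = obs, expectedFraction = expected, result = res,
       aboveChance = obs > expected && pValue(res) < alpha)
}

#' Count seeds whose correlate lists are enriched above chance
#'
#' Applies [perSeedChanceTest()] to every eligible correlate list and counts
#' how many are above chance.
#'
#' @param clists list of [CorrelateList-class] objects.
#' @inheritParams perSeedChanceTest
#' @return list with `count`, `eligible`, and `fraction` = count/eligible.
#' @export
countAboveChance <- function(clists, seedUniverse, genomeSize = 23000L,
                             alpha = 1e-4) {
  el <- Filter(eligible, clists)
  if (length(el) == 0L) stop("no eligible correlate lists")
  above <- vapply(el, function(cl)
    perSeedChanceTest(cl, seedUniverse, genomeSize, alpha)$aboveChance,
    logical(1))
  list(count = sum(above), eligible = length(el),
       fraction = sum(above) / length(el))
}

#' Chi-square enrichment of a flag set in the leading edge
#'
#' Builds the 2x2 table of (in/out of the leading edge) x (flagged/unflagged)
#' over `universe` minus `exclude` and applies [chiSquare2x2()]. Passing the
#' seed set as `exclude` reproduces the seed-removed variant of the analysis,
#' which asks whether the enrichment persists among non-seed transcripts.
#'
#' @param leSet leading-edge gene ids.
#' @param flagSet flagged gene ids (e.g. regulator-responsive transcripts).
#' @param universe gene ids defining the population.
#' @param exclude gene ids removed from the population before tabulation.
#' @param correct Yates correction flag passed to [chiSquare2x2()].
#' @return a [ContingencyResult-class].
#' @export
leFlagChisq <- function(leSet, flagSet, universe, exclude = character(0),
                        correct = FALSE) {
  u <- setdiff(unique(universe), exclude)
  if (length(u) == 0L) stop("empty universe after exclusion")
  le <- u %in% leSet
  fl <- u %in% flagSet
  tab <- c(sum(le & fl), sum(le & !fl), sum(!le & fl), sum(!le & !fl))
  chiSquare2x2(tab, correct = correct)
}

#' Filter a PPI edge list to annotated/unannotated interactions
#'
#' Retains only edges with exactly one endpoint in the annotated set (MC+),
#' and counts for every unannotated (MC-) protein its distinct annotated
#' interaction partners.
#'
#' @param edges data.frame with columns `protein_a`, `protein_b` (an
#'   unordered, deduplicated edge list; see [readPpiTsv()]).
#' @param mcSet annotated protein ids.
#' @return list with `keptEdges` (same shape as `edges`) and `partnership`
#'   (named integer vector: MC- protein -> number of distinct MC+ partners).
#' @export
ppiMcFilter <- function(edges, mcSet) {
  stopifnot(is.data.frame(edges),
            all(c("protein_a", "protein_b") %in% names(edges)))
  aIn <- edges$protein_a %in% mcSet
  bIn <- edges$protein_b %in% mcSet
  keep <- xor(aIn, bIn)
  kept <- edges[keep, , drop = FALSE]
  rownames(kept) <- NULL
  mcMinus <- ifelse(kept$protein_a %in% mcSet, kept$protein_b, kept$protein_a)
  mcPlus <- ifelse(kept$protein_a %in% mcSet, kept$protein_a, kept$protein_b)
  if (length(mcMinus)) {
    counts <- tapply(mcPlus, mcMinus, function(p) length(unique(p)))
    partnership <- as.integer(counts)
    names(partnership) <- names(counts)
  } else partnership <- integer(0)
  list(keptEdges = kept, partnership = partnership)
}

#' Fisher enrichment of interaction-supported MC- proteins in the leading edge
#'
#' Restricts the MC- partnership map to proteins with at least `minPartners`
#' distinct annotated partners and tests their over-representation inside the
#' leading edge with a one-sided Fisher exact test over `universe`.
#'
#' @param partnership named integer vector from [ppiMcFilter()].
#' @param leSet leading-edge gene ids.
#' @param universe population gene ids.
#' @param minPartners minimum distinct annotated partners (the analysis is
#'   typically swept over 1, 2, 5, 10).
#' @return a [ContingencyResult-class]; an empty retained set gives p = 1.
#' @export
mcMinusLeFet <- function(partnership, leSet, universe, minPartners = 1L) {
  minPartners <- .assertCount(minPartners, "minPartners")
  u <- unique(universe)
  retained <- names(partnership)[partnership >= minPartners]
  retained <- intersect(retained, u)
  if (length(retained) == 0L) {
    tab <- matrix(c(0L, sum(u %in% leSet), 0L, sum(!(u %in% leSet))),
                  2L, 2L, byrow = TRUE)
    return(new("ContingencyResult", table = tab, statistic = NA_real_,
               pValue = 1, method = "fisher_one_sided_greater",
               oddsRatio = NA_real_))
  }
  le <- u %in% leSet
  rt <- u %in% retained
  tab <- c(sum(le & rt), sum(le & !rt), sum(!le & rt), sum(!le & !rt))
  fisherExact2x2(tab)
}
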