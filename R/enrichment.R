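#' @include AllClasses.R AllGenerics.R
NULL

#' Running-sum step scores
#'
#' For a ranked list of N transcripts containing G class members, the walk
#' gains `sqrt((N-G)/G)` at each member and loses `sqrt(G/(N-G))` at each
#' non-member, so it starts and ends at zero and the product of the step
#' magnitudes is one.
#'
#' @param N ranked-list length.
#' @param G number of class members, `0 < G < N`.
#' @return named numeric vector `c(up = ..., down = ...)`.
#' @examples
#' stepScores(10, 5)        # c(up = 1, down = -1)
#' round(stepScores(18385, 935), 2)
#' @export
stepScores <- function(N, G) {
  N <- .assertCount(N, "N"); G <- .assertCount(G, "G", min = 0L)
  if (G <= 0L || G >= N) stop("need 0 < G < N")
  c(up = sqrt((N - G) / G), down = -sqrt(G / (N - G)))
}

.enrichmentCore <- function(genes, isSeed) {
  N <- length(genes)
  G <- sum(isSeed)
  if (G == 0L) stop("no class members in the ranked list")
  if (G == N) stop("every ranked gene is a class member")
  st <- stepScores(N, G)
  steps <- ifelse(isSeed, st[["up"]], st[["down"]])
  rs <- cumsum(steps)
  maxPos <- which.max(rs)          # earliest position attaining the maximum
  half <- ceiling(G / 2)
  pos50 <- which(isSeed)[half]
  new("EnrichmentProfile", N = N, G = G,
      upStep = st[["up"]], downStep = st[["down"]],
      runningSum = rs, maxES = rs[maxPos], maxPosition = as.integer(maxPos),
      leadingEdge = genes[seq_len(maxPos)],
      seed50Percent = 100 * pos50 / N,
      permP = NA_real_, nullMaxES = numeric(0), B = 0L,
      rankedGenes = genes, isSeed = isSeed)
}

.rankedGenesAndFlags <- function(ranked, seedSet) {
  stopifnot(is(ranked, "RankedMasterList"))
  genes <- entries(ranked)$gene_id
  isSeed <- genes %in% seedSet
  list(genes = genes, isSeed = isSeed)
}

#' Running-sum enrichment of a seed set in a ranked master list
#'
#' Walks down the ranked list applying the [stepScores()] and records the
#' running sum, its maximum (the enrichment score), the leading edge (all
#' transcripts at or before the earliest maximum), and the seed50 statistic.
#' Permutation fields are left unset; see [permutationNull()].
#'
#' @param ranked a [RankedMasterList-class].
#' @param seedSet gene ids constituting the class; must intersect the list
#'   but not cover it.
#' @return an [EnrichmentProfile-class].
#' @export
runningSumEnrichment <- function(ranked, seedSet) {
  rf <- .rankedGenesAndFlags(ranked, seedSet)
  .enrichmentCore(rf$genes, rf$isSeed)
}

#' @describeIn seed50 compute seed50 for a ranked list and a seed set:
#'   the smallest prefix holding at least `ceiling(G/2)` seeds, as a percent
#'   of the list length.
#' @param seedSet gene ids (ranked-list method).
#' @export
setMethod("seed50", "RankedMasterList", function(x, seedSet, ...) {
  rf <- .rankedGenesAndFlags(x, seedSet)
  G <- sum(rf$isSeed)
  if (G == 0L) stop("no class members in the ranked list")
  100 * which(rf$isSeed)[ceiling(G / 2)] / length(rf$genes)
})

#' Permutation null for the running-sum enrichment score
#'
#' Re-derives the running sum B times after reassigning the G seed labels
#' uniformly at random over the N positions of the pre-ordered list (the
#' ordering itself is never shuffled), recording each replicate's maximum
#' enrichment score. The permutation p-value uses the add-one estimator
#' `(1 + #\{null >= observed\}) / (B + 1)`, which is never exactly zero.
#'
#' @inheritParams runningSumEnrichment
#' @param B number of random walks (default 1000).
#' @param rngSeed integer seed; identical seeds give identical nulls.
#' @return an [EnrichmentProfile-class] with `permP`, `nullMaxES` and `B` set.
#' @export
permutationNull <- function(ranked, seedSet, B = 1000L, rngSeed = 1L) {
  B <- .assertCount(B, "B")
  prof <- runningSumEnrichment(ranked, seedSet)
  N <- prof@N; G <- prof@G
  up <- prof@upStep; down <- prof@downStep
  null <- withRNG(rngSeed, {
    vapply(seq_len(B), function(b) {
      steps <- rep(down, N)
      steps[sample.int(N, G)] <- up
      max(cumsum(steps))
    }, numeric(1))
  })
  p <- (1 + sum(null >= prof@maxES)) / (B + 1)
  initialize(prof, permP = p, nullMaxES = null, B = B)
}

#' Export an enrichment profile as a per-position table
#'
#' @param profile an [EnrichmentProfile-class].
#' @return data.frame with position, gene_id, is_seed, running_sum.
#' @export
profileTable <- function(profile) {
  stopifnot(is(profile, "EnrichmentProfile"))
  data.frame(position = seq_len(profile@N), gene_id = profile@rankedGenes,
             is_seed = profile@isSeed, running_sum = profile@runningSum,
             stringsAsFactors = FALSE)
}
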