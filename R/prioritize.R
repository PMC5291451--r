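#' @include AllClasses.R AllGenerics.R
NULL

#' Recurrent candidates: leading edge intersected with a disease module
#'
#' @param leSet leading-edge gene ids from the compendium-wide analysis.
#' @param moduleGenes gene ids of an independently derived disease module.
#' @return the intersection, sorted.
#' @export
recurrentCandidates <- function(leSet, moduleGenes) {
  sort(intersect(unique(leSet), unique(moduleGenes)))
}

#' Guilt-by-association pathway enrichment for one candidate
#'
#' Re-queries the compendium with the candidate to recover its correlate
#' list, then scores each required pathway term with the conservative
#' [easeScore()]: k = term genes in the list, n = list size, K = term genes
#' overall, M = the configured genome size. A candidate passes when every
#' required term reaches `alpha`.
#'
#' @param compendium a [Compendium-class].
#' @param candidate gene id.
#' @param termAnnotations named list of term gene sets.
#' @param requiredTerms term ids that must all be enriched.
#' @param genomeSize population size for the EASE denominator (default 23000).
#' @param alpha per-term EASE threshold (default 0.05).
#' @param ... correlation-engine settings passed to [correlateList()].
#' @return a candidate report: list with `candidateId`, `termScores`
#'   (data.frame: term_id, ease_p, neglog10_p, k, n, K, M), `passes`,
#'   `rankScore` (sum of -log10 p over required terms), and `reason`.
#' @export
guiltByAssociation <- function(compendium, candidate, termAnnotations,
                               requiredTerms, genomeSize = 23000L,
                               alpha = 0.05, ...) {
  stopifnot(all(requiredTerms %in% names(termAnnotations)))
  cl <- correlateList(compendium, candidate, ...)
  empty <- data.frame(term_id = character(0), ease_p = numeric(0),
                      neglog10_p = numeric(0), k = integer(0), n = integer(0),
                      K = integer(0), M = integer(0), stringsAsFactors = FALSE)
  if (!eligible(cl))
    return(list(candidateId = candidate, termScores = empty, passes = FALSE,
                rankScore = 0, reason = "ineligible_candidate"))
  genes <- entries(cl)$gene_id
  n <- length(genes)
  rows <- lapply(requiredTerms, function(tm) {
    tset <- unique(termAnnotations[[tm]])
    K <- min(length(tset), genomeSize)
    k <- sum(genes %in% tset)
    p <- if (n == 0L) 1 else pValue(easeScore(k, min(n, genomeSize), K, genomeSize))
    data.frame(term_id = tm, ease_p = p, neglog10_p = -log10(p),
               k = k, n = n, K = K, M = genomeSize, stringsAsFactors = FALSE)
  })
  ts <- do.call(rbind, rows)
  passes <- nrow(ts) > 0L && all(ts$ease_p <= alpha)
  list(candidateId = candidate, termScores = ts, passes = passes,
       rankScore = sum(ts$neglog10_p), reason = "ok")
}

#' Select and rank passing candidates
#'
#' Retains reports that pass every required term and orders them by
#' decreasing rank score (sum of -log10 EASE p over required terms; with
#' `method = "min"`, the minimum of -log10 p), ties broken by gene id.
#'
#' @param reports list of reports from [guiltByAssociation()].
#' @param alpha re-applied per-term threshold (default 0.05).
#' @param method "sum" (default) or "min" combination of the per-term scores.
#' @return the ordered list of passing reports.
#' @export
selectCandidates <- function(reports, alpha = 0.05, method = c("sum", "min")) {
  method <- match.arg(method)
  keep <- Filter(function(rp)
    nrow(rp$termScores) > 0L && all(rp$termScores$ease_p <= alpha), reports)
  if (length(keep) == 0L) return(list())
  score <- vapply(keep, function(rp)
    if (method == "sum") sum(rp$termScores$neglog10_p)
    else min(rp$termScores$neglog10_p), numeric(1))
  ids <- vapply(keep, function(rp) rp$candidateId, character(1))
  keep <- keep[order(-score, ids)]
  for (i in seq_along(keep)) keep[[i]]$rankScore <-
    if (method == "sum") sum(keep[[i]]$termScores$neglog10_p)
    else min(keep[[i]]$termScores$neglog10_p)
  keep
}

#' Flatten candidate reports into an exportable table
#'
#' @param reports list of candidate reports (see [guiltByAssociation()]).
#' @return data.frame with one row per candidate-term pair plus rank score
#'   and pass flag.
#' @export
candidateTable <- function(reports) {
  if (length(reports) == 0L)
    return(data.frame(candidate_id = character(0), term_id = character(0),
                      ease_p = numeric(0), neglog10_p = numeric(0),
                      rank_score = numeric(0), passes = logical(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, lapply(reports, function(rp) {
    ts <- rp$termScores
    if (nrow(ts) == 0L)
      return(data.frame(candidate_id = rp$candidateId, term_id = NA_character_,
                        ease_p = NA_real_, neglog10_p = NA_real_,
                        rank_score = rp$rankScore, passes = rp$passes,
                        stringsAsFactors = FALSE))
    data.frame(candidate_id = rp$candidateId, term_id = ts$term_id,
               ease_p = ts$ease_p, neglog10_p = ts$neglog10_p,
               rank_score = rp$rankScore, passes = rp$passes,
               stringsAsFactors = FALSE)
  }))
}
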