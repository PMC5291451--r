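#' @include AllClasses.R AllGenerics.R
NULL

#' Merge correlate lists into a seed co-expression network
#'
#' Nodes are all seeds with eligible lists plus every gene appearing in any
#' eligible list; each seed-correlate pair contributes one undirected edge.
#' An unordered pair discovered from both endpoints is kept once with the
#' maximum correlation.
#'
#' @param clists list of [CorrelateList-class] objects.
#' @param rThreshold threshold recorded on the network (defaults to the
#'   first list's threshold).
#' @return a [SeedNetwork-class]; empty input gives an empty network.
#' @export
assembleNetwork <- function(clists, rThreshold = NULL) {
  el <- Filter(eligible, clists)
  thr <- if (!is.null(rThreshold)) rThreshold
         else if (length(clists)) clists[[1L]]@rThreshold else 0.5
  if (length(el) == 0L)
    return(new("SeedNetwork", nodes = character(0),
               edges = data.frame(gene_a = character(0), gene_b = character(0),
                                  r = numeric(0), stringsAsFactors = FALSE),
               rThreshold = thr))
  parts <- lapply(el, function(cl) {
    e <- entries(cl)
    if (nrow(e) == 0L) return(NULL)
    data.frame(gene_a = pmin(seedId(cl), e$gene_id),
               gene_b = pmax(seedId(cl), e$gene_id),
               r = e$r, stringsAsFactors = FALSE)
  })
  all <- do.call(rbind, parts)
  nodes <- sort(unique(c(vapply(el, seedId, character(1)),
                         if (!is.null(all)) c(all$gene_a, all$gene_b))))
  if (is.null(all))
    return(new("SeedNetwork", nodes = nodes,
               edges = data.frame(gene_a = character(0), gene_b = character(0),
                                  r = numeric(0), stringsAsFactors = FALSE),
               rThreshold = thr))
  key <- paste(all$gene_a, all$gene_b)
  rmax <- tapply(all$r, key, max)
  first <- !duplicated(key)
  edges <- all[first, , drop = FALSE]
  edges$r <- as.numeric(rmax[paste(edges$gene_a, edges$gene_b)])
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  new("SeedNetwork", nodes = nodes, edges = edges, rThreshold = thr)
}

#' Occurrence-ranked master transcript list
#'
#' Ranks every gene appearing in the eligible correlate lists by the number
#' of lists containing it (most recurrent first). Ties are broken by the
#' maximum correlation the gene attains in any list, then by ascending gene
#' id, so the ranking is deterministic. Seeds themselves are ranked whenever
#' they occur in other seeds' lists; set `includeSeeds = FALSE` to drop them.
#'
#' @param clists list of [CorrelateList-class] objects (at least one eligible).
#' @param includeSeeds keep genes that are themselves seeds (default TRUE).
#' @return a [RankedMasterList-class].
#' @export
rankedMasterList <- function(clists, includeSeeds = TRUE) {
  el <- Filter(eligible, clists)
  if (length(el) == 0L) stop("no eligible correlate lists")
  parts <- lapply(el, function(cl) entries(cl)[, c("gene_id", "r")])
  all <- do.call(rbind, parts)
  if (!includeSeeds) {
    seeds <- vapply(el, seedId, character(1))
    all <- all[!(all$gene_id %in% seeds), , drop = FALSE]
  }
  if (nrow(all) == 0L) stop("no entries across eligible lists")
  cnt <- table(all$gene_id)
  rmax <- tapply(all$r, all$gene_id, max)
  genes <- names(cnt)
  e <- data.frame(gene_id = genes,
                  occurrence_count = as.integer(cnt),
                  max_r = as.numeric(rmax[genes]),
                  stringsAsFactors = FALSE)
  e <- e[order(-e$occurrence_count, -e$max_r, e$gene_id), , drop = FALSE]
  rownames(e) <- NULL
  new("RankedMasterList", entries = e)
}
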