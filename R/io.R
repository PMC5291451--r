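#' @include AllClasses.R AllGenerics.R
NULL

#' Read a tab-separated expression matrix
#'
#' Expects a header row of sample ids and gene ids in the first column.
#' Duplicate gene rows are a hard error; non-numeric cells are reported with
#' their line number.
#'
#' @param path file path.
#' @return numeric matrix (genes x samples).
#' @export
readExpressionTsv <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t", row.names = NULL,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop(sprintf("%s: expected gene column plus samples", path))
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    dup <- which(duplicated(ids))[1L]
    stop(sprintf("%s: duplicate gene id '%s' at line %d", path, ids[dup], dup + 1L))
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(apply(df[, -1L, drop = FALSE], 1L,
                       function(x) anyNA(suppressWarnings(as.numeric(x)))))[1L]
    stop(sprintf("%s: non-numeric expression value at line %d", path, bad + 1L))
  }
  rownames(m) <- ids
  m
}

#' Write an expression matrix as TSV
#'
#' @param x numeric matrix with gene row names.
#' @param path file path.
#' @export
writeExpressionTsv <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Assemble a Compendium from expression TSV files
#'
#' @param paths character vector of file paths (names become dataset ids).
#' @return a [Compendium-class] whose universe is the union of all gene ids.
#' @export
readCompendium <- function(paths) {
  if (is.null(names(paths)))
    names(paths) <- sub("\\.[^.]*$", "", basename(paths))
  dats <- lapply(paths, readExpressionTsv)
  uni <- sort(unique(unlist(lapply(dats, rownames))))
  new("Compendium", datasets = dats, geneUniverse = uni)
}

#' Write a Compendium as one TSV per dataset
#'
#' @param compendium a [Compendium-class].
#' @param dir output directory (created if absent).
#' @return named vector of written paths.
#' @export
writeCompendium <- function(compendium, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  dats <- datasets(compendium)
  paths <- file.path(dir, paste0(names(dats), ".tsv"))
  names(paths) <- names(dats)
  for (i in seq_along(dats)) writeExpressionTsv(dats[[i]], paths[i])
  invisible(paths)
}

#' Read gene sets from a GMT file
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' genes within a set are dropped with a warning; malformed lines are
#' reported with their line number.
#'
#' @param path file path.
#' @return named list of gene-id vectors.
#' @export
readGmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L)
      stop(sprintf("%s: malformed GMT line %d (need name, description, genes)",
                   path, i))
    genes <- f[-(1:2)]
    if (anyDuplicated(genes)) {
      warning(sprintf("%s: duplicate genes in set '%s' (line %d); deduplicated",
                      path, f[1L], i))
      genes <- unique(genes)
    }
    out[[f[1L]]] <- genes
  }
  out
}

#' Write gene sets as GMT
#'
#' @param sets named list of gene-id vectors.
#' @param path file path.
#' @param descriptions optional character vector parallel to `sets`.
#' @export
writeGmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i)
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t"),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a two-column protein-protein interaction edge list
#'
#' Self-pairs are dropped and duplicate unordered pairs collapsed; both are
#' counted in a message. Lines without exactly two fields are an error with
#' their line number.
#'
#' @param path file path.
#' @param header whether the first line is a header (default TRUE).
#' @return data.frame `protein_a`, `protein_b` in canonical (sorted) order.
#' @export
readPpiTsv <- function(path, header = TRUE) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (header) lines <- lines[-1L]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad))
    stop(sprintf("%s: expected two tab-separated fields at line %d", path,
                 bad[1L] + as.integer(header)))
  a <- vapply(parts, `[`, character(1), 1L)
  b <- vapply(parts, `[`, character(1), 2L)
  selfPair <- a == b
  if (any(selfPair))
    message(sprintf("readPpiTsv: dropped %d self-pair(s)", sum(selfPair)))
  a <- a[!selfPair]; b <- b[!selfPair]
  e <- .canonPairs(a, b)
  dup <- duplicated(paste(e$protein_a, e$protein_b))
  if (any(dup))
    message(sprintf("readPpiTsv: collapsed %d duplicate pair(s)", sum(dup)))
  e <- e[!dup, , drop = FALSE]
  e <- e[order(e$protein_a, e$protein_b), , drop = FALSE]
  rownames(e) <- NULL
  e
}

#' Write a PPI edge list as TSV
#' @param edges data.frame `protein_a`, `protein_b`.
#' @param path file path.
#' @export
writePpiTsv <- function(edges, path) {
  utils::write.table(edges[, c("protein_a", "protein_b")], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a one-gene-per-line list
#' @param path file path.
#' @return character vector (deduplicated, order preserved).
#' @export
readGeneList <- function(path) {
  g <- readLines(path, warn = FALSE)
  g <- trimws(g)
  unique(g[nzchar(g)])
}

#' Write a one-gene-per-line list
#' @param genes character vector.
#' @param path file path.
#' @export
writeGeneList <- function(genes, path) {
  writeLines(genes, path)
  invisible(path)
}

# write a data.frame with comment-prefixed provenance header lines
.writeTableWithHeader <- function(df, path, header = character(0)) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(header)) writeLines(paste0("# ", header), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write correlate lists as a single TSV
#'
#' Columns: seed_id, gene_id, r, n_datasets_supporting. Ineligible seeds are
#' recorded with an `eligible` flag and no entries.
#'
#' @param clists list of [CorrelateList-class].
#' @param path file path.
#' @param header optional provenance lines written as `# ` comments.
#' @export
writeCorrelateListsTsv <- function(clists, path, header = character(0)) {
  rows <- lapply(clists, function(cl) {
    e <- entries(cl)
    if (nrow(e) == 0L)
      return(data.frame(seed_id = seedId(cl), gene_id = NA_character_,
                        r = NA_real_, n_datasets_supporting = NA_integer_,
                        eligible = eligible(cl), stringsAsFactors = FALSE))
    data.frame(seed_id = seedId(cl), gene_id = e$gene_id, r = e$r,
               n_datasets_supporting = e$n_datasets_supporting,
               eligible = TRUE, stringsAsFactors = FALSE)
  })
  .writeTableWithHeader(do.call(rbind, rows), path, header)
}

#' Write a ranked master list as TSV
#' @param ranked a [RankedMasterList-class].
#' @param path file path.
#' @param header optional provenance comment lines.
#' @export
writeMasterListTsv <- function(ranked, path, header = character(0)) {
  e <- entries(ranked)
  df <- data.frame(rank = seq_len(nrow(e)), gene_id = e$gene_id,
                   occurrence_count = e$occurrence_count,
                   stringsAsFactors = FALSE)
  .writeTableWithHeader(df, path, header)
}

#' Write a network edge list as TSV
#' @param network a [SeedNetwork-class].
#' @param path file path.
#' @param minR optional display filter: only edges with r at or above this
#'   value are exported (the analysis itself never filters beyond the list
#'   threshold).
#' @param header optional provenance comment lines.
#' @export
writeNetworkTsv <- function(network, path, minR = NULL, header = character(0)) {
  e <- networkEdges(network)
  if (!is.null(minR)) e <- e[e$r >= minR, , drop = FALSE]
  .writeTableWithHeader(e, path, header)
}

#' Write an enrichment profile (per-position walk plus summary block)
#' @param profile an [EnrichmentProfile-class].
#' @param path file path.
#' @param header optional extra provenance comment lines.
#' @export
writeProfileTsv <- function(profile, path, header = character(0)) {
  s <- c(header,
         sprintf("N=%d", profile@N), sprintf("G=%d", profile@G),
         sprintf("up_step=%.10g", profile@upStep),
         sprintf("down_step=%.10g", profile@downStep),
         sprintf("max_es=%.10g", profile@maxES),
         sprintf("max_position=%d", profile@maxPosition),
         sprintf("seed50_percent=%.10g", profile@seed50Percent),
         sprintf("perm_p=%.10g", profile@permP),
         sprintf("B=%d", profile@B))
  .writeTableWithHeader(profileTable(profile), path, s)
}
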