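#' @import methods
NULL

#' Compendium: a collection of expression datasets over a shared gene universe
#'
#' Container for a multi-dataset expression compendium. Each dataset is a
#' numeric genes x samples matrix with gene identifiers as row names; gene
#' content may differ between datasets (platform dropout), but every gene must
#' belong to the shared universe. This emulates a large co-regulation database
#' in which every seed transcript can be queried for correlated transcripts
#' across many independent experiments.
#'
#' @slot datasets named list of numeric matrices (genes x samples, row names =
#'   gene ids, unique within a dataset, at least 3 samples each).
#' @slot geneUniverse character vector of all gene identifiers, ordered.
#' @export
setClass("Compendium",
  representation(datasets = "list", geneUniverse = "character"),
  validity = function(object) {
    msg <- character()
    if (length(object@datasets) == 0L) msg <- c(msg, "no datasets")
    if (anyDuplicated(object@geneUniverse))
      msg <- c(msg, "duplicated gene ids in geneUniverse")
    for (nm in names(object@datasets)) {
      x <- object@datasets[[nm]]
      if (!is.matrix(x) || !is.numeric(x))
        msg <- c(msg, sprintf("dataset '%s' is not a numeric matrix", nm))
      else {
        if (ncol(x) < 3L)
          msg <- c(msg, sprintf("dataset '%s' has fewer than 3 samples", nm))
        if (is.null(rownames(x)) || anyDuplicated(rownames(x)))
          msg <- c(msg, sprintf("dataset '%s' has missing or duplicated gene ids", nm))
        else if (!all(rownames(x) %in% object@geneUniverse))
          msg <- c(msg, sprintf("dataset '%s' has genes outside the universe", nm))
      }
    }
    if (length(msg)) msg else TRUE
  })

#' CorrelateList: transcripts co-expressed with one seed
#'
#' Result of querying the compendium with a single seed transcript: all genes
#' whose combined Pearson correlation with the seed reaches the threshold,
#' with the number of supporting datasets. Seeds under-represented in the
#' compendium yield an ineligible (empty) list, mirroring query transcripts
#' that cannot produce a correlate table.
#'
#' @slot seedId the query gene id.
#' @slot entries data.frame with columns `gene_id`, `r`, `n_datasets_supporting`,
#'   sorted by decreasing `r`, ties by gene id; never contains the seed.
#' @slot rThreshold correlation threshold applied (signed; positive correlates only).
#' @slot eligible FALSE when the seed was too sparsely represented; entries are
#'   then empty.
#' @export
setClass("CorrelateList",
  representation(seedId = "character", entries = "data.frame",
                 rThreshold = "numeric", eligible = "logical"),
  validity = function(object) {
    msg <- character()
    e <- object@entries
    need <- c("gene_id", "r", "n_datasets_supporting")
    if (!all(need %in% names(e))) return("entries must have gene_id, r, n_datasets_supporting")
    if (object@seedId %in% e$gene_id) msg <- c(msg, "seed present in its own entries")
    if (nrow(e) && any(e$r < object@rThreshold - 1e-12))
      msg <- c(msg, "entry below rThreshold")
    if (!object@eligible && nrow(e) > 0L)
      msg <- c(msg, "ineligible list must have empty entries")
    if (nrow(e) > 1L) {
      ord <- order(-e$r, e$gene_id)
      if (!identical(ord, seq_len(nrow(e)))) msg <- c(msg, "entries not sorted")
    }
    if (length(msg)) msg else TRUE
  })

#' SeedNetwork: merged co-expression network
#'
#' Union of all eligible correlate lists: nodes are seeds and their correlates,
#' edges join a seed to each of its correlates at or above the threshold. Each
#' unordered pair appears once; if discovered from both endpoints the maximum
#' correlation is retained.
#'
#' @slot nodes character vector of gene ids.
#' @slot edges data.frame with columns `gene_a`, `gene_b`, `r` (gene_a < gene_b).
#' @slot rThreshold numeric.
#' @export
setClass("SeedNetwork",
  representation(nodes = "character", edges = "data.frame", rThreshold = "numeric"),
  validity = function(object) {
    e <- object@edges
    if (!all(c("gene_a", "gene_b", "r") %in% names(e)))
      return("edges must have gene_a, gene_b, r")
    if (nrow(e)) {
      if (any(e$gene_a == e$gene_b)) return("self edge present")
      if (any(e$gene_a > e$gene_b)) return("edges not in canonical order")
      if (anyDuplicated(paste(e$gene_a, e$gene_b))) return("duplicate edge")
    }
    TRUE
  })

#' RankedMasterList: transcripts ordered by correlate-list occurrence
#'
#' All network transcripts ranked by the number of correlate lists in which
#' they appear (most recurrent first). Ties are broken by the maximum
#' correlation observed for the gene in any list, then by gene id, so the
#' ordering is deterministic.
#'
#' @slot entries data.frame with columns `gene_id`, `occurrence_count`,
#'   `max_r`; `occurrence_count` non-increasing.
#' @export
setClass("RankedMasterList",
  representation(entries = "data.frame"),
  validity = function(object) {
    e <- object@entries
    if (!all(c("gene_id", "occurrence_count") %in% names(e)))
      return("entries must have gene_id, occurrence_count")
    if (nrow(e)) {
      if (any(diff(e$occurrence_count) > 0)) return("occurrence_count increases down the list")
      if (any(e$occurrence_count < 1L)) return("occurrence_count below 1")
      if (anyDuplicated(e$gene_id)) return("duplicated gene in master list")
    }
    TRUE
  })

#' EnrichmentProfile: running-sum enrichment of a gene class in a ranked list
#'
#' Kolmogorov-Smirnov style running sum over a ranked master list: an up-step
#' of sqrt((N-G)/G) is added at each of the G class members ("seeds") and a
#' down-step of -sqrt(G/(N-G)) at each of the N-G non-members, so the walk
#' ends at zero. The maximum of the walk is the enrichment score; everything
#' at or before the earliest maximum is the leading edge. seed50 is the
#' smallest top fraction of the list (in percent) holding half the class.
#' Permutation fields are filled by [permutationNull()].
#'
#' @slot N ranked-list length.
#' @slot G number of class members present in the list.
#' @slot upStep,downStep step scores.
#' @slot runningSum numeric vector of length N.
#' @slot maxES maximum enrichment score.
#' @slot maxPosition earliest position attaining maxES.
#' @slot leadingEdge gene ids at positions 1..maxPosition.
#' @slot seed50Percent percent of the list holding >= ceiling(G/2) members.
#' @slot permP permutation p-value (NA until computed).
#' @slot nullMaxES max enrichment scores of the permutation replicates.
#' @slot B number of permutation replicates (0 until computed).
#' @slot rankedGenes the ranked gene ids.
#' @slot isSeed logical class-membership indicator along the list.
#' @export
setClass("EnrichmentProfile",
  representation(N = "integer", G = "integer", upStep = "numeric",
                 downStep = "numeric", runningSum = "numeric",
                 maxES = "numeric", maxPosition = "integer",
                 leadingEdge = "character", seed50Percent = "numeric",
                 permP = "numeric", nullMaxES = "numeric", B = "integer",
                 rankedGenes = "character", isSeed = "logical"),
  validity = function(object) {
    msg <- character()
    if (length(object@runningSum) != object@N) msg <- c(msg, "runningSum length != N")
    if (object@G <= 0L || object@G >= object@N) msg <- c(msg, "need 0 < G < N")
    if (abs(object@upStep * abs(object@downStep) - 1) > 1e-9)
      msg <- c(msg, "step scores do not satisfy up * |down| = 1")
    if (abs(object@runningSum[object@N]) > 1e-6 * object@upStep)
      msg <- c(msg, "running sum does not return to zero")
    if (length(msg)) msg else TRUE
  })

#' ContingencyResult: a 2x2 table with its enrichment statistic
#'
#' @slot table 2x2 integer matrix (rows: in/out of the focal set; columns:
#'   flagged/unflagged).
#' @slot statistic test statistic (NA for exact tests).
#' @slot pValue p-value in (0, 1].
#' @slot method one of "fisher_one_sided_greater", "chi_square", "ease".
#' @slot oddsRatio sample odds ratio ad/bc (may be Inf or NA on zero cells).
#' @export
setClass("ContingencyResult",
  representation(table = "matrix", statistic = "numeric", pValue = "numeric",
                 method = "character", oddsRatio = "numeric"),
  validity = function(object) {
    msg <- character()
    if (!identical(dim(object@table), c(2L, 2L))) msg <- c(msg, "table must be 2x2")
    if (any(object@table < 0)) msg <- c(msg, "negative cell")
    if (is.na(object@pValue) || object@pValue <= 0 || object@pValue > 1)
      msg <- c(msg, "pValue must lie in (0,1]")
    if (!object@method %in% c("fisher_one_sided_greater", "chi_square", "ease"))
      msg <- c(msg, "unknown method")
    if (length(msg)) msg else TRUE
  })

#' SimTruth: planted ground truth of a synthetic compendium
#'
#' @slot moduleMembership named character vector over the gene universe;
#'   NA for background genes.
#' @slot seedSet designated seed genes (subset of the seed module).
#' @slot regulatorResponsiveSet planted regulator-responsive genes.
#' @slot ppiEdges data.frame `protein_a`, `protein_b` (canonical order, no
#'   self pairs).
#' @slot pathwayAnnotations named list of gene-id vectors.
#' @slot rngSeed integer seed the truth was generated under.
#' @export
setClass("SimTruth",
  representation(moduleMembership = "character", seedSet = "character",
                 regulatorResponsiveSet = "character", ppiEdges = "data.frame",
                 pathwayAnnotations = "list", rngSeed = "integer"),
  validity = function(object) {
    msg <- character()
    uni <- names(object@moduleMembership)
    if (is.null(uni)) return("moduleMembership must be named by gene id")
    if (!all(object@seedSet %in% uni)) msg <- c(msg, "seedSet outside universe")
    if (nrow(object@ppiEdges) &&
        any(object@ppiEdges$protein_a == object@ppiEdges$protein_b))
      msg <- c(msg, "self pair in ppiEdges")
    bad <- vapply(object@pathwayAnnotations, function(g) !all(g %in% uni), logical(1))
    if (any(bad)) msg <- c(msg, "annotation genes outside universe")
    if (length(msg)) msg else TRUE
  })

#' CompartmentPanel: enrichment profiles for several seed sets
#'
#' @slot compartments named list; each element has `seeds` (gene ids) and
#'   `profile` (an [EnrichmentProfile-class]).
#' @slot ordering compartment names sorted by ascending seed50.
#' @slot skipped names of compartments with fewer than 2 eligible seeds.
#' @export
setClass("CompartmentPanel",
  representation(compartments = "list", ordering = "character",
                 skipped = "character"),
  validity = function(object) {
    if (!all(object@ordering %in% names(object@compartments)))
      return("ordering names not among compartments")
    TRUE
  })
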