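#' @include AllClasses.R AllGenerics.R
NULL

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with its default:
#' correlation threshold 0.5 (signed; positive correlates only), at least 3
#' shared datasets per pair, seed eligibility at 25% dataset presence, a
#' 23,000-gene genome, 1,000 permutation walks, above-chance significance at
#' 1e-4, EASE threshold 0.05, and interaction-partner thresholds 1, 2, 5, 10.
#' The configuration is echoed into every artifact header for provenance.
#'
#' @param rThreshold correlation threshold.
#' @param minSharedDatasets minimum qualifying datasets per gene pair.
#' @param minPresenceFraction seed-eligibility presence fraction.
#' @param genomeSize genome size for contingency denominators.
#' @param BPermutations permutation replicates.
#' @param alphaChance per-seed above-chance significance level.
#' @param alphaEase per-term EASE threshold.
#' @param partnerThresholds interaction-count thresholds to sweep.
#' @param rngSeed integer seed governing all pipeline randomness.
#' @return list of class `pipelineConfig`.
#' @export
pipelineConfig <- function(rThreshold = 0.5, minSharedDatasets = 3L,
                           minPresenceFraction = 0.25, genomeSize = 23000L,
                           BPermutations = 1000L, alphaChance = 1e-4,
                           alphaEase = 0.05, partnerThresholds = c(1L, 2L, 5L, 10L),
                           rngSeed = 1L) {
  structure(list(rThreshold = rThreshold,
                 minSharedDatasets = .assertCount(minSharedDatasets, "minSharedDatasets"),
                 minPresenceFraction = .assertFraction(minPresenceFraction, "minPresenceFraction"),
                 genomeSize = .assertCount(genomeSize, "genomeSize"),
                 BPermutations = .assertCount(BPermutations, "BPermutations"),
                 alphaChance = alphaChance, alphaEase = alphaEase,
                 partnerThresholds = as.integer(partnerThresholds),
                 rngSeed = as.integer(rngSeed)),
            class = "pipelineConfig")
}

.configHeader <- function(config) {
  c(sprintf("seedcoex version %s", as.character(utils::packageVersion("seedcoex"))),
    vapply(names(unclass(config)), function(k)
      sprintf("%s=%s", k, paste(format(config[[k]]), collapse = ",")),
      character(1)))
}

#' Run the full seed-centric co-expression analysis end to end
#'
#' Executes correlate-list construction, network assembly, master-list
#' ranking, running-sum enrichment with permutation null, leading-edge
#' cross-referencing (per-seed above-chance counts, regulator-responsive
#' chi-square with and without seed removal, MC+/MC- interaction Fisher
#' sweep), and guilt-by-association candidate prioritization. Each stage
#' writes a tab-separated artifact with a provenance header and logs its
#' record counts. Deterministic given `config$rngSeed`.
#'
#' @param compendium a [Compendium-class].
#' @param seeds seed gene ids (the annotated compartment set).
#' @param config a [pipelineConfig()].
#' @param outDir output directory (created if needed); NULL skips writing.
#' @param responsiveSet optional regulator-responsive gene ids.
#' @param ppi optional PPI edge data.frame (`protein_a`, `protein_b`).
#' @param moduleGenes optional disease-module gene list for prioritization.
#' @param termAnnotations optional named list of pathway term gene sets.
#' @param requiredTerms term ids each candidate must be enriched for.
#' @param verbose log per-stage record counts (default TRUE).
#' @return (invisibly) list with the stage results: `correlateLists`,
#'   `network`, `ranked`, `profile`, `aboveChance`, `leChisq`,
#'   `leChisqSeedRemoved`, `ppiFets`, `candidates`, `artifacts`.
#' @export
runPipeline <- function(compendium, seeds, config = pipelineConfig(),
                        outDir = NULL, responsiveSet = NULL, ppi = NULL,
                        moduleGenes = NULL, termAnnotations = NULL,
                        requiredTerms = character(0), verbose = TRUE) {
  stopifnot(inherits(config, "pipelineConfig"))
  log <- function(fmt, ...) if (verbose) message(sprintf(fmt, ...))
  hdr <- .configHeader(config)
  artifacts <- character(0)
  keep <- function(name, path) { artifacts[name] <<- path; path }
  if (!is.null(outDir)) dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  seeds <- intersect(seeds, geneUniverse(compendium))
  cls <- correlateLists(compendium, seeds, rThreshold = config$rThreshold,
                        minSharedDatasets = config$minSharedDatasets,
                        minPresenceFraction = config$minPresenceFraction)
  nEl <- sum(vapply(cls, eligible, logical(1)))
  log("correlate: %d seeds queried, %d eligible", length(cls), nEl)
  if (nEl == 0L) stop("pipeline stage 'correlate': no eligible seeds")
  if (!is.null(outDir))
    writeCorrelateListsTsv(cls, keep("correlate_lists",
                                     file.path(outDir, "correlate_lists.tsv")), hdr)

  net <- assembleNetwork(cls)
  log("network: %d nodes, %d edges", length(networkNodes(net)),
      nrow(networkEdges(net)))
  if (!is.null(outDir))
    writeNetworkTsv(net, keep("network", file.path(outDir, "network_edges.tsv")),
                    header = hdr)

  ranked <- rankedMasterList(cls)
  log("master list: %d ranked transcripts", nrow(entries(ranked)))
  if (!is.null(outDir))
    writeMasterListTsv(ranked, keep("master_list",
                                    file.path(outDir, "master_list.tsv")), hdr)

  prof <- permutationNull(ranked, seeds, B = config$BPermutations,
                          rngSeed = config$rngSeed)
  log("enrichment: max ES %.4g at %d/%d, seed50 %.3g%%, perm p %.4g",
      maxES(prof), maxPosition(prof), prof@N, seed50(prof), permP(prof))
  if (!is.null(outDir))
    writeProfileTsv(prof, keep("profile", file.path(outDir, "enrichment_profile.tsv")),
                    hdr)

  above <- countAboveChance(cls, seeds, config$genomeSize, config$alphaChance)
  log("above-chance: %d/%d seeds (%.1f%%)", above$count, above$eligible,
      100 * above$fraction)

  le <- leadingEdge(prof)
  uni <- geneUniverse(compendium)
  leChisq <- leChisqNoSeeds <- NULL
  if (!is.null(responsiveSet)) {
    leChisq <- leFlagChisq(le, responsiveSet, uni)
    leChisqNoSeeds <- leFlagChisq(le, responsiveSet, uni, exclude = seeds)
    log("LE responsive chi-square: p %.4g (all), p %.4g (seeds removed)",
        pValue(leChisq), pValue(leChisqNoSeeds))
  }

  ppiFets <- NULL
  if (!is.null(ppi)) {
    flt <- ppiMcFilter(ppi, seeds)
    log("PPI filter: %d/%d edges retained, %d MC- proteins with partners",
        nrow(flt$keptEdges), nrow(ppi), length(flt$partnership))
    ppiFets <- lapply(config$partnerThresholds, function(th)
      mcMinusLeFet(flt$partnership, le, uni, th))
    names(ppiFets) <- paste0("min_partners_", config$partnerThresholds)
    for (i in seq_along(ppiFets))
      log("PPI FET %s: OR %.3g, p %.4g", names(ppiFets)[i],
          oddsRatio(ppiFets[[i]]), pValue(ppiFets[[i]]))
  }

  cands <- NULL
  if (!is.null(moduleGenes) && !is.null(termAnnotations) &&
      length(requiredTerms)) {
    rec <- recurrentCandidates(le, moduleGenes)
    log("prioritize: %d recurrent candidates", length(rec))
    reports <- lapply(rec, function(g)
      guiltByAssociation(compendium, g, termAnnotations, requiredTerms,
                         genomeSize = config$genomeSize,
                         alpha = config$alphaEase,
                         rThreshold = config$rThreshold,
                         minSharedDatasets = config$minSharedDatasets,
                         minPresenceFraction = config$minPresenceFraction))
    cands <- selectCandidates(reports, alpha = config$alphaEase)
    log("prioritize: %d candidates pass all required terms", length(cands))
    if (!is.null(outDir))
      .writeTableWithHeader(candidateTable(cands),
                            keep("candidates", file.path(outDir, "candidates.tsv")),
                            hdr)
  }

  invisible(list(correlateLists = cls, network = net, ranked = ranked,
                 profile = prof, aboveChance = above, leChisq = leChisq,
                 leChisqSeedRemoved = leChisqNoSeeds, ppiFets = ppiFets,
                 candidates = cands, artifacts = artifacts))
}
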