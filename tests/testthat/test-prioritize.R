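# candidate prioritization: intersection, guilt-by-association, ranking

test_that("recurrent candidates are the plain set intersection", {
  expect_length(recurrentCandidates(c("A", "B"), c("C", "D")), 0)
  expect_setequal(recurrentCandidates(c("A", "B"), c("B", "A")), c("A", "B"))
  expect_setequal(recurrentCandidates(c("A", "B", "C"), c("B", "C", "D")),
                  c("B", "C"))
  # commutative and idempotent
  expect_identical(recurrentCandidates(c("A", "B", "C"), c("B", "C", "D")),
                   recurrentCandidates(c("B", "C", "D"), c("A", "B", "C")))
  expect_identical(recurrentCandidates(c("B", "C"), c("B", "C")), c("B", "C"))
})

test_that("zero term overlap gives EASE p = 1 and a failing report", {
  sim <- strongModuleSim(nGenes = 60, moduleSize = 8, loadingMean = 1,
                         loadingSd = 0, noiseSd = 0.1, nDatasets = 3,
                         samples = 20, rngSeed = 61)
  mod <- names(which(!is.na(moduleMembership(sim$truth))))
  terms <- list(T1 = c("g00059", "g00060"))  # background genes, no overlap
  rp <- guiltByAssociation(sim$compendium, mod[1], terms, "T1",
                           genomeSize = 60)
  expect_equal(rp$termScores$ease_p, 1)
  expect_equal(rp$termScores$neglog10_p, 0)
  expect_false(rp$passes)
})

test_that("reported EASE values re-verify against the brute-force oracle", {
  sim <- strongModuleSim(nGenes = 80, moduleSize = 10, loadingMean = 1,
                         loadingSd = 0, noiseSd = 0.2, nDatasets = 3,
                         samples = 20, rngSeed = 62)
  mod <- names(which(!is.na(moduleMembership(sim$truth))))
  terms <- list(T1 = mod, T2 = c(mod[1:5], paste0("g000", 71:79)))
  rp <- guiltByAssociation(sim$compendium, mod[1], terms, c("T1", "T2"),
                           genomeSize = 80)
  for (i in seq_len(nrow(rp$termScores))) {
    row <- rp$termScores[i, ]
    kj <- max(row$k - 1, 0)
    oracle <- if (row$k == 0) 1 else
      bruteFisherGreater(kj, row$n - row$k, row$K - kj,
                         row$M - (row$n - 1) - (row$K - kj))
    expect_equal(row$ease_p, oracle, tolerance = 1e-9)
  }
})

test_that("ineligible candidates yield a failing report with a reason code", {
  sim <- strongModuleSim(rngSeed = 63)
  comp <- sim$compendium
  gene <- geneUniverse(comp)[1]
  dats <- lapply(datasets(comp), function(X) X[rownames(X) != gene, , drop = FALSE])
  comp0 <- new("Compendium", datasets = dats, geneUniverse = geneUniverse(comp))
  rp <- guiltByAssociation(comp0, gene, list(T1 = "g00002"), "T1")
  expect_false(rp$passes)
  expect_identical(rp$reason, "ineligible_candidate")
})

test_that("selection keeps passers, ranks by summed -log10 p, breaks ties by id", {
  mkReport <- function(id, ps) {
    ts <- data.frame(term_id = paste0("T", seq_along(ps)), ease_p = ps,
                     neglog10_p = -log10(ps), k = 5L, n = 10L, K = 10L,
                     M = 100L, stringsAsFactors = FALSE)
    list(candidateId = id, termScores = ts, passes = all(ps <= 0.05),
         rankScore = sum(-log10(ps)), reason = "ok")
  }
  a <- mkReport("a", c(1e-3, 1e-3))   # rank score 6
  b <- mkReport("b", c(1e-2, 1e-2))   # rank score 4
  fail <- mkReport("z", c(0.5, 1e-6))
  sel <- selectCandidates(list(fail, b, a))
  expect_equal(vapply(sel, `[[`, character(1), "candidateId"), c("a", "b"))
  expect_equal(sel[[1]]$rankScore, 6, tolerance = 1e-9)
  # invariant to input order
  sel2 <- selectCandidates(list(a, fail, b))
  expect_identical(vapply(sel2, `[[`, character(1), "candidateId"),
                   vapply(sel, `[[`, character(1), "candidateId"))
  # ties broken by ascending id
  tie1 <- mkReport("m", c(1e-2, 1e-2))
  tie2 <- mkReport("k", c(1e-2, 1e-2))
  selT <- selectCandidates(list(tie1, tie2))
  expect_equal(vapply(selT, `[[`, character(1), "candidateId"), c("k", "m"))
  expect_length(selectCandidates(list(fail)), 0)
  # min-based combination available behind a flag
  selMin <- selectCandidates(list(a, b), method = "min")
  expect_equal(selMin[[1]]$rankScore, 3, tolerance = 1e-9)
})

test_that("increasing term overlap never decreases the rank score", {
  ps <- vapply(1:9, function(k) pValue(easeScore(k, 10, 20, 200)), numeric(1))
  scores <- -log10(ps)
  expect_true(all(diff(scores) >= -1e-12))
})
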