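# synthetic-compendium generator: planted structure, determinism, dropout

test_that("noise-free common factor makes within-module pairs perfectly correlated", {
  sim <- strongModuleSim(nGenes = 30, moduleSize = 10, loadingMean = 1,
                         loadingSd = 0, noiseSd = 1e-9, nDatasets = 2,
                         samples = 15, rngSeed = 11)
  X <- datasets(sim$compendium)[[1]]
  mod <- names(moduleMembership(sim$truth))[!is.na(moduleMembership(sim$truth))]
  for (pair in list(c(1, 2), c(3, 7), c(5, 10))) {
    r <- cor(X[mod[pair[1]], ], X[mod[pair[2]], ])
    expect_equal(r, 1.0, tolerance = 1e-6)
  }
})

test_that("identical rng seed reproduces identical matrices; different seeds differ", {
  a <- strongModuleSim(rngSeed = 42)
  b <- strongModuleSim(rngSeed = 42)
  c <- strongModuleSim(rngSeed = 43)
  expect_identical(datasets(a$compendium), datasets(b$compendium))
  expect_identical(seedSet(a$truth), seedSet(b$truth))
  expect_false(identical(datasets(a$compendium), datasets(c$compendium)))
})

test_that("null compendium matches a Monte-Carlo oracle for the |r| >= 0.5 tail", {
  nSamples <- 20
  sim <- simulateCompendium(simParams(
    nDatasets = 1, samplesPerDataset = nSamples, nGenes = 2000,
    moduleSpecs = data.frame(module_id = "m1", size = 10, loading_mean = 0,
                             loading_sd = 0),
    noiseSd = 1, rngSeed = 5))
  X <- datasets(sim$compendium)[[1]]
  # disjoint pairs so the indicator draws are independent
  idx <- matrix(seq_len(2000), ncol = 2, byrow = TRUE)
  robs <- vapply(seq_len(nrow(idx)), function(i)
    cor(X[idx[i, 1], ], X[idx[i, 2], ]), numeric(1))
  pObs <- mean(abs(robs) >= 0.5)
  # independent Monte-Carlo oracle on the null Pearson distribution
  set.seed(99)
  nOracle <- 10000
  rNull <- vapply(seq_len(nOracle), function(i)
    cor(rnorm(nSamples), rnorm(nSamples)), numeric(1))
  pOracle <- mean(abs(rNull) >= 0.5)
  se <- sqrt(pOracle * (1 - pOracle) * (1 / nrow(idx) + 1 / nOracle))
  expect_lt(abs(pObs - pOracle), 3 * se)
})

test_that("dropout marks the expected fraction of gene-dataset pairs absent", {
  frac <- 0.3
  sim <- strongModuleSim(nGenes = 500, nDatasets = 10, samples = 5,
                         noiseSd = 1, dropout = frac, rngSeed = 21)
  present <- sum(vapply(datasets(sim$compendium), nrow, integer(1)))
  total <- 500 * 10
  pAbsent <- 1 - present / total
  se <- sqrt(frac * (1 - frac) / total)
  expect_lt(abs(pAbsent - frac), 3 * se)
})

test_that("parameter validation rejects inconsistent simulation settings", {
  ms <- data.frame(module_id = "m1", size = 200, loading_mean = 1, loading_sd = 0)
  expect_error(simParams(2, 10, 100, ms), "exceed")
  ms$size <- 10
  expect_error(simParams(2, 10, 100, ms, noiseSd = 0), "noiseSd")
  expect_error(simParams(2, 10, 100, ms, dropoutFraction = 1), "dropoutFraction")
})

test_that("planted PPI edges follow the within/between inclusion rules", {
  sim <- strongModuleSim(nGenes = 20, moduleSize = 4, rngSeed = 3)
  truth <- sim$truth
  # complete within-module graph, nothing else
  t1 <- simulatePPI(truth, pWithin = 1, pBetween = 0, rngSeed = 1)
  expect_equal(nrow(ppiEdges(t1)), 6)  # choose(4, 2)
  mm <- moduleMembership(truth)
  expect_true(all(!is.na(mm[ppiEdges(t1)$protein_a])))
  expect_true(all(!is.na(mm[ppiEdges(t1)$protein_b])))
  # empty graph
  t0 <- simulatePPI(truth, pWithin = 0, pBetween = 0, rngSeed = 1)
  expect_equal(nrow(ppiEdges(t0)), 0)
  # determinism and no self/duplicate pairs
  t2 <- simulatePPI(truth, pWithin = 0.7, pBetween = 0.05, rngSeed = 9)
  t3 <- simulatePPI(truth, pWithin = 0.7, pBetween = 0.05, rngSeed = 9)
  expect_identical(ppiEdges(t2), ppiEdges(t3))
  e <- ppiEdges(t2)
  expect_true(all(e$protein_a != e$protein_b))
  expect_false(anyDuplicated(paste(e$protein_a, e$protein_b)) > 0)
})

test_that("between-module PPI edge count matches the binomial oracle", {
  # 50 module genes in pairs-free background: between pairs ~ Binomial
  sim <- strongModuleSim(nGenes = 47, moduleSize = 2, rngSeed = 13)
  # non-module pairs: choose(47,2) - 1 = 1080 >= 1000
  nBetween <- choose(47, 2) - 1
  p <- 0.05
  counts <- vapply(1:30, function(s) {
    t <- simulatePPI(sim$truth, pWithin = 1, pBetween = p, rngSeed = s)
    nrow(ppiEdges(t)) - 1L   # subtract the single within edge
  }, numeric(1))
  expSE <- sqrt(nBetween * p * (1 - p))
  expect_lt(abs(mean(counts) - nBetween * p), 3 * expSE / sqrt(30))
})

test_that("planted annotations hit the module and background at their rates", {
  sim <- strongModuleSim(nGenes = 1000, moduleSize = 100, rngSeed = 17)
  truth <- sim$truth
  # degenerate rates select exactly the module / nothing
  tAll <- simulateAnnotations(truth, 1, 0, rngSeed = 1)
  mm <- moduleMembership(truth)
  expect_setequal(regulatorResponsiveSet(tAll), names(mm)[!is.na(mm)])
  tNone <- simulateAnnotations(truth, 0, 0, rngSeed = 1)
  expect_length(regulatorResponsiveSet(tNone), 0)
  # binomial oracle at (0.8, 0.05): expect ~(80, 45)
  tMix <- simulateAnnotations(truth, 0.8, 0.05, rngSeed = 23)
  resp <- regulatorResponsiveSet(tMix)
  inMod <- sum(resp %in% names(mm)[!is.na(mm)])
  inBg <- length(resp) - inMod
  expect_lt(abs(inMod - 80), 3 * sqrt(100 * 0.8 * 0.2))
  expect_lt(abs(inBg - 45), 3 * sqrt(900 * 0.05 * 0.95))
  # pathway terms obey per-term rates and unknown modules error
  tTerm <- simulateAnnotations(truth, 0, 0,
    terms = data.frame(term_id = "T1", module_fraction = 1,
                       background_fraction = 0), rngSeed = 2)
  expect_setequal(pathwayAnnotations(tTerm)$T1, names(mm)[!is.na(mm)])
  expect_error(simulateAnnotations(truth, 0, 0,
    terms = data.frame(term_id = "T1", module_fraction = 1,
                       background_fraction = 0, module_id = "nope"),
    rngSeed = 2), "unknown module")
})
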