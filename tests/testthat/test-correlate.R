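# correlation engine: pairwise combined Pearson r and correlate lists

test_that("identical and negated expression vectors give r of +1 and -1", {
  base <- matrix(rnorm(5 * 10), 5, 10,
                 dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  X1 <- rbind(base, A = base[1, ] * 2 + 3, B = -base[1, ])
  X2 <- X1 + 0  # second dataset with the same structure
  comp <- compendiumFromMatrices(d1 = X1, d2 = X2)
  up <- pairwiseCorrelation(comp, "g1", "A", minSharedDatasets = 1)
  dn <- pairwiseCorrelation(comp, "g1", "B", minSharedDatasets = 1)
  expect_true(up$defined)
  expect_equal(up$r, 1.0, tolerance = 1e-9)
  expect_equal(dn$r, -1.0, tolerance = 1e-9)
})

test_that("single-dataset combined r equals the textbook Pearson formula", {
  a <- c(1, 2, 3, 4, 5)
  b <- c(2, 1, 4, 3, 6)
  X <- rbind(a = a, b = b)
  colnames(X) <- paste0("s", 1:5)
  comp <- compendiumFromMatrices(d1 = X)
  got <- pairwiseCorrelation(comp, "a", "b", minSharedDatasets = 1)
  # independent direct evaluation of the formula
  num <- sum((a - mean(a)) * (b - mean(b)))
  den <- sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(got$r, num / den, tolerance = 1e-12)
  expect_equal(got$nDatasets, 1L)
})

test_that("pairwise correlation is symmetric and errors on unknown genes", {
  sim <- strongModuleSim(rngSeed = 2)
  comp <- sim$compendium
  ab <- pairwiseCorrelation(comp, "g00001", "g00020", minSharedDatasets = 1)
  ba <- pairwiseCorrelation(comp, "g00020", "g00001", minSharedDatasets = 1)
  expect_identical(ab$r, ba$r)
  expect_error(pairwiseCorrelation(comp, "nope", "g00001"), "not in universe")
})

test_that("constant genes yield an undefined result with a distinct reason", {
  X <- rbind(flat = rep(1, 8), g2 = rnorm(8))
  colnames(X) <- paste0("s", 1:8)
  comp <- compendiumFromMatrices(d1 = X)
  got <- pairwiseCorrelation(comp, "flat", "g2", minSharedDatasets = 1)
  expect_false(got$defined)
  expect_identical(got$reason, "constant_gene")
  few <- pairwiseCorrelation(comp, "flat", "g2", minSharedDatasets = 2)
  expect_false(few$defined)
})

test_that("Fisher-z combination weights datasets by sample size", {
  set.seed(7)
  mk <- function(n, target) {
    x <- rnorm(n)
    noise <- rnorm(n)
    noise <- residuals(lm(noise ~ x))
    y <- target * scale(x)[, 1] + sqrt(1 - target^2) * scale(noise)[, 1]
    rbind(a = x, b = y)
  }
  X1 <- mk(10, 0.9); colnames(X1) <- paste0("s", 1:10)
  X2 <- mk(40, 0.2); colnames(X2) <- paste0("s", 1:40)
  comp <- compendiumFromMatrices(d1 = X1, d2 = X2)
  got <- pairwiseCorrelation(comp, "a", "b", minSharedDatasets = 1)
  r1 <- cor(X1["a", ], X1["b", ])
  r2 <- cor(X2["a", ], X2["b", ])
  manual <- tanh((atanh(r1) * 7 + atanh(r2) * 37) / 44)
  expect_equal(got$r, manual, tolerance = 1e-12)
  # combined estimate sits between the per-dataset values
  expect_true(got$r > min(r1, r2) && got$r < max(r1, r2))
})

test_that("a noise-free planted module yields the other module genes at r ~ 1", {
  sim <- strongModuleSim(nGenes = 50, moduleSize = 10, loadingMean = 1,
                         loadingSd = 0, noiseSd = 1e-9, nDatasets = 3,
                         samples = 15, rngSeed = 4)
  mod <- names(which(!is.na(moduleMembership(sim$truth))))
  cl <- correlateList(sim$compendium, mod[1])
  expect_true(eligible(cl))
  expect_setequal(entries(cl)$gene_id, setdiff(mod, mod[1]))
  expect_true(all(abs(entries(cl)$r - 1) < 1e-6))
})

test_that("threshold semantics: strong anticorrelates are excluded, seed never listed", {
  base <- rnorm(12)
  X <- rbind(seed = base, pos = base + rnorm(12, 0, 0.01),
             neg = -base + rnorm(12, 0, 0.01), bg = rnorm(12))
  colnames(X) <- paste0("s", 1:12)
  comp <- compendiumFromMatrices(d1 = X, d2 = X, d3 = X)
  cl <- correlateList(comp, "seed", rThreshold = 0.5)
  expect_true("pos" %in% entries(cl)$gene_id)
  expect_false("neg" %in% entries(cl)$gene_id)   # |r| ~ 0.9 but negative
  expect_false("seed" %in% entries(cl)$gene_id)
})

test_that("seed absent from enough datasets is ineligible with empty entries", {
  sim <- strongModuleSim(rngSeed = 5)
  comp <- sim$compendium
  # remove the seed from every dataset
  seed <- seedSet(sim$truth)[1]
  dats <- lapply(datasets(comp), function(X) X[rownames(X) != seed, , drop = FALSE])
  comp0 <- new("Compendium", datasets = dats, geneUniverse = geneUniverse(comp))
  cl <- correlateList(comp0, seed)
  expect_false(eligible(cl))
  expect_equal(nrow(entries(cl)), 0)
})

test_that("lowering the threshold never shrinks a correlate list", {
  sim <- strongModuleSim(noiseSd = 1, loadingMean = 0.7, rngSeed = 6)
  seed <- seedSet(sim$truth)[1]
  sizes <- vapply(c(0.9, 0.7, 0.5, 0.3, 0.1), function(th)
    nrow(entries(correlateList(sim$compendium, seed, rThreshold = th))),
    numeric(1))
  expect_true(all(diff(sizes) >= 0))
})
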