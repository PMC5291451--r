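# leading-edge cross-referencing: above-chance tests, flag chi-square, PPI

test_that("expected by-chance fraction follows from the reference set and genome", {
  cl <- makeCorrelateList("s", paste0("g", 1:10))
  got <- perSeedChanceTest(cl, seedUniverse = paste0("m", 1:1500),
                           genomeSize = 23000)
  expect_equal(got$expectedFraction, 1500 / 23000, tolerance = 1e-12)
  expect_equal(round(100 * got$expectedFraction), 7)
  # zero reference members in the list: never above chance
  expect_false(got$aboveChance)
  expect_equal(got$observedFraction, 0)
})

test_that("a reference-dense correlate list is called above chance with an oracle-checked p", {
  mpets <- paste0("m", 1:1500)
  listGenes <- c(paste0("m", 1:50), paste0("x", 1:50))  # 50% vs 7% expected
  cl <- makeCorrelateList("s", listGenes)
  got <- perSeedChanceTest(cl, mpets, genomeSize = 23000)
  expect_true(got$aboveChance)
  a <- 50; b <- 50; c <- 1450; d <- 23000 - 100 - 1450
  expect_equal(pValue(got$result), bruteFisherGreater(a, b, c, d),
               tolerance = 1e-9)
  expect_lt(pValue(got$result), 1e-4)
})

test_that("ineligible or empty lists give p = 1 and never count above chance", {
  cl <- makeCorrelateList("s", character(0), eligible = FALSE)
  got <- perSeedChanceTest(cl, paste0("m", 1:100), genomeSize = 1000)
  expect_false(got$aboveChance)
  expect_equal(pValue(got$result), 1)
  lists <- list(makeCorrelateList("a", character(0)),
                makeCorrelateList("b", character(0)))
  cnt <- countAboveChance(lists, paste0("m", 1:100), genomeSize = 1000)
  expect_equal(cnt$count, 0)
  expect_error(countAboveChance(list(cl), paste0("m", 1:100), 1000),
               "no eligible")
})

test_that("LE flag chi-square counts match brute-force set intersection", {
  universe <- paste0("g", 1:100)
  le <- paste0("g", 1:30)
  flag <- paste0("g", c(10:40, 90:95))
  seeds <- paste0("g", 1:5)
  res <- leFlagChisq(le, flag, universe, exclude = seeds)
  u <- setdiff(universe, seeds)
  a <- length(intersect(intersect(u, le), flag))
  b <- length(setdiff(intersect(u, le), flag))
  c <- length(intersect(setdiff(u, le), flag))
  d <- length(setdiff(setdiff(u, le), flag))
  expect_equal(contingencyTable(res),
               matrix(as.integer(c(a, b, c, d)), 2, 2, byrow = TRUE))
  ref <- suppressWarnings(chisq.test(matrix(c(a, b, c, d), 2, 2, byrow = TRUE),
                                     correct = FALSE))
  expect_equal(pValue(res), ref$p.value, tolerance = 1e-9)
})

test_that("an independent flag set gives a near-zero chi-square statistic", {
  # flag assignment stratified to be exactly independent of LE membership
  universe <- paste0("g", 1:200)
  le <- universe[1:50]
  flag <- c(universe[1:10], universe[51:80])   # 20% in both strata
  res <- leFlagChisq(le, flag, universe)
  expect_equal(statistic(res), 0, tolerance = 1e-9)
})

test_that("PPI filter keeps exactly-one-annotated-endpoint edges and counts partners", {
  mc <- c("M1", "M2", "M3", "M4")
  edges <- data.frame(
    protein_a = c("M1", "M1", "P1", "P1", "P1", "P1", "P1", "P2"),
    protein_b = c("M2", "P1", "M2", "M3", "M4", "P2", "P3", "P3"),
    stringsAsFactors = FALSE)
  got <- ppiMcFilter(edges, mc)
  # M1-M2 (both annotated) and P1-P2, P1-P3, P2-P3 (neither) are dropped
  expect_equal(nrow(got$keptEdges), 4)
  # star: P1 binds M1, M2, M3, M4 -> 4 distinct annotated partners
  expect_equal(unname(got$partnership["P1"]), 4L)
  expect_setequal(names(got$partnership), "P1")
})

test_that("MC- leading-edge Fisher handles thresholds and empty retained sets", {
  partnership <- c(P1 = 5L, P2 = 2L, P3 = 1L)
  universe <- c(paste0("P", 1:3), paste0("x", 1:17))
  le <- c("P1", "P2", "x1", "x2")
  rAll <- mcMinusLeFet(partnership, le, universe, minPartners = 1)
  # brute-force table: retained = P1,P2,P3; LE = 4 genes
  expect_equal(contingencyTable(rAll),
               matrix(c(2L, 2L, 1L, 15L), 2, 2, byrow = TRUE))
  expect_equal(pValue(rAll), bruteFisherGreater(2, 2, 1, 15), tolerance = 1e-9)
  r2 <- mcMinusLeFet(partnership, le, universe, minPartners = 2)
  expect_equal(contingencyTable(r2)[1, 1], 2L)
  rEmpty <- mcMinusLeFet(partnership, le, universe, minPartners = 10)
  expect_equal(pValue(rEmpty), 1)
})

test_that("above-chance false-positive rate under a null compendium stays at alpha", {
  # no planted structure: correlate lists arise by chance only
  falsePos <- 0L
  nTests <- 0L
  for (rep in 1:4) {
    sim <- strongModuleSim(nGenes = 400, moduleSize = 20, loadingMean = 0,
                           loadingSd = 0, noiseSd = 1, nDatasets = 4,
                           samples = 12, seedFrac = 1, rngSeed = 600 + rep)
    seeds <- seedSet(sim$truth)
    cls <- correlateLists(sim$compendium, seeds, rThreshold = 0.3,
                          minSharedDatasets = 2)
    for (cl in Filter(eligible, cls)) {
      got <- perSeedChanceTest(cl, seeds, genomeSize = 400, alpha = 1e-4)
      nTests <- nTests + 1L
      if (got$aboveChance) falsePos <- falsePos + 1L
    }
  }
  alpha <- 1e-4
  bound <- nTests * alpha + 3 * sqrt(nTests * alpha * (1 - alpha))
  expect_lte(falsePos, max(bound, 1))
})
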