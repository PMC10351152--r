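test_that("low-expression filter applies the strict >10-in-10% rule", {
  m <- matrix(0L, 3, 20,
              dimnames = list(c("boundary", "under", "zero"), NULL))
  m["boundary", 1:2] <- 11L   # >10 in exactly ceiling(10%) = 2 samples
  m["under", 1:2] <- 10L      # 10 is not > 10
  kept <- suppressMessages(filterLowExpression(m))
  expect_identical(rownames(kept), "boundary")

  set.seed(42)
  r <- matrix(rpois(1200, 8), 100, 12,
              dimnames = list(sprintf("g%03d", 1:100), NULL))
  kept <- suppressMessages(filterLowExpression(r))
  expect_identical(rownames(kept), filterOracle(r))
  expect_warning(suppressMessages(filterLowExpression(matrix(1L, 2, 10))),
                 "no genes")
})

test_that("TMM factors behave for depth-only differences", {
  set.seed(1)
  s1 <- rpois(200, 50)
  m <- cbind(s1 = s1, s2 = 3L * s1)
  f <- normalizationFactors(m)
  expect_equal(unname(f), c(1, 1), tolerance = 1e-8)
  expect_equal(unname(normalizationFactors(cbind(only = s1))), 1)
  expect_error(normalizationFactors(cbind(a = s1, bad = 0L * s1)), "bad")
})

test_that("TMM matches an independent trimmed-mean computation", {
  set.seed(7)
  y <- matrix(rnbinom(400, mu = 100, size = 5), 100, 4,
              dimnames = list(NULL, paste0("s", 1:4)))
  y[1:10, 1] <- y[1:10, 1] * 8L  # composition shift in sample 1
  f <- normalizationFactors(y)
  expect_equal(prod(f)^(1 / 4), 1, tolerance = 1e-10)

  # oracle: explicit sort-and-trim against the same reference sample
  lib <- colSums(y)
  uq <- apply(sweep(y, 2, lib, "/"), 2, quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  oracle <- sapply(seq_len(ncol(y)), function(j) {
    if (j == ref) return(1)
    ok <- y[, j] > 0 & y[, ref] > 0
    pO <- y[ok, j] / lib[j]; pR <- y[ok, ref] / lib[ref]
    M <- log2(pO / pR); A <- 0.5 * log2(pO * pR)
    w <- (1 - pO) / (lib[j] * pO) + (1 - pR) / (lib[ref] * pR)
    n <- length(M)
    loM <- floor(0.3 * n) + 1; hiM <- n + 1 - loM
    loA <- floor(0.05 * n) + 1; hiA <- n + 1 - loA
    keep <- rank(M) >= loM & rank(M) <= hiM &
      rank(A) >= loA & rank(A) <= hiA
    2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  })
  oracle <- oracle / exp(mean(log(oracle)))
  expect_equal(unname(f), unname(oracle), tolerance = 1e-10)
})

test_that("TMM agrees with edgeR on a positive-count matrix", {
  skip_if_not_installed("edgeR")
  set.seed(9)
  y <- matrix(rnbinom(3000, mu = 80, size = 3) + 1L, 500, 6)
  colnames(y) <- paste0("s", 1:6)
  f <- normalizationFactors(y)
  fe <- edgeR::calcNormFactors(y, method = "TMM")
  expect_equal(unname(f), unname(fe), tolerance = 0.02)
})

test_that("dispersion estimates recover the simulated truth", {
  set.seed(3)
  groups <- rep(c("A", "B"), each = 8)
  pois <- matrix(rpois(2000 * 16, lambda = 100), 2000, 16)
  phiP <- estimateDispersion(pois, groups)
  expect_lte(median(phiP), 0.02)

  med <- sapply(1:10, function(s) {
    set.seed(100 + s)
    nb <- matrix(rnbinom(500 * 20, mu = 200, size = 1 / 0.2), 500, 20)
    median(estimateDispersion(nb, rep(c("A", "B"), each = 10)))
  })
  expect_gte(median(med), 0.1)
  expect_lte(median(med), 0.3)

  const <- rbind(rep(50L, 8), matrix(rpois(80, 50), 10, 8))
  rownames(const) <- c("flat", sprintf("v%02d", 1:10))
  phi <- estimateDispersion(const, rep(c("A", "B"), each = 4),
                            normFactors = rep(1, 8))
  expect_identical(unname(phi["flat"]), 0)
  expect_true(all(phi >= 0))
})

test_that("the NB Wald contrast is antisymmetric and validates classes", {
  se <- tinyCohort(seed = 2)
  md <- as.data.frame(colData(se))
  y <- assay(se, "counts")
  ab <- testDifferentialExpression(y, md, contrast = c("LM1", "CC"))
  ba <- testDifferentialExpression(y, md, contrast = c("CC", "LM1"))
  expect_equal(ab$logFC, -ba$logFC)
  expect_equal(ab$PValue, ba$PValue)
  expect_true(all(ab$FDR >= ab$PValue))
  expect_error(testDifferentialExpression(y, md, contrast = c("ZZ", "CC")),
               "'ZZ' absent")
})

test_that("planted effects are recovered at the printed thresholds", {
  se <- simulateCohort(cohortConfig(seed = 21))
  filt <- suppressMessages(filterLowExpression(se))
  de <- testDifferentialExpression(filt, contrast = c("LM1", "CC"))
  gs <- callDE(de, dePreset("paper"))
  truth <- groundTruth(se)
  expect_gte(mean(truth$de_up_genes %in% gs$up), 0.9)
  expect_gte(mean(truth$de_down_genes %in% gs$down), 0.9)
})

test_that("BH adjustment matches the step-up definition", {
  expect_equal(adjustPvaluesBH(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(adjustPvaluesBH(rep(0.2, 5)), rep(0.2, 5))
  expect_error(adjustPvaluesBH(c(0.5, 1.2)), "0, 1")
  set.seed(8)
  p <- runif(1000)
  expect_equal(adjustPvaluesBH(p), bhOracle(p))
  # permutation invariance up to re-indexing
  perm <- sample(1000)
  expect_equal(adjustPvaluesBH(p[perm]), adjustPvaluesBH(p)[perm])
})

test_that("DE calls use strict threshold inequalities", {
  tab <- data.frame(gene_id = sprintf("g%d", 1:6),
                    logFC = c(4.0, 4.1, -4.1, -4.0, 8, -8),
                    PValue = c(1e-5, 1e-5, 1e-5, 1e-5, 5e-4, 0.009),
                    FDR = c(1e-4, 1e-4, 1e-4, 1e-4, 0.009, 0.02))
  gs <- callDE(tab, dePreset("paper"))
  # g1/g4 sit exactly on |logFC| = 4 and are excluded by the strict '>'
  expect_identical(gs$up, c("g2", "g5"))
  expect_identical(gs$down, "g3")   # g6 fails adjusted p < 0.01
  gsRaw <- callDE(tab, dePreset("public2"))
  expect_identical(gsRaw$up, c("g2", "g5"))
  expect_identical(gsRaw$down, c("g3", "g6"))  # raw p 0.009 passes < 0.01
})

test_that("preset thresholds expand to the printed values", {
  p <- dePreset("paper")
  expect_equal(c(p$minAbsLogFC, p$pCutoff), c(4, 0.01))
  expect_identical(p$pMode, "adjusted")
  expect_equal(dePreset("public1")$pCutoff, 1e-3)
  expect_identical(dePreset("public1")$pMode, "raw")
  expect_equal(dePreset("public2")$pCutoff, 0.01)
})

test_that("sample embedding is geometric and matches a dense eigensolver", {
  se <- simulateCohort(cohortConfig(nPatients = 5, mixtureWeight = 0.5,
                                    seed = 6))
  emb <- suppressMessages(computeSampleEmbedding(se))
  cls <- as.character(colData(se)$tissue_class)
  cen <- tapply(emb[, 1], cls, mean)
  expect_true(cen["LM1"] > min(cen["CC"], cen["AL"]) &&
                cen["LM1"] < max(cen["CC"], cen["AL"]))

  # duplicated sample gets identical coordinates
  y <- assay(se, "counts")
  y2 <- cbind(y, dup = y[, 1])
  emb2 <- suppressMessages(computeSampleEmbedding(y2))
  expect_equal(unname(emb2[1, ]), unname(emb2[ncol(y2), ]), tolerance = 1e-8)

  # toy matrix against an independent eigen-decomposition
  toy <- matrix(c(5, 0, 0, 9,
                  0, 5, 9, 0,
                  2, 2, 2, 2), nrow = 4,
                dimnames = list(paste0("g", 1:4), paste0("s", 1:3)))
  embT <- suppressMessages(computeSampleEmbedding(toy, topN = 4))
  lc <- logCPM(toy)
  x <- t(lc - rowMeans(lc))
  ev <- eigen(x %*% t(x))
  oracle <- ev$vectors[, 1:2] %*% diag(sqrt(ev$values[1:2]))
  expect_equal(abs(unname(embT)), abs(oracle), tolerance = 1e-8)
})

test_that("self-contrast p-values are near-uniform", {
  se <- simulateCohort(cohortConfig(nPatients = 8, nGenes = 1000,
                                    plantedLogFC = 0, seed = 31))
  cls <- colData(se)$tissue_class
  y <- assay(se, "counts")[, cls == "CC"]
  md <- data.frame(sample_id = colnames(y),
                   tissue_class = rep(c("g1", "g2"), 4))
  y <- suppressMessages(filterLowExpression(y))
  de <- testDifferentialExpression(y, md, contrast = c("g1", "g2"))
  ks <- suppressWarnings(ks.test(de$PValue, "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("consensus mode is the intersection of the two test variants", {
  se <- tinyCohort(seed = 4)
  filt <- suppressMessages(filterLowExpression(se))
  md <- as.data.frame(colData(filt))
  y <- assay(filt, "counts")
  cons <- callDEConsensus(y, md, contrast = c("LM1", "CC"))
  tcall <- callDE(testDifferentialExpression(y, md, c("LM1", "CC")),
                  dePreset("paper"))
  ncall <- callDE(testDifferentialExpression(y, md, c("LM1", "CC"),
                                             pReference = "normal"),
                  dePreset("paper"))
  expect_setequal(cons$up, intersect(tcall$up, ncall$up))
  # the normal variant is anticonservative relative to t, so the
  # consensus coincides with the stricter t-based call set
  expect_true(all(cons$up %in% ncall$up))
  expect_true(all(tcall$up %in% ncall$up))
})
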