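test_that("GMT files parse strictly and round-trip", {
  path <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("pw1\tfirst pathway\tA\tB\tC",
               "pw2\tsecond pathway\tB\tB\tD"), path)
  db <- loadGeneSets(path)
  expect_length(db, 2)
  expect_identical(db$pw1, c("A", "B", "C"))
  expect_identical(db$pw2, c("B", "D"))  # duplicate gene deduplicated

  writeLines(c("pw1\tok\tA", "broken line"), path)
  expect_error(loadGeneSets(path), "line 2")
  writeLines(c("pw1\tx\tA", "pw1\ty\tB"), path)
  expect_error(loadGeneSets(path), "duplicate pathway")

  db151 <- simulatePathways(sprintf("g%04d", 1:500), nPathways = 151,
                            seed = 4)
  writeGeneSets(db151, path)
  back <- loadGeneSets(path)
  expect_length(back, 151)
  expect_identical(unclass(back)[1:151], unclass(db151)[1:151])
})

test_that("pathway expression filter keeps strictly more than five genes", {
  expressed <- sprintf("e%02d", 1:30)
  db <- list(five = expressed[1:5], six = expressed[1:6],
             full = expressed[1:20],
             none = c("x1", "x2", "x3", "x4", "x5", "x6", "x7"))
  class(db) <- "PathwayDB"
  kept <- filterPathways(db, expressed)
  expect_identical(names(kept), c("six", "full"))

  set.seed(2)
  rdb <- simulatePathways(sprintf("g%03d", 1:200), nPathways = 40,
                          sizeRange = c(3, 12), seed = 2)
  expr <- sample(sprintf("g%03d", 1:200), 80)
  kept <- filterPathways(rdb, expr)
  oracle <- names(rdb)[vapply(rdb, function(g) {
    hits <- 0
    for (x in g) if (x %in% expr) hits <- hits + 1
    hits > 5
  }, logical(1))]
  expect_identical(names(kept), oracle)
})

test_that("the gap statistic finds no structure in a single blob", {
  set.seed(10)
  blob <- matrix(rnorm(60, sd = 0.2), 30, 2)
  expect_equal(as.integer(gapStatisticK(blob, kMax = 4, seed = 1)), 1L)
  flat <- matrix(1, 10, 2)
  expect_equal(as.integer(gapStatisticK(flat, kMax = 3, seed = 1)), 1L)
  expect_error(gapStatisticK(blob[1:3, ], kMax = 4), "kMax")
})

test_that("the gap statistic recovers three planted blobs", {
  hits <- sapply(1:5, function(s) {
    set.seed(s)
    x <- rbind(matrix(rnorm(40, 0), 20, 2), matrix(rnorm(40, 6), 20, 2),
               matrix(rnorm(40, 12), 20, 2))
    as.integer(gapStatisticK(x, kMax = 6, seed = s))
  })
  expect_gte(sum(hits == 3), 4)
})

test_that("gap values match a brute-force computation at fixed draws", {
  x <- rbind(matrix(c(0, 0.1, 0, 0.1, 0, 0, 0.1, 0.1), 4, 2),
             matrix(c(10, 10.1, 10, 10, 10, 10.1, 10, 10.1), 4, 2))
  set.seed(99)
  draws <- lapply(1:3, function(i)
    rbind(matrix(runif(8, 0, 1), 4, 2), matrix(runif(8, 9, 10.1), 4, 2)))
  k <- gapStatisticK(x, kMax = 2, referenceDraws = draws, seed = 5)
  logW <- sapply(1:2, function(kk) log(withinSSOracle(x, kk)))
  logWref <- sapply(1:2, function(kk)
    sapply(draws, function(d) log(withinSSOracle(d, kk))))
  gapOracle <- colMeans(logWref) - logW
  seOracle <- apply(logWref, 2, sd) * sqrt(1 + 1 / 3)
  expect_equal(unname(attr(k, "gap")), unname(gapOracle), tolerance = 1e-8)
  expect_equal(unname(attr(k, "se")), unname(seOracle), tolerance = 1e-8)
  expect_equal(as.integer(k),
               if (gapOracle[1] >= gapOracle[2] - seOracle[2]) 1L else 2L)
})

test_that("gap-selected k is invariant to feature-wise rescaling", {
  set.seed(12)
  x <- rbind(matrix(rnorm(40, 0, 0.3), 20, 2),
             matrix(rnorm(40, 5, 0.3), 20, 2))
  xs <- sweep(x, 2, c(100, 0.01), "*")
  expect_equal(as.integer(gapStatisticK(x, kMax = 4, seed = 3)),
               as.integer(gapStatisticK(xs, kMax = 4, seed = 3)))
})

test_that("partition equivalence is permutation-invariant and an equivalence", {
  expect_true(partitionsEquivalent(c(0, 0, 1, 1), c(1, 1, 0, 0)))
  expect_false(partitionsEquivalent(c(0, 0, 1, 1), c(0, 1, 0, 1)))
  set.seed(6)
  for (i in 1:20) {
    a <- sample(1:3, 12, replace = TRUE)
    relab <- sample(3)[a]          # relabelled copy
    b <- sample(1:3, 12, replace = TRUE)
    expect_true(partitionsEquivalent(a, a))                  # reflexive
    expect_true(partitionsEquivalent(a, relab))              # permutation
    expect_equal(partitionsEquivalent(a, b),
                 partitionsEquivalent(b, a))                 # symmetric
    if (partitionsEquivalent(a, relab) && partitionsEquivalent(relab, b))
      expect_true(partitionsEquivalent(a, b))                # transitive
  }
})

test_that("replica stability separates structured from unstructured data", {
  set.seed(20)
  blobs <- rbind(matrix(rnorm(20, 0, 0.1), 10, 2),
                 matrix(rnorm(20, 8, 0.1), 10, 2))
  rownames(blobs) <- sprintf("s%02d", 1:20)
  res <- clusterStability(blobs, 2, nReplicas = 200, seed = 1)
  expect_equal(res$stabilityFraction, 1.0)
  expect_true(res$stable)
  expect_named(res$referencePartition, rownames(blobs))

  fr <- sapply(1:5, function(s) {
    set.seed(s)
    clusterStability(matrix(runif(400), 40, 10), 2, nReplicas = 200,
                     seed = s)$stabilityFraction
  })
  expect_lt(median(fr), 0.95)

  expect_error(clusterStability(blobs, 1), "at least 2")
  expect_error(clusterStability(matrix(1, 5, 2), 2), "distinct")
})

test_that("consensus votes follow the anchor classes and flag ties", {
  md <- data.frame(sample_id = c("cc1", "cc2", "al1", "al2"),
                   tissue_class = c("CC", "CC", "AL", "AL"))
  res <- structure(list(pathway_id = "pw", k = 2L, replicaCount = 10L,
                        stabilityFraction = 1, stable = TRUE,
                        referencePartition = c(cc1 = 1L, cc2 = 1L,
                                               al1 = 2L, al2 = 2L)),
                   class = "StabilityResult")
  cons <- consensusAssignment(list(res), md)
  expect_identical(cons$vote_string, rep("1/1", 4))
  expect_identical(cons$majority_block, c("CC", "CC", "AL", "AL"))

  # 14 stable pathways; sample lm1 clusters with liver in 12 of them
  mkres <- function(lmWithLiver) {
    part <- c(cc1 = 1L, cc2 = 1L, al1 = 2L, al2 = 2L,
              lm1 = if (lmWithLiver) 2L else 1L)
    structure(list(pathway_id = "p", k = 2L, replicaCount = 10L,
                   stabilityFraction = 1, stable = TRUE,
                   referencePartition = part), class = "StabilityResult")
  }
  md2 <- rbind(md, data.frame(sample_id = "lm1", tissue_class = "LM1"))
  results <- c(lapply(1:12, function(i) mkres(TRUE)),
               lapply(1:2, function(i) mkres(FALSE)))
  cons2 <- consensusAssignment(results, md2)
  lm <- cons2[cons2$sample_id == "lm1", ]
  expect_identical(lm$majority_block, "AL")
  expect_gt(lm$votes, 10)
  expect_identical(lm$vote_string, "12/14")

  # even split between blocks: lexicographic winner, tie flagged
  tied <- c(lapply(1:7, function(i) mkres(TRUE)),
            lapply(1:7, function(i) mkres(FALSE)))
  consT <- consensusAssignment(tied, md2)
  lmT <- consT[consT$sample_id == "lm1", ]
  expect_true(lmT$tie)
  expect_identical(lmT$majority_block, "AL")  # AL < CC lexicographically
})

test_that("pathway-level driver flags planted sample blocks as stable", {
  se <- tinyCohort(seed = 8, nGenes = 200, w = 1)
  filt <- suppressMessages(filterLowExpression(se))
  db <- simulatePathways(rownames(filt), nPathways = 4,
                         sizeRange = c(10, 20), seed = 3)
  stab <- pathwayStability(filt, db, nReplicas = 50, seed = 5)
  expect_length(stab, 4)
  expect_true(all(vapply(stab, function(s)
    s$stabilityFraction >= 0 && s$stabilityFraction <= 1, logical(1))))
})

test_that("relaxed Rand-index conservation is at least as permissive as exact", {
  set.seed(30)
  x <- rbind(matrix(rnorm(30, 0, 1.5), 15, 2),
             matrix(rnorm(30, 4, 1.5), 15, 2))
  exact <- clusterStability(x, 2, nReplicas = 100, seed = 2)
  rand <- clusterStability(x, 2, nReplicas = 100, seed = 2,
                           conservation = "rand", randThreshold = 0.9)
  expect_gte(rand$stabilityFraction, exact$stabilityFraction)
  # identical partitions have Rand index 1, so threshold 1 equals exact
  rand1 <- clusterStability(x, 2, nReplicas = 100, seed = 2,
                            conservation = "rand", randThreshold = 1)
  expect_equal(rand1$stabilityFraction, exact$stabilityFraction)
})

test_that("gap-selected k agrees with cluster::clusGap on separated blobs", {
  skip_if_not_installed("cluster")
  set.seed(41)
  x <- rbind(matrix(rnorm(30, 0, 0.3), 15, 2),
             matrix(rnorm(30, 6, 0.3), 15, 2))
  cg <- cluster::clusGap(x, FUNcluster = function(d, k)
    kmeans(d, k, nstart = 5), K.max = 4, B = 50,
    spaceH0 = "original", verbose = FALSE)
  kRef <- cluster::maxSE(cg$Tab[, "gap"], cg$Tab[, "SE.sim"],
                         method = "Tibs2001SEmax")
  expect_equal(as.integer(gapStatisticK(x, kMax = 4, seed = 7)), kRef)
})
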