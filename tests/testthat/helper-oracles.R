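# Independent brute-force oracles, written from the definitions and kept
# free of any package internals.

# Step-up FDR adjustment applied literally to the definition.
bhOracle <- function(p) {
  n <- length(p)
  ord <- order(p)
  adj <- numeric(n)
  sorted <- p[ord]
  for (i in seq_len(n)) {
    adj[i] <- min(1, min(n * sorted[i:n] / (i:n)))
  }
  out <- numeric(n)
  out[ord] <- adj
  out
}

# Double-loop low-expression filter.
filterOracle <- function(m, minCount = 10, frac = 0.10) {
  need <- ceiling(frac * ncol(m))
  keep <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    hits <- 0
    for (j in seq_len(ncol(m))) if (m[i, j] > minCount) hits <- hits + 1
    keep[i] <- hits >= need
  }
  rownames(m)[keep]
}

# Running-sum KS enrichment by explicit walk (signed max deviation;
# an exact two-sided tie counts as no enrichment).
ksOracle <- function(ranked, geneSet) {
  n <- sum(ranked %in% geneSet)
  N <- length(ranked)
  run <- 0
  hi <- lo <- 0
  for (g in ranked) {
    run <- run + if (g %in% geneSet) 1 / n else -1 / (N - n)
    if (run > hi) hi <- run
    if (run < lo) lo <- run
  }
  if (hi > -lo) hi else if (-lo > hi) lo else 0
}

# Upper-tail hypergeometric probability by pmf enumeration.
hyperOracle <- function(k, K, N, n) {
  tot <- 0
  for (x in k:min(K, n)) {
    tot <- tot + choose(K, x) * choose(N - K, n - x) / choose(N, n)
  }
  tot
}

# Minimal within-cluster sum of squares by exhaustive partition search
# (tiny n only).
withinSSOracle <- function(x, k) {
  n <- nrow(x)
  best <- Inf
  grid <- do.call(expand.grid, rep(list(seq_len(k)), n))
  for (r in seq_len(nrow(grid))) {
    lab <- as.integer(grid[r, ])
    if (length(unique(lab)) < k) next
    ss <- 0
    for (cl in unique(lab)) {
      pts <- x[lab == cl, , drop = FALSE]
      ss <- ss + sum(sweep(pts, 2, colMeans(pts), "-")^2)
    }
    if (ss < best) best <- ss
  }
  best
}

# Small well-separated cohort used by several tests.
tinyCohort <- function(seed = 1, nGenes = 300, logfc = 6, w = 0.8) {
  simulateCohort(cohortConfig(nPatients = 6, nGenes = nGenes,
                              nLiverProgram = 15, nColonProgram = 15,
                              mixtureWeight = w, plantedLogFC = logfc,
                              seed = seed))
}

fixturePath <- function(f) system.file("extdata", f, package = "LiverMetSig")

# Reference built over an arbitrary gene universe with exchangeable
# standard-normal profiles.
randomReference <- function(genes, nCompounds = 5,
                            contexts = c("ctxA", "ctxB"), seed = 1) {
  set.seed(seed)
  cols <- expand.grid(compound = sprintf("C%02d", seq_len(nCompounds)),
                      context = contexts, stringsAsFactors = FALSE)
  m <- matrix(rnorm(length(genes) * nrow(cols)), length(genes),
              dimnames = list(genes, paste(cols$compound, cols$context,
                                           sep = "|")))
  PerturbationReference(m, cols$compound, cols$context,
                        data.frame(compound = unique(cols$compound),
                                   name = unique(cols$compound),
                                   mechanism_class = "test"))
}
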