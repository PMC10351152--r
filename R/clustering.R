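#' Load gene sets from a GMT file
#'
#' Standard GMT: one pathway per line, tab-separated — id, description,
#' then genes. Duplicate genes within a line are dropped; duplicate
#' pathway ids are an error.
#'
#' @param path path to a GMT file.
#' @return A \code{PathwayDB}: named list of unique gene-id vectors with
#'   a \code{descriptions} attribute.
#' @export
loadGeneSets <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    stop("malformed GMT line ", bad[1], ": fewer than 3 fields")
  ids <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(ids))
    stop("duplicate pathway name(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  db <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(db) <- ids
  if (any(lengths(db) == 0)) stop("empty pathway after load")
  attr(db, "descriptions") <- vapply(fields, `[[`, character(1), 2)
  class(db) <- "PathwayDB"
  db
}

#' Write gene sets to a GMT file
#'
#' @param db a \code{PathwayDB}.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeGeneSets <- function(db, path) {
  desc <- attr(db, "descriptions")
  if (is.null(desc)) desc <- names(db)
  lines <- vapply(seq_along(db), function(i)
    paste(c(names(db)[i], desc[i], db[[i]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Keep pathways with enough expressed genes
#'
#' Retains the pathways with strictly more than \code{minExpressed} of
#' their members among the expressed genes.
#'
#' @param db a \code{PathwayDB}.
#' @param expressedGenes character vector of expressed gene ids.
#' @param minExpressed threshold (strict \code{>}; default keeps
#'   pathways with more than five expressed genes).
#' @return Filtered \code{PathwayDB}.
#' @export
filterPathways <- function(db, expressedGenes, minExpressed = 5) {
  if (!length(expressedGenes)) stop("expressed gene list is empty")
  nExp <- vapply(db, function(g) sum(g %in% expressedGenes), integer(1))
  keep <- nExp > minExpressed
  out <- db[keep]
  attr(out, "descriptions") <- attr(db, "descriptions")[keep]
  class(out) <- "PathwayDB"
  out
}

# k-means++ seeding followed by Lloyd iterations.
.kmeansPP <- function(x, k, iterMax = 100) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- rowSums(sweep(x, 2, x[centers[1], ], "-")^2)
    for (i in 2:k) {
      if (all(d2 == 0)) centers[i] <- sample.int(n, 1)
      else centers[i] <- sample.int(n, 1, prob = d2)
      d2 <- pmin(d2, rowSums(sweep(x, 2, x[centers[i], ], "-")^2))
    }
  }
  init <- x[centers, , drop = FALSE]
  init <- init + matrix(stats::rnorm(length(init), 0, 1e-10), nrow = k)
  suppressWarnings(stats::kmeans(x, centers = init, iter.max = iterMax,
                                 algorithm = "Lloyd"))
}

# Total within-cluster sum of squares at a given k (k = 1 allowed).
.withinSS <- function(x, k) {
  if (k == 1) return(sum(sweep(x, 2, colMeans(x), "-")^2))
  .kmeansPP(x, k)$tot.withinss
}

#' Gap-statistic choice of the number of clusters
#'
#' For k = 1..kMax computes the log within-cluster dispersion of the data
#' and of \code{nReference} uniform reference draws over the observed
#' per-feature ranges; gap(k) is the mean reference log-dispersion minus
#' the observed one. Returns the smallest k with
#' \code{gap(k) >= gap(k+1) - se(k+1)} (first-SE rule), or kMax when no
#' k qualifies. All points identical gives k = 1.
#'
#' @param data samples x features numeric matrix.
#' @param kMax largest k considered (needs at least kMax + 1 samples).
#' @param nReference number of reference draws.
#' @param seed integer seed for reference draws and K-means inits.
#' @param referenceDraws optional list of precomputed reference data sets
#'   (samples x features matrices); overrides the uniform draws, e.g. to
#'   compare against an external computation on fixed references.
#' @return Integer k, with attributes \code{gap} and \code{se} (length
#'   kMax) for inspection.
#' @export
gapStatisticK <- function(data, kMax, nReference = 50, seed = 1,
                          referenceDraws = NULL) {
  x <- as.matrix(data)
  if (nrow(x) < kMax + 1) stop("need at least kMax + 1 samples")
  if (all(apply(x, 2, function(cc) max(cc) - min(cc)) == 0))
    return(structure(1L, gap = rep(0, kMax), se = rep(0, kMax)))
  lo <- apply(x, 2, min)
  hi <- apply(x, 2, max)
  if (!is.null(referenceDraws)) nReference <- length(referenceDraws)
  .withSeed(.subSeed(seed, 6), {
    logW <- vapply(seq_len(kMax), function(k) log(.withinSS(x, k)),
                   numeric(1))
    logWref <- matrix(NA_real_, nReference, kMax)
    for (b in seq_len(nReference)) {
      ref <- if (is.null(referenceDraws))
        sapply(seq_along(lo), function(j) stats::runif(nrow(x), lo[j], hi[j]))
      else as.matrix(referenceDraws[[b]])
      logWref[b, ] <- vapply(seq_len(kMax), function(k)
        log(.withinSS(ref, k)), numeric(1))
    }
  })
  gap <- colMeans(logWref) - logW
  se <- apply(logWref, 2, stats::sd) * sqrt(1 + 1 / nReference)
  k <- kMax
  for (i in seq_len(kMax - 1)) {
    if (gap[i] >= gap[i + 1] - se[i + 1]) { k <- i; break }
  }
  structure(as.integer(k), gap = gap, se = se)
}

# Canonical form of a partition: clusters renumbered by first appearance.
.canonicalPartition <- function(labels) {
  match(labels, unique(labels))
}

#' Are two partitions identical up to label permutation?
#'
#' @param a,b cluster label vectors over the same samples (same order).
#' @return TRUE when the two label vectors induce the same partition.
#' @examples
#' partitionsEquivalent(c(0, 0, 1, 1), c(1, 1, 0, 0))  # TRUE
#' @export
partitionsEquivalent <- function(a, b) {
  stopifnot(length(a) == length(b))
  identical(.canonicalPartition(a), .canonicalPartition(b))
}

# Rand index between two partitions: agreeing pairs / all pairs.
.randIndex <- function(a, b) {
  n <- length(a)
  sameA <- outer(a, a, "==")
  sameB <- outer(b, b, "==")
  up <- upper.tri(sameA)
  mean(sameA[up] == sameB[up])
}

#' Replica-based K-means stability
#'
#' Repeats K-means \code{nReplicas} times with independent seeded
#' k-means++ initializations. The reference partition is the replica with
#' the lowest within-cluster dispersion; a replica conserves the cluster
#' composition when its partition equals the reference up to label
#' permutation (the default strict reading), or, in the relaxed mode,
#' when its Rand index with the reference is at least
#' \code{randThreshold}. The clustering is stable when the conserving
#' fraction reaches \code{conservationThreshold}.
#'
#' @param data samples x features matrix (rownames = sample ids).
#' @param k number of clusters (>= 2; needs >= k distinct points).
#' @param nReplicas number of replicas.
#' @param conservationThreshold stability cutoff on the conserving
#'   fraction.
#' @param seed integer master seed; per-replica seeds are derived from
#'   it.
#' @param pathwayId optional label carried in the result.
#' @param conservation \code{"exact"} (partition identity up to label
#'   permutation) or \code{"rand"} (Rand index mode).
#' @param randThreshold Rand-index cutoff for the relaxed mode.
#' @return List of class \code{StabilityResult}: \code{pathway_id},
#'   \code{k}, \code{replicaCount}, \code{stabilityFraction},
#'   \code{stable}, \code{referencePartition} (named integer vector).
#' @export
clusterStability <- function(data, k, nReplicas = 500,
                             conservationThreshold = 0.95, seed = 1,
                             pathwayId = NA_character_,
                             conservation = c("exact", "rand"),
                             randThreshold = 0.99) {
  conservation <- match.arg(conservation)
  x <- as.matrix(data)
  if (k < 2) stop("'k' must be at least 2")
  if (nrow(unique(x)) < k)
    stop("fewer distinct points than clusters")
  parts <- matrix(NA_integer_, nReplicas, nrow(x))
  wss <- numeric(nReplicas)
  .withSeed(.subSeed(seed, 7), {
    for (r in seq_len(nReplicas)) {
      km <- .kmeansPP(x, k)
      parts[r, ] <- .canonicalPartition(km$cluster)
      wss[r] <- km$tot.withinss
    }
  })
  ref <- which.min(wss)
  conserved <- if (conservation == "exact")
    vapply(seq_len(nReplicas), function(r)
      identical(parts[r, ], parts[ref, ]), logical(1))
  else
    vapply(seq_len(nReplicas), function(r)
      .randIndex(parts[r, ], parts[ref, ]) >= randThreshold, logical(1))
  frac <- mean(conserved)
  refPart <- parts[ref, ]
  names(refPart) <- rownames(x)
  structure(list(pathway_id = pathwayId, k = as.integer(k),
                 replicaCount = as.integer(nReplicas),
                 stabilityFraction = frac,
                 stable = frac >= conservationThreshold,
                 referencePartition = refPart),
            class = "StabilityResult")
}

#' Per-pathway feature matrix for sample clustering
#'
#' Log2-CPM of a pathway's expressed genes, each gene standardized to
#' zero mean and unit variance across samples (constant genes dropped),
#' transposed to samples x genes.
#'
#' @param counts count matrix or SummarizedExperiment.
#' @param genes the pathway's gene ids.
#' @param normFactors optional normalization factors.
#' @return samples x genes numeric matrix.
#' @export
pathwayFeatureMatrix <- function(counts, genes, normFactors = NULL) {
  y <- .countMatrix(counts)
  lc <- logCPM(y, normFactors)
  lc <- lc[rownames(lc) %in% genes, , drop = FALSE]
  if (!nrow(lc)) stop("no pathway genes present in the count matrix")
  lc <- lc - rowMeans(lc)
  sdv <- apply(lc, 1, stats::sd)
  lc <- lc[sdv > 0, , drop = FALSE] / sdv[sdv > 0]
  t(lc)
}

#' Cross-pathway consensus block assignment
#'
#' For every stable pathway, each cluster of its reference partition is
#' named by the majority anchor tissue class among its member samples
#' (ties broken by the lexicographically smallest class). Each sample
#' then votes, across all stable pathways, for the block it was assigned
#' to; the majority block and a "votes/total" record are reported.
#'
#' @param stableResults list of \code{StabilityResult}s (at least 1).
#' @param metadata data.frame/DataFrame with \code{sample_id} and
#'   \code{tissue_class} anchor labels.
#' @return data.frame with one row per sample: \code{sample_id},
#'   \code{majority_block}, \code{votes}, \code{total},
#'   \code{vote_string}, \code{tie} flag.
#' @export
consensusAssignment <- function(stableResults, metadata) {
  if (!length(stableResults)) stop("need at least one stable pathway")
  md <- as.data.frame(metadata)
  anchors <- stats::setNames(as.character(md$tissue_class),
                             as.character(md$sample_id))
  samples <- names(stableResults[[1]]$referencePartition)
  votes <- matrix(0L, length(samples), 0,
                  dimnames = list(samples, NULL))
  blockVotes <- list()
  for (res in stableResults) {
    part <- res$referencePartition[samples]
    blocks <- vapply(sort(unique(part)), function(cl) {
      members <- samples[part == cl]
      tab <- table(anchors[members])
      winners <- names(tab)[tab == max(tab)]
      sort(winners)[1]
    }, character(1))
    names(blocks) <- sort(unique(part))
    vote <- blocks[as.character(part)]
    for (s in seq_along(samples)) {
      b <- vote[s]
      blockVotes[[samples[s]]] <- c(blockVotes[[samples[s]]], b)
    }
  }
  total <- length(stableResults)
  rows <- lapply(samples, function(s) {
    tab <- table(blockVotes[[s]])
    best <- max(tab)
    winners <- sort(names(tab)[tab == best])
    data.frame(sample_id = s, majority_block = winners[1],
               votes = as.integer(best), total = total,
               vote_string = sprintf("%d/%d", best, total),
               tie = length(winners) > 1, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Pathway-level clustering stability over a cohort
#'
#' Convenience driver: for each pathway with enough expressed genes,
#' builds the sample feature matrix, selects k with the gap statistic,
#' and measures replica stability at that k.
#'
#' @param counts filtered count matrix or SummarizedExperiment.
#' @param db a \code{PathwayDB} (already filtered or not).
#' @param kMax largest k for the gap statistic.
#' @param nReplicas replicas per pathway.
#' @param conservationThreshold stability cutoff.
#' @param nReference gap-statistic reference draws.
#' @param seed integer master seed.
#' @return List of \code{StabilityResult}s, one per pathway.
#' @export
pathwayStability <- function(counts, db, kMax = 6, nReplicas = 500,
                             conservationThreshold = 0.95,
                             nReference = 50, seed = 1) {
  y <- .countMatrix(counts)
  db <- filterPathways(db, rownames(y))
  out <- vector("list", length(db))
  names(out) <- names(db)
  for (i in seq_along(db)) {
    x <- pathwayFeatureMatrix(y, db[[i]])
    k <- gapStatisticK(x, kMax = min(kMax, nrow(x) - 1),
                       nReference = nReference,
                       seed = .subSeed(seed, 100 + i))
    if (k < 2) {
      # one cluster: trivially conserved, but carries no block structure
      refPart <- stats::setNames(rep(1L, nrow(x)), rownames(x))
      out[[i]] <- structure(list(pathway_id = names(db)[i], k = 1L,
                                 replicaCount = as.integer(nReplicas),
                                 stabilityFraction = 1,
                                 stable = TRUE,
                                 referencePartition = refPart),
                            class = "StabilityResult")
    } else {
      out[[i]] <- clusterStability(x, k, nReplicas = nReplicas,
                                   conservationThreshold = conservationThreshold,
                                   seed = .subSeed(seed, 200 + i),
                                   pathwayId = names(db)[i])
    }
  }
  out
}
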