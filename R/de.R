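#' Remove genes with low expression
#'
#' Keeps the genes with more than \code{minCount} counts in at least
#' \code{ceiling(minSampleFraction * n_samples)} samples (the "> 10 counts
#' in at least 10\% of the samples" rule). The sample set is unchanged.
#'
#' @param counts count matrix (genes x samples) or SummarizedExperiment.
#' @param minCount count threshold (strict \code{>}).
#' @param minSampleFraction fraction of samples that must exceed it.
#' @return Object of the same type restricted to the retained genes; a
#'   warning is raised (not an error) if no gene survives.
#' @examples
#' m <- matrix(c(20, 20, 0, 0), 2, 2,
#'             dimnames = list(c("a", "b"), c("s1", "s2")))
#' filterLowExpression(m)
#' @export
filterLowExpression <- function(counts, minCount = 10,
                                minSampleFraction = 0.10) {
  y <- .countMatrix(counts)
  need <- ceiling(minSampleFraction * ncol(y))
  keep <- rowSums(y > minCount) >= need
  message(sprintf("low-expression filter: %d of %d genes retained",
                  sum(keep), nrow(y)))
  if (!any(keep)) warning("no genes pass the low-expression filter")
  counts[keep, , drop = FALSE]
}

#' Trimmed-mean-of-M-values normalization factors
#'
#' Per-sample scaling factors computed by trimming log-ratios (M, 30\%
#' two-sided) and log-intensities (A, 5\% two-sided) against a reference
#' sample, with precision weights, then rescaled to geometric mean 1.
#' Effective library size = total count x factor.
#'
#' @param counts count matrix (genes x samples) or SummarizedExperiment.
#' @param logratioTrim,sumTrim two-sided trim fractions for M and A.
#' @return Named numeric vector of positive factors, geometric mean 1.
#' @export
normalizationFactors <- function(counts, logratioTrim = 0.30,
                                 sumTrim = 0.05) {
  y <- .countMatrix(counts)
  lib <- colSums(y)
  if (any(lib == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(y)[lib == 0], collapse = ", "))
  if (ncol(y) == 1L) {
    f <- 1
    names(f) <- colnames(y)
    return(f)
  }
  # reference: sample whose upper-quartile CPM is closest to the mean
  uq <- apply(sweep(y, 2, lib, "/"), 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(y)), function(j) {
    if (j == ref) return(1)
    .tmmPair(y[, j], y[, ref], lib[j], lib[ref], logratioTrim, sumTrim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(y)
  f
}

# One sample against the reference: weighted trimmed mean of M values.
.tmmPair <- function(obs, ref, nO, nR, logratioTrim, sumTrim) {
  ok <- obs > 0 & ref > 0
  if (!any(ok)) return(1)
  pO <- obs[ok] / nO
  pR <- ref[ok] / nR
  M <- log2(pO / pR)
  A <- 0.5 * log2(pO * pR)
  w <- (1 - pO) / (nO * pO) + (1 - pR) / (nR * pR)
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  loM <- floor(n * logratioTrim) + 1
  hiM <- n + 1 - loM
  loA <- floor(n * sumTrim) + 1
  hiA <- n + 1 - loA
  keep <- rank(M) >= loM & rank(M) <= hiM & rank(A) >= loA & rank(A) <= hiA
  if (!any(keep)) return(1)
  2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
}

#' Method-of-moments negative-binomial dispersion
#'
#' Per-gene moment estimate of the dispersion \code{phi} (variance
#' \code{mu + phi * mu^2}) on normalized counts, pooled over groups with
#' at least two samples and shrunk toward the across-gene median.
#' Genes with no within-group variation get dispersion exactly 0.
#'
#' @param counts count matrix or SummarizedExperiment.
#' @param groups per-sample group labels.
#' @param shrink weight in [0,1] pulled toward the across-gene median.
#' @param normFactors optional normalization factors.
#' @return Named non-negative numeric vector, one entry per gene.
#' @export
estimateDispersion <- function(counts, groups, shrink = 0.3,
                               normFactors = NULL) {
  y <- .countMatrix(counts)
  groups <- as.character(groups)
  stopifnot(length(groups) == ncol(y))
  if (is.null(normFactors)) normFactors <- normalizationFactors(y)
  eff <- colSums(y) * normFactors
  q <- sweep(y, 2, mean(eff) / eff, "*")
  use <- names(which(table(groups) >= 2))
  if (!length(use)) stop("need at least one group with >= 2 samples")
  num <- den <- rep(0, nrow(y))
  varsum <- rep(0, nrow(y))
  df <- 0
  for (gset in use) {
    cols <- which(groups == gset)
    m <- rowMeans(q[, cols, drop = FALSE])
    v <- apply(q[, cols, drop = FALSE], 1, stats::var)
    wt <- length(cols) - 1
    # per-group moment estimate (v - m) / m^2, combined with df weights
    num <- num + wt * (v - m) / pmax(m, 1e-8)^2
    den <- den + wt
    varsum <- varsum + wt * v
    df <- df + wt
  }
  phi <- pmax(num / den, 0)
  med <- stats::median(phi)
  out <- (1 - shrink) * phi + shrink * med
  out[varsum == 0] <- 0  # genes constant within every group
  names(out) <- rownames(y)
  out
}

#' Negative-binomial Wald test for a two-group contrast
#'
#' Tests each gene for differential expression between two tissue classes
#' on TMM-normalized counts. The log2 fold-change is the ratio of
#' pseudo-counted normalized group means (contrast class minus reference
#' class); the statistic is the logFC over its delta-method standard
#' error under the negative-binomial variance at the shrunk
#' method-of-moments dispersion, referred to a t distribution with
#' \code{nA + nB - 2} degrees of freedom. P-values are BH-adjusted.
#'
#' @param counts count matrix or SummarizedExperiment with a counts assay
#'   (typically after \code{\link{filterLowExpression}}).
#' @param metadata data.frame/DataFrame with \code{sample_id} and
#'   \code{tissue_class} (ignored for a SummarizedExperiment, whose
#'   colData is used).
#' @param contrast length-2 character vector \code{c(A, B)}; logFC is
#'   A minus B.
#' @param dispersion optional per-gene dispersions; estimated on the two
#'   contrast groups when missing.
#' @param pseudoCount added to each normalized group mean before the log
#'   ratio (stabilizes logFC at zero counts).
#' @param pReference reference distribution for the Wald statistic:
#'   \code{"t"} (default, \code{nA + nB - 2} df, small-sample calibrated)
#'   or \code{"normal"} (the asymptotic chi-square-equivalent variant).
#' @return data.frame with columns \code{gene_id}, \code{logFC},
#'   \code{PValue}, \code{FDR}, one row per gene.
#' @seealso \code{\link{callDEConsensus}} for the two-variant consensus
#'   mode.
#' @export
testDifferentialExpression <- function(counts, metadata = NULL,
                                       contrast, dispersion = NULL,
                                       pseudoCount = 0.5,
                                       pReference = c("t", "normal")) {
  pReference <- match.arg(pReference)
  if (is(counts, "SummarizedExperiment") && is.null(metadata))
    metadata <- as.data.frame(SummarizedExperiment::colData(counts))
  y <- .countMatrix(counts)
  cls <- as.character(metadata$tissue_class)
  names(cls) <- as.character(metadata$sample_id)
  cls <- cls[colnames(y)]
  stopifnot(length(contrast) == 2L)
  for (cc in contrast) {
    n <- sum(cls == cc, na.rm = TRUE)
    if (n == 0) stop("contrast class '", cc, "' absent from the data")
    if (n < 2) stop("contrast class '", cc, "' has fewer than 2 samples")
  }
  sel <- which(cls %in% contrast)
  y <- y[, sel, drop = FALSE]
  cls <- cls[sel]
  f <- normalizationFactors(y)
  eff <- colSums(y) * f
  scale <- mean(eff) / eff           # per-sample scaling to common depth
  q <- sweep(y, 2, scale, "*")
  if (is.null(dispersion))
    dispersion <- estimateDispersion(y, cls, normFactors = f)
  a <- cls == contrast[1]
  b <- cls == contrast[2]
  nA <- sum(a); nB <- sum(b)
  mA <- rowMeans(q[, a, drop = FALSE]) + pseudoCount
  mB <- rowMeans(q[, b, drop = FALSE]) + pseudoCount
  logFC <- log2(mA / mB)
  # Var(q_j) = m * scale_j + phi * m^2 under NB sampling at common depth
  vA <- (mA %o% scale[a] + dispersion * mA^2) |> rowSums()
  vB <- (mB %o% scale[b] + dispersion * mB^2) |> rowSums()
  vLogA <- vA / nA^2 / (mA^2 * log(2)^2)
  vLogB <- vB / nB^2 / (mB^2 * log(2)^2)
  stat <- logFC / sqrt(vLogA + vLogB)
  p <- if (pReference == "t") 2 * stats::pt(-abs(stat), df = nA + nB - 2)
       else 2 * stats::pnorm(-abs(stat))
  data.frame(gene_id = rownames(y), logFC = logFC, PValue = p,
             FDR = adjustPvaluesBH(p), row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment, order-preserving with the
#' input indexing and clipped at 1.
#'
#' @param p numeric vector of p-values in [0, 1].
#' @return Adjusted p-values, same length and order as \code{p}.
#' @export
adjustPvaluesBH <- function(p) {
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(p, method = "BH")
}

#' Differential-expression call thresholds
#'
#' @param minAbsLogFC minimum absolute log2 fold-change (strict \code{>}).
#' @param pMode \code{"adjusted"} (BH) or \code{"raw"}.
#' @param pCutoff p-value cutoff (strict \code{<}).
#' @return List of class \code{DECallThresholds}.
#' @seealso \code{\link{dePreset}} for the named presets.
#' @export
deThresholds <- function(minAbsLogFC = 4, pMode = c("adjusted", "raw"),
                         pCutoff = 0.01) {
  pMode <- match.arg(pMode)
  if (pCutoff <= 0 || pCutoff >= 1) stop("'pCutoff' must lie in (0, 1)")
  if (minAbsLogFC <= 0) stop("'minAbsLogFC' must be positive")
  structure(list(minAbsLogFC = minAbsLogFC, pMode = pMode,
                 pCutoff = pCutoff), class = "DECallThresholds")
}

#' Named threshold presets
#'
#' \code{"paper"}: BH-adjusted p < 0.01 and |logFC| > 4 (the in-house
#' cohort); \code{"public1"}: raw p < 1e-3 and |logFC| > 4;
#' \code{"public2"}: raw p < 0.01 and |logFC| > 4 (the two public
#' comparator datasets).
#'
#' @param name preset name.
#' @return A \code{\link{deThresholds}} object.
#' @export
dePreset <- function(name = c("paper", "public1", "public2")) {
  switch(match.arg(name),
         paper = deThresholds(4, "adjusted", 0.01),
         public1 = deThresholds(4, "raw", 1e-3),
         public2 = deThresholds(4, "raw", 0.01))
}

#' Pair of up/down gene sets for one contrast
#'
#' @param up,down character vectors of gene ids (disjoint).
#' @param contrastLabel label for the contrast that produced them.
#' @return List of class \code{GeneSetPair}.
#' @export
geneSetPair <- function(up = character(), down = character(),
                        contrastLabel = "") {
  up <- sort(unique(as.character(up)))
  down <- sort(unique(as.character(down)))
  if (length(intersect(up, down)))
    stop("'up' and 'down' must be disjoint")
  structure(list(up = up, down = down, contrast_label = contrastLabel),
            class = "GeneSetPair")
}

#' Call differentially expressed genes
#'
#' Applies the strict threshold rule: up when \code{logFC > minAbsLogFC}
#' and the chosen p-value is \code{< pCutoff}; down symmetrically.
#'
#' @param table DE result table from
#'   \code{\link{testDifferentialExpression}}.
#' @param thresholds a \code{\link{deThresholds}} object or preset name.
#' @param contrastLabel label stored on the returned pair.
#' @return A \code{\link{geneSetPair}} with genes sorted by id.
#' @export
callDE <- function(table, thresholds = dePreset("paper"),
                   contrastLabel = "") {
  if (is.character(thresholds)) thresholds <- dePreset(thresholds)
  stopifnot(nrow(table) > 0)
  p <- if (thresholds$pMode == "adjusted") table$FDR else table$PValue
  sig <- p < thresholds$pCutoff
  geneSetPair(up = table$gene_id[sig & table$logFC > thresholds$minAbsLogFC],
              down = table$gene_id[sig & table$logFC < -thresholds$minAbsLogFC],
              contrastLabel = contrastLabel)
}

#' Consensus DE calls from two test variants
#'
#' Runs the contrast under both reference distributions of
#' \code{\link{testDifferentialExpression}} (t and asymptotic normal) and
#' keeps only the genes called in both — a conservative intersection of
#' two closely related test families. The default pipeline uses the
#' single t-referred test; this mode is opt-in.
#'
#' @inheritParams testDifferentialExpression
#' @param thresholds a \code{\link{deThresholds}} object or preset name.
#' @param contrastLabel label stored on the returned pair.
#' @return A \code{\link{geneSetPair}}: the intersection of the two
#'   variants' up and down calls.
#' @export
callDEConsensus <- function(counts, metadata = NULL, contrast,
                            thresholds = dePreset("paper"),
                            contrastLabel = "") {
  a <- callDE(testDifferentialExpression(counts, metadata, contrast,
                                         pReference = "t"),
              thresholds, contrastLabel)
  b <- callDE(testDifferentialExpression(counts, metadata, contrast,
                                         pReference = "normal"),
              thresholds, contrastLabel)
  geneSetPair(up = intersect(a$up, b$up), down = intersect(a$down, b$down),
              contrastLabel = contrastLabel)
}

#' Two-dimensional sample embedding
#'
#' Principal-coordinate embedding of samples on the \code{topN} most
#' variable genes of the log2-CPM matrix (pseudo-count 1). Genes are
#' centered; the returned axes are the leading principal components with
#' a fixed sign convention (the largest-magnitude gene loading on each
#' axis is positive).
#'
#' @param counts count matrix or SummarizedExperiment.
#' @param topN number of most-variable genes used (all genes, with a
#'   notice, when fewer are available).
#' @param nDims number of dimensions returned.
#' @return samples x nDims coordinate matrix.
#' @export
computeSampleEmbedding <- function(counts, topN = 2000, nDims = 2) {
  y <- .countMatrix(counts)
  if (ncol(y) < 3) stop("need at least 3 samples")
  lc <- logCPM(y)
  if (topN > nrow(lc)) {
    message("topN exceeds the gene count; using all ", nrow(lc), " genes")
    topN <- nrow(lc)
  }
  v <- apply(lc, 1, stats::var)
  sel <- order(v, decreasing = TRUE)[seq_len(topN)]
  x <- lc[sel, , drop = FALSE]
  x <- x - rowMeans(x)
  sv <- svd(t(x), nu = nDims, nv = nDims)
  coords <- sv$u %*% diag(sv$d[seq_len(nDims)], nDims)
  for (d in seq_len(nDims)) {
    load <- sv$v[, d]
    if (load[which.max(abs(load))] < 0) coords[, d] <- -coords[, d]
  }
  dimnames(coords) <- list(colnames(y), paste0("dim", seq_len(nDims)))
  coords
}
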