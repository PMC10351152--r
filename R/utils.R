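# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG state without disturbing the caller's
# stream. All package randomness flows through this.
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic substream seeds derived from a master seed; kept < 2^31.
.subSeed <- function(seed, stream) {
  (abs(as.numeric(seed)) * 7919 + stream * 104729) %% 2147483629
}

# Extract a plain integer count matrix from a matrix or SummarizedExperiment.
.countMatrix <- function(x) {
  if (is(x, "SummarizedExperiment")) x <- SummarizedExperiment::assay(x, "counts")
  if (!is.matrix(x)) x <- as.matrix(x)
  storage.mode(x) <- "numeric"
  x
}

#' Log2 counts-per-million
#'
#' CPM on effective library sizes (library size times normalization
#' factor), then \code{log2(cpm + pseudo)}.
#'
#' @param counts count matrix (genes x samples) or SummarizedExperiment
#'   with a \code{counts} assay.
#' @param normFactors optional per-sample normalization factors; computed
#'   with \code{\link{normalizationFactors}} when missing.
#' @param pseudo pseudo-count added before taking logs.
#' @return Numeric matrix of log2-CPM values, same dimensions as input.
#' @export
logCPM <- function(counts, normFactors = NULL, pseudo = 1) {
  y <- .countMatrix(counts)
  if (is.null(normFactors)) normFactors <- normalizationFactors(y)
  eff <- colSums(y) * normFactors
  log2(sweep(y, 2, eff / 1e6, "/") + pseudo)
}
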