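#' Validate a query signature against a perturbation reference
#'
#' Drops query genes absent from the reference (they cannot contribute to
#' any ranking) and enforces the query-size bounds on what remains:
#' between \code{minGenes} and \code{maxGenes} genes in total.
#'
#' @param signature a \linkS4class{SignatureSet}.
#' @param reference a \linkS4class{PerturbationReference}.
#' @param minGenes,maxGenes inclusive post-drop size bounds (10 and 150
#'   by default).
#' @return List with \code{query} (trimmed \linkS4class{SignatureSet})
#'   and \code{dropped} (character vector of removed genes).
#' @export
validateQuery <- function(signature, reference, minGenes = 10,
                          maxGenes = 150) {
  genes <- referenceGenes(reference)
  up <- signatureUp(signature)
  down <- signatureDown(signature)
  dropped <- c(setdiff(up, genes), setdiff(down, genes))
  if (length(dropped))
    message("query gene(s) not annotated in the reference, dropped: ",
            paste(dropped, collapse = ", "))
  up <- intersect(up, genes)
  down <- intersect(down, genes)
  n <- length(up) + length(down)
  if (n < minGenes || n > maxGenes)
    stop("query has ", n, " genes after dropping unannotated ones; ",
         "must have between ", minGenes, " and ", maxGenes)
  list(query = SignatureSet(up = up, down = down,
                            name = signature@name,
                            provenance = signatureProvenance(signature)),
       dropped = dropped)
}

# Signed maximum deviation of the weighted KS running sum for one gene
# set against a ranked profile. hits: logical over the ranked list.
.ksEnrichment <- function(hits) {
  n <- sum(hits)
  N <- length(hits)
  step <- ifelse(hits, 1 / n, -1 / (N - n))
  run <- cumsum(step)
  mx <- max(run)
  mn <- min(run)
  # equal deviation in both directions is a balanced (null) enrichment;
  # calling it 0 keeps the score antisymmetric under profile negation
  if (mx > -mn) mx else if (-mn > mx) mn else 0
}

#' CMAP-style connectivity score of a query against one profile
#'
#' Ranks the profile's genes by differential-response score (descending,
#' ties broken by gene id) and computes a weighted Kolmogorov-Smirnov
#' enrichment for the query's up and down sets: hits contribute
#' \code{+1/n}, misses \code{-1/(N-n)}, and the enrichment is the signed
#' maximum deviation of the running sum (an exact two-sided tie in the
#' deviation counts as no enrichment). With both directions present the
#' combined statistic is \code{(ES(up) - ES(down)) / 2}; an up-only query
#' scores \code{ES(up)}, a down-only query \code{-ES(down)}. The result
#' is scaled to [-100, 100]: +100 means the profile mimics the
#' signature, -100 that it maximally inverts it.
#'
#' @param query validated \linkS4class{SignatureSet}.
#' @param profile named numeric vector of per-gene scores for one
#'   (compound, context) column.
#' @return Numeric score in [-100, 100]; a constant profile scores 0
#'   (flagged via attribute \code{flat = TRUE}).
#' @export
connectivityScore <- function(query, profile) {
  if (max(profile) - min(profile) == 0) {
    message("constant profile: connectivity score undefined, reporting 0")
    return(structure(0, flat = TRUE))
  }
  ord <- order(-profile, names(profile))
  ranked <- names(profile)[ord]
  up <- signatureUp(query)
  down <- signatureDown(query)
  esUp <- if (length(up)) .ksEnrichment(ranked %in% up) else NULL
  esDown <- if (length(down)) .ksEnrichment(ranked %in% down) else NULL
  s <- if (!is.null(esUp) && !is.null(esDown)) (esUp - esDown) / 2
       else if (!is.null(esUp)) esUp
       else if (!is.null(esDown)) -esDown
       else stop("empty query")
  100 * s
}

#' Screen a perturbation reference with a query signature
#'
#' Scores every (compound, context) profile, then adds a \code{global}
#' context per compound: the mean of its per-context scores. Ranks are
#' dense within each context, ascending by score (rank 1 = strongest
#' signature inverter), with ties broken by compound id.
#'
#' @param query validated \linkS4class{SignatureSet} (see
#'   \code{\link{validateQuery}}).
#' @param reference a \linkS4class{PerturbationReference}.
#' @return data.frame with columns \code{compound}, \code{context},
#'   \code{score}, \code{rank}, ordered by context, then score, then
#'   compound.
#' @export
screenCompounds <- function(query, reference) {
  sc <- referenceScores(reference)
  perCol <- vapply(seq_len(ncol(sc)), function(j)
    as.numeric(connectivityScore(query, sc[, j])), numeric(1))
  res <- data.frame(compound = reference@compound,
                    context = reference@context,
                    score = perCol, stringsAsFactors = FALSE)
  glob <- stats::aggregate(score ~ compound, data = res, FUN = mean)
  glob$context <- "global"
  res <- rbind(res, glob[, c("compound", "context", "score")])
  res <- res[order(res$context, res$score, res$compound), ]
  res$rank <- stats::ave(res$score, res$context,
                         FUN = function(s) match(s, sort(unique(s))))
  res$rank <- as.integer(res$rank)
  rownames(res) <- NULL
  res
}

#' Select screening hits
#'
#' Compounds whose score is strictly below \code{cutoff} in every
#' required context. Compounds missing a required context are excluded
#' (logged). Results are ordered by global score ascending (strongest
#' inverters first).
#'
#' @param results screen table from \code{\link{screenCompounds}}.
#' @param cutoff score cutoff (strict \code{<}).
#' @param contextsRequired contexts that must all pass; defaults to every
#'   context present (including \code{global}).
#' @return Character vector of compound ids.
#' @export
selectHits <- function(results, cutoff = -95, contextsRequired = NULL) {
  if (is.null(contextsRequired)) contextsRequired <- unique(results$context)
  missing <- setdiff(contextsRequired, unique(results$context))
  if (length(missing))
    stop("context(s) absent from results: ", paste(missing, collapse = ", "))
  keep <- vapply(unique(results$compound), function(cmp) {
    sub <- results[results$compound == cmp &
                     results$context %in% contextsRequired, ]
    if (length(unique(sub$context)) < length(contextsRequired)) {
      message("compound ", cmp, " missing required context(s); excluded")
      return(FALSE)
    }
    all(sub$score < cutoff)
  }, logical(1))
  hits <- unique(results$compound)[keep]
  glob <- results[results$context == "global" &
                    results$compound %in% hits, ]
  if (nrow(glob)) hits <- glob$compound[order(glob$score)]
  hits
}

#' Summarize mechanism classes within a score band
#'
#' Counts compounds per mechanism class among those whose global
#' connectivity score falls inside \code{scoreBand} (inclusive), the
#' "most negatively correlated" slice of the screen. Compounds without
#' metadata are counted as class \code{"unknown"}.
#'
#' @param results screen table from \code{\link{screenCompounds}}.
#' @param compoundMeta data.frame with \code{compound} and
#'   \code{mechanism_class} columns.
#' @param scoreBand length-2 numeric band on the global score.
#' @param compounds optional restriction to these compound ids (e.g. the
#'   hits).
#' @return data.frame with \code{mechanism_class}, \code{count},
#'   \code{proportion} (summing to 1), ordered by decreasing count.
#' @export
summarizeClasses <- function(results, compoundMeta,
                             scoreBand = c(-100, -50), compounds = NULL) {
  glob <- results[results$context == "global", ]
  if (!is.null(compounds)) glob <- glob[glob$compound %in% compounds, ]
  glob <- glob[glob$score >= scoreBand[1] & glob$score <= scoreBand[2], ]
  if (!nrow(glob))
    return(data.frame(mechanism_class = character(), count = integer(),
                      proportion = numeric()))
  cls <- compoundMeta$mechanism_class[match(glob$compound,
                                            compoundMeta$compound)]
  cls[is.na(cls)] <- "unknown"
  tab <- sort(table(cls), decreasing = TRUE)
  data.frame(mechanism_class = names(tab), count = as.integer(tab),
             proportion = as.numeric(tab) / sum(tab),
             stringsAsFactors = FALSE, row.names = NULL)
}
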