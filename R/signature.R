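#' Intersect gene sets across contrasts
#'
#' Exact intersection of the up (or down) members of two or more
#' \code{\link{geneSetPair}}s, sorted by gene id.
#'
#' @param sets list of \code{GeneSetPair} objects (at least 2).
#' @param direction \code{"up"} or \code{"down"}.
#' @return Sorted character vector of shared gene ids.
#' @export
intersectGeneSets <- function(sets, direction = c("up", "down")) {
  direction <- match.arg(direction)
  if (length(sets) < 2) stop("need at least 2 gene-set pairs")
  sort(Reduce(intersect, lapply(sets, `[[`, direction)))
}

#' Parse a semicolon-separated tissue-enrichment field
#'
#' Fields look like \code{"intestine: 224.8;liver: 442.2"}; levels are
#' optional.
#'
#' @param x character vector of enrichment strings.
#' @return List (one element per input) of named numeric vectors: names
#'   are tissues, values the expression levels (NA when absent).
#' @export
parseEnrichedTissues <- function(x) {
  lapply(x, function(s) {
    if (is.na(s) || !nzchar(s)) return(stats::setNames(numeric(0), character(0)))
    parts <- strsplit(trimws(strsplit(s, ";")[[1]]), ":")
    lv <- vapply(parts, function(p)
      if (length(p) > 1) suppressWarnings(as.numeric(trimws(p[2]))) else NA_real_,
      numeric(1))
    stats::setNames(lv, vapply(parts, function(p) trimws(p[1]), character(1)))
  })
}

#' Classify genes by tissue enrichment
#'
#' Labels each gene \code{liver_only}, \code{intestine_only}, \code{both}
#' or \code{neither} according to an atlas-style annotation table. A gene
#' is liver-enriched when the annotation lists liver among its enriched
#' tissues; no expression-level cutoff is applied. Genes absent from the
#' annotation are \code{neither} (logged).
#'
#' @param genes character vector of gene ids.
#' @param annotation data.frame with columns \code{gene_id} and
#'   \code{enriched_tissues}.
#' @param tissues length-2 character vector naming the two tissues of
#'   interest, in (liver-like, intestine-like) order.
#' @return List with \code{labels} (named character per gene) and
#'   \code{counts} (named integer vector \code{liver_only},
#'   \code{intestine_only}, \code{both}, \code{neither}).
#' @export
classifyTissueEnrichment <- function(genes, annotation,
                                     tissues = c("liver", "intestine")) {
  stopifnot(length(tissues) == 2)
  idx <- match(toupper(genes), toupper(annotation$gene_id))
  missing <- genes[is.na(idx)]
  if (length(missing))
    message("gene(s) absent from annotation, classified 'neither': ",
            paste(missing, collapse = ", "))
  parsed <- parseEnrichedTissues(annotation$enriched_tissues[idx])
  labels <- vapply(parsed, function(tt) {
    inLiver <- tissues[1] %in% names(tt)
    inIntestine <- tissues[2] %in% names(tt)
    if (inLiver && inIntestine) "both"
    else if (inLiver) "liver_only"
    else if (inIntestine) "intestine_only"
    else "neither"
  }, character(1))
  labels[is.na(idx)] <- "neither"
  names(labels) <- genes
  counts <- vapply(c("liver_only", "intestine_only", "both", "neither"),
                   function(l) sum(labels == l), integer(1))
  list(labels = labels, counts = counts)
}

#' Derive the core metastasis signature
#'
#' Intersects the up-regulated genes of the matched in-house contrast,
#' the unmatched in-house contrast and any external-dataset contrasts;
#' down-regulation is handled symmetrically. Adding inputs can only
#' shrink the core. Provenance records every contributing input.
#'
#' @param ownMatched,ownUnmatched \code{\link{geneSetPair}}s from the
#'   matched and unmatched in-house comparisons.
#' @param external list of external-dataset \code{GeneSetPair}s (may be
#'   empty).
#' @param name label for the resulting signature.
#' @return A \linkS4class{SignatureSet}.
#' @export
deriveCoreSignature <- function(ownMatched, ownUnmatched,
                                external = list(), name = "core") {
  inputs <- c(list(ownMatched, ownUnmatched), external)
  datasets <- c("own_matched", "own_unmatched",
                if (length(external)) paste0("external_", seq_along(external)))
  up <- sort(Reduce(intersect, lapply(inputs, `[[`, "up")))
  down <- sort(Reduce(intersect, lapply(inputs, `[[`, "down")))
  prov <- Map(function(ds, gp) list(dataset = ds,
                                    contrast = gp$contrast_label,
                                    operation = "intersect"),
              datasets, inputs)
  SignatureSet(up = up, down = down, name = name,
               provenance = unname(prov))
}

#' Hypergeometric over-representation test
#'
#' One-sided (upper tail) hypergeometric test of each pathway's overlap
#' with a gene set against a stated universe, BH-adjusted across
#' pathways.
#'
#' @param geneSet character vector of gene ids, all within
#'   \code{universe}.
#' @param pathwayDb named list of pathway gene vectors (a
#'   \code{PathwayDB}).
#' @param universe character vector, the testable gene universe.
#' @return data.frame with columns \code{pathway}, \code{overlap},
#'   \code{pathway_size}, \code{fold}, \code{p}, \code{adj_p}, ordered by
#'   \code{p}.
#' @export
enrichmentTest <- function(geneSet, pathwayDb, universe) {
  geneSet <- unique(geneSet)
  universe <- unique(universe)
  bad <- setdiff(geneSet, universe)
  if (length(bad))
    stop("gene(s) outside the universe: ", paste(bad, collapse = ", "))
  N <- length(universe)
  n <- length(geneSet)
  rows <- lapply(names(pathwayDb), function(pw) {
    path <- intersect(pathwayDb[[pw]], universe)
    K <- length(path)
    k <- length(intersect(geneSet, path))
    p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fold <- if (K > 0 && n > 0) (k / n) / (K / N) else NA_real_
    data.frame(pathway = pw, overlap = k, pathway_size = K, fold = fold,
               p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$adj_p <- adjustPvaluesBH(out$p)
  out[order(out$p, out$pathway), , drop = FALSE]
}

#' Read the packaged core-signature table
#'
#' Parses a TSV with columns \code{gene}, \code{name}, \code{ensembl_id},
#' \code{enriched_tissues} into the signature (all genes up-regulated in
#' metastasis) and its annotation table. The packaged fixture
#' (\code{system.file("extdata", "table1_signature.tsv", package =
#' "LiverMetSig")}) carries the 22-gene colon-to-liver metastasis core
#' signature with its tissue-enrichment annotations.
#'
#' @param path path to the TSV file.
#' @return List with \code{signature} (\linkS4class{SignatureSet}) and
#'   \code{annotation} (data.frame gene_id, ensembl_id,
#'   enriched_tissues).
#' @export
readSignatureTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene", "ensembl_id", "enriched_tissues")
  if (!all(need %in% colnames(tab)))
    stop("signature table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(toupper(tab$gene)))
    stop("duplicate gene symbols in signature table")
  sig <- SignatureSet(up = tab$gene, name = "colon-to-liver-metastasis",
                      provenance = list(list(dataset = "packaged",
                                             contrast = "LM-vs-CC",
                                             operation = "load")))
  ann <- data.frame(gene_id = toupper(tab$gene),
                    ensembl_id = tab$ensembl_id,
                    enriched_tissues = tab$enriched_tissues,
                    stringsAsFactors = FALSE)
  list(signature = sig, annotation = ann)
}
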