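#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

#' Gene signature with provenance
#'
#' Ordered up- and down-regulated gene lists together with a provenance
#' record of the intersections that produced them. The default metastasis
#' signature is up-only: the genes over-expressed in liver metastases
#' relative to the matched primary colon tumors.
#'
#' @slot name character(1) label for the signature.
#' @slot up character vector of up-regulated gene symbols (upper case).
#' @slot down character vector of down-regulated gene symbols.
#' @slot provenance list of records, each a list with elements
#'   \code{dataset}, \code{contrast}, \code{operation}.
#'
#' @aliases SignatureSet-class
#' @exportClass SignatureSet
setClass("SignatureSet",
  representation(
    name = "character",
    up = "character",
    down = "character",
    provenance = "list"
  ),
  prototype(name = "signature", up = character(), down = character(),
            provenance = list())
)

setValidity("SignatureSet", function(object) {
  msg <- character()
  if (length(object@name) != 1L)
    msg <- c(msg, "'name' must be a single string")
  if (anyDuplicated(object@up) || anyDuplicated(object@down))
    msg <- c(msg, "gene lists must not contain duplicates")
  if (length(intersect(object@up, object@down)))
    msg <- c(msg, "'up' and 'down' gene sets must be disjoint")
  if (length(msg)) msg else TRUE
})

#' Construct a SignatureSet
#'
#' @param up,down character vectors of gene symbols; symbols are
#'   upper-cased and de-duplicated, order preserved.
#' @param name signature label.
#' @param provenance list of provenance records (see
#'   \linkS4class{SignatureSet}).
#' @return A \linkS4class{SignatureSet}.
#' @examples
#' sig <- SignatureSet(up = c("FGA", "FGB", "CRP"), name = "toy")
#' signatureUp(sig)
#' @export
SignatureSet <- function(up = character(), down = character(),
                         name = "signature", provenance = list()) {
  new("SignatureSet", name = name,
      up = unique(toupper(as.character(up))),
      down = unique(toupper(as.character(down))),
      provenance = provenance)
}

#' Compound perturbation reference
#'
#' A local, self-contained stand-in for a connectivity-map style resource:
#' per-gene differential-response scores for each compound in each cellular
#' context, plus compound mechanism-class metadata. Columns of
#' \code{scores} are (compound, context) pairs.
#'
#' @slot scores numeric matrix, genes x (compound, context) columns.
#' @slot compound character vector, per-column compound id.
#' @slot context character vector, per-column context label.
#' @slot compoundMeta data.frame with columns \code{compound},
#'   \code{name}, \code{mechanism_class}.
#'
#' @aliases PerturbationReference-class
#' @exportClass PerturbationReference
setClass("PerturbationReference",
  representation(
    scores = "matrix",
    compound = "character",
    context = "character",
    compoundMeta = "data.frame"
  )
)

setValidity("PerturbationReference", function(object) {
  msg <- character()
  if (ncol(object@scores) != length(object@compound) ||
      ncol(object@scores) != length(object@context))
    msg <- c(msg, "one compound and context label per score column")
  if (is.null(rownames(object@scores)))
    msg <- c(msg, "score matrix must carry gene ids as rownames")
  else if (anyDuplicated(rownames(object@scores)))
    msg <- c(msg, "duplicate gene ids in score matrix")
  if (anyNA(object@scores))
    msg <- c(msg, "every (compound, context) column must be complete")
  if (!all(c("compound", "mechanism_class") %in% colnames(object@compoundMeta)))
    msg <- c(msg, "compoundMeta needs 'compound' and 'mechanism_class' columns")
  if (length(msg)) msg else TRUE
})

#' Construct a PerturbationReference
#'
#' @param scores gene x column numeric matrix with gene rownames.
#' @param compound,context per-column labels.
#' @param compoundMeta data.frame(compound, name, mechanism_class).
#' @return A \linkS4class{PerturbationReference}.
#' @export
PerturbationReference <- function(scores, compound, context, compoundMeta) {
  new("PerturbationReference", scores = scores,
      compound = as.character(compound), context = as.character(context),
      compoundMeta = as.data.frame(compoundMeta))
}

#' Organoid culture measurement at one timepoint
#'
#' Organoid count, mean maximal diameter (micrometers) and viability for a
#' patient-derived organoid culture. Viability entered as a percent
#' (> 1) is normalized to a fraction on construction.
#'
#' @slot nOrganoids non-negative organoid count.
#' @slot meanMaxDiameter mean maximal diameter, micrometers.
#' @slot viability viable-cell fraction in [0, 1].
#'
#' @aliases OrganoidTimepoint-class
#' @exportClass OrganoidTimepoint
setClass("OrganoidTimepoint",
  representation(nOrganoids = "numeric", meanMaxDiameter = "numeric",
                 viability = "numeric")
)

setValidity("OrganoidTimepoint", function(object) {
  msg <- character()
  if (object@nOrganoids < 0 || object@nOrganoids != round(object@nOrganoids))
    msg <- c(msg, "'nOrganoids' must be a non-negative integer")
  if (object@viability < 0 || object@viability > 1)
    msg <- c(msg, "'viability' must lie in [0, 1]")
  if (object@nOrganoids > 0 && object@meanMaxDiameter <= 0)
    msg <- c(msg, "'meanMaxDiameter' must be positive when organoids formed")
  if (length(msg)) msg else TRUE
})

#' Construct an OrganoidTimepoint
#'
#' @param nOrganoids organoid count.
#' @param meanMaxDiameter mean maximal diameter (micrometers).
#' @param viability viable fraction in [0,1], or a percent in (1, 100].
#' @return An \linkS4class{OrganoidTimepoint}.
#' @examples
#' OrganoidTimepoint(100, 200, 90)  # 90% viability
#' @export
OrganoidTimepoint <- function(nOrganoids, meanMaxDiameter, viability) {
  if (viability > 1) viability <- viability / 100
  new("OrganoidTimepoint", nOrganoids = as.numeric(nOrganoids),
      meanMaxDiameter = as.numeric(meanMaxDiameter),
      viability = as.numeric(viability))
}

#' Two-agent dose-response inhibition grid
#'
#' Inhibition fractions on a complete dose grid for two agents, with the
#' zero-dose margins present: row/column 1 are the single-agent responses
#' and cell (1,1) is the untreated well (inhibition 0 by convention).
#'
#' @slot dosesA,dosesB ascending dose vectors including 0.
#' @slot inhibition matrix of inhibition fractions in [0,1],
#'   rows indexed by dosesA, columns by dosesB.
#'
#' @aliases DoseResponseMatrix-class
#' @exportClass DoseResponseMatrix
setClass("DoseResponseMatrix",
  representation(dosesA = "numeric", dosesB = "numeric",
                 inhibition = "matrix")
)

setValidity("DoseResponseMatrix", function(object) {
  msg <- character()
  if (nrow(object@inhibition) != length(object@dosesA) ||
      ncol(object@inhibition) != length(object@dosesB))
    msg <- c(msg, "inhibition grid dimensions must match the dose vectors")
  if (length(object@dosesA) < 2L || length(object@dosesB) < 2L ||
      object@dosesA[1] != 0 || object@dosesB[1] != 0)
    msg <- c(msg, "dose grids must include the zero-dose single-agent margins")
  if (is.unsorted(object@dosesA, strictly = TRUE) ||
      is.unsorted(object@dosesB, strictly = TRUE))
    msg <- c(msg, "doses must be strictly ascending")
  if (anyNA(object@inhibition) || any(object@inhibition < 0) ||
      any(object@inhibition > 1))
    msg <- c(msg, "inhibition values must be complete fractions in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a DoseResponseMatrix
#'
#' @param dosesA,dosesB ascending dose vectors starting at 0.
#' @param inhibition inhibition fraction matrix (dosesA x dosesB).
#' @return A \linkS4class{DoseResponseMatrix}.
#' @export
DoseResponseMatrix <- function(dosesA, dosesB, inhibition) {
  inhibition <- as.matrix(inhibition)
  inhibition[1, 1] <- 0
  new("DoseResponseMatrix", dosesA = as.numeric(dosesA),
      dosesB = as.numeric(dosesB), inhibition = inhibition)
}

setMethod("show", "SignatureSet", function(object) {
  cat("SignatureSet \"", object@name, "\": ", length(object@up), " up, ",
      length(object@down), " down gene(s)\n", sep = "")
  if (length(object@up))
    cat("  up:   ", paste(utils::head(object@up, 8), collapse = ", "),
        if (length(object@up) > 8) ", ..." else "", "\n", sep = "")
  if (length(object@down))
    cat("  down: ", paste(utils::head(object@down, 8), collapse = ", "),
        if (length(object@down) > 8) ", ..." else "", "\n", sep = "")
  cat("  provenance: ", length(object@provenance), " record(s)\n", sep = "")
})

setMethod("show", "PerturbationReference", function(object) {
  cat("PerturbationReference: ", nrow(object@scores), " genes, ",
      length(unique(object@compound)), " compounds, contexts: ",
      paste(unique(object@context), collapse = ", "), "\n", sep = "")
})

setMethod("show", "OrganoidTimepoint", function(object) {
  cat(sprintf("OrganoidTimepoint: n = %g, diameter = %g um, viability = %g\n",
              object@nOrganoids, object@meanMaxDiameter, object@viability))
})

setMethod("show", "DoseResponseMatrix", function(object) {
  cat(sprintf("DoseResponseMatrix: %d x %d grid, agent A doses %g-%g, agent B doses %g-%g\n",
              length(object@dosesA), length(object@dosesB),
              min(object@dosesA), max(object@dosesA),
              min(object@dosesB), max(object@dosesB)))
})

#' Accessors for signature gene lists
#'
#' @param x a \linkS4class{SignatureSet}.
#' @return Character vector of gene symbols (\code{signatureUp},
#'   \code{signatureDown}) or the provenance list.
#' @rdname SignatureSet-accessors
#' @export
setGeneric("signatureUp", function(x) standardGeneric("signatureUp"))
#' @rdname SignatureSet-accessors
#' @export
setGeneric("signatureDown", function(x) standardGeneric("signatureDown"))
#' @rdname SignatureSet-accessors
#' @export
setGeneric("signatureProvenance",
           function(x) standardGeneric("signatureProvenance"))

#' @rdname SignatureSet-accessors
setMethod("signatureUp", "SignatureSet", function(x) x@up)
#' @rdname SignatureSet-accessors
setMethod("signatureDown", "SignatureSet", function(x) x@down)
#' @rdname SignatureSet-accessors
setMethod("signatureProvenance", "SignatureSet", function(x) x@provenance)

#' Accessors for perturbation references
#'
#' @param x a \linkS4class{PerturbationReference}.
#' @return The score matrix, per-column compound/context labels, gene ids,
#'   or the compound metadata table.
#' @rdname PerturbationReference-accessors
#' @export
setGeneric("referenceScores", function(x) standardGeneric("referenceScores"))
#' @rdname PerturbationReference-accessors
#' @export
setGeneric("referenceCompounds",
           function(x) standardGeneric("referenceCompounds"))
#' @rdname PerturbationReference-accessors
#' @export
setGeneric("referenceContexts",
           function(x) standardGeneric("referenceContexts"))
#' @rdname PerturbationReference-accessors
#' @export
setGeneric("referenceGenes", function(x) standardGeneric("referenceGenes"))
#' @rdname PerturbationReference-accessors
#' @export
setGeneric("compoundMeta", function(x) standardGeneric("compoundMeta"))

#' @rdname PerturbationReference-accessors
setMethod("referenceScores", "PerturbationReference", function(x) x@scores)
#' @rdname PerturbationReference-accessors
setMethod("referenceCompounds", "PerturbationReference",
          function(x) x@compound)
#' @rdname PerturbationReference-accessors
setMethod("referenceContexts", "PerturbationReference",
          function(x) unique(x@context))
#' @rdname PerturbationReference-accessors
setMethod("referenceGenes", "PerturbationReference",
          function(x) rownames(x@scores))
#' @rdname PerturbationReference-accessors
setMethod("compoundMeta", "PerturbationReference", function(x) x@compoundMeta)
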