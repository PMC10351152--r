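#' Read a count matrix from TSV
#'
#' Expects a header row of sample ids and gene ids in the first column.
#' Parsing is strict: duplicate gene or sample ids and non-integer cells
#' are errors naming the offender.
#'
#' @param path path to the TSV file.
#' @return Integer matrix, genes x samples.
#' @export
readCountMatrix <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  samples <- colnames(tab)[-1]
  if (anyDuplicated(samples))
    stop("duplicate sample id(s): ",
         paste(unique(samples[duplicated(samples)]), collapse = ", "))
  genes <- as.character(tab[[1]])
  if (anyDuplicated(genes))
    stop("duplicate gene id(s): ",
         paste(unique(genes[duplicated(genes)]), collapse = ", "))
  m <- as.matrix(tab[, -1, drop = FALSE])
  suppressWarnings(storage.mode(m) <- "numeric")
  bad <- which(is.na(m) | m < 0 | m != round(m), arr.ind = TRUE)
  if (nrow(bad))
    stop(sprintf("non-integer count at gene '%s', sample '%s'",
                 genes[bad[1, 1]], samples[bad[1, 2]]))
  storage.mode(m) <- "integer"
  dimnames(m) <- list(genes, samples)
  m
}

#' Write a count matrix as TSV
#'
#' @param counts matrix or SummarizedExperiment.
#' @param path output path.
#' @return Invisibly, the path.
#' @export
writeCountMatrix <- function(counts, path) {
  y <- .countMatrix(counts)
  df <- data.frame(gene_id = rownames(y), y, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read / write sample metadata TSV
#'
#' Columns: \code{sample_id}, \code{patient_id}, \code{tissue_class},
#' \code{matched}.
#'
#' @param path file path.
#' @return \code{readSampleMetadata}: a data.frame.
#' @export
readSampleMetadata <- function(path) {
  md <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "patient_id", "tissue_class")
  if (!all(need %in% colnames(md)))
    stop("metadata must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(md$sample_id)) stop("duplicate sample_id in metadata")
  md
}

#' @rdname readSampleMetadata
#' @param metadata data.frame or DataFrame of sample metadata.
#' @export
writeSampleMetadata <- function(metadata, path) {
  utils::write.table(as.data.frame(metadata), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write / read a signature as JSON
#'
#' @param signature a \linkS4class{SignatureSet}.
#' @param path file path.
#' @export
writeSignatureSet <- function(signature, path) {
  jsonlite::write_json(
    list(name = signature@name, up = signatureUp(signature),
         down = signatureDown(signature),
         provenance = signatureProvenance(signature)),
    path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname writeSignatureSet
#' @export
readSignatureSet <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  prov <- x$provenance
  if (is.data.frame(prov)) prov <- lapply(seq_len(nrow(prov)),
                                          function(i) as.list(prov[i, ]))
  SignatureSet(up = x$up, down = if (is.null(x$down)) character() else x$down,
               name = x$name, provenance = if (is.null(prov)) list() else prov)
}

#' Write / read a perturbation reference
#'
#' Scores go to a TSV with gene rows and \code{"compound|context"}
#' columns; compound metadata to a second TSV.
#'
#' @param reference a \linkS4class{PerturbationReference}.
#' @param path scores TSV path.
#' @param metaPath metadata TSV path.
#' @export
writePerturbationReference <- function(reference, path, metaPath) {
  df <- data.frame(gene_id = referenceGenes(reference),
                   referenceScores(reference), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(compoundMeta(reference), metaPath, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writePerturbationReference
#' @export
readPerturbationReference <- function(path, metaPath) {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  parts <- strsplit(colnames(m), "|", fixed = TRUE)
  if (any(lengths(parts) != 2))
    stop("score columns must be named 'compound|context'")
  meta <- utils::read.delim(metaPath, stringsAsFactors = FALSE)
  PerturbationReference(m,
                        vapply(parts, `[[`, character(1), 1),
                        vapply(parts, `[[`, character(1), 2),
                        meta)
}

#' Read a dose-response inhibition grid from TSV
#'
#' First row and first column carry the doses; the top-left cell is
#' ignored. Cells are inhibition fractions.
#'
#' @param path TSV path.
#' @return A \linkS4class{DoseResponseMatrix}.
#' @export
readDoseResponseMatrix <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE)
  dosesB <- as.numeric(colnames(tab)[-1])
  dosesA <- as.numeric(tab[[1]])
  DoseResponseMatrix(dosesA, dosesB,
                     as.matrix(tab[, -1, drop = FALSE]))
}

#' @rdname readDoseResponseMatrix
#' @param m a \linkS4class{DoseResponseMatrix}.
#' @export
writeDoseResponseMatrix <- function(m, path) {
  df <- data.frame(dose_a = m@dosesA, m@inhibition, check.names = FALSE)
  colnames(df) <- c("dose_a", m@dosesB)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Pipeline configuration
#'
#' Declarative configuration for \code{\link{runPipeline}}. The preset
#' expands to the printed DE thresholds: \code{paper} (adjusted p < 0.01,
#' |logFC| > 4), \code{public1} (raw p < 1e-3), \code{public2}
#' (raw p < 0.01).
#'
#' @param stages character vector of stages to run, in dependency order
#'   among \code{simulate}, \code{de}, \code{signature}, \code{cluster},
#'   \code{connect}, \code{organoid}.
#' @param preset DE threshold preset name.
#' @param seed integer master seed (mandatory; every stochastic stage
#'   derives its stream from it).
#' @param cohort a \code{\link{cohortConfig}} for the simulate stage.
#' @param nReplicas,conservation clustering stability parameters.
#' @param hitCutoff connectivity hit cutoff.
#' @param ... further stage parameters stored as-is.
#' @return List of class \code{PipelineConfig}.
#' @export
pipelineConfig <- function(stages = c("simulate", "de", "signature",
                                      "cluster", "connect", "organoid"),
                           preset = "paper", seed,
                           cohort = cohortConfig(seed = seed),
                           nReplicas = 500, conservation = 0.95,
                           hitCutoff = -95, ...) {
  if (missing(seed)) stop("'seed' is mandatory")
  structure(list(stages = stages, preset = preset, seed = as.integer(seed),
                 cohort = cohort, nReplicas = nReplicas,
                 conservation = conservation, hitCutoff = hitCutoff,
                 extra = list(...)),
            class = "PipelineConfig")
}

#' Run the pipeline end to end
#'
#' Executes the requested stages in dependency order on a simulated
#' cohort, writing each stage's outputs plus a manifest JSON (parameters,
#' seeds, file MD5 hashes) into \code{outDir}. Identical configuration
#' and seed give byte-identical outputs.
#'
#' @param config a \code{\link{pipelineConfig}}.
#' @param outDir output directory (created if needed).
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config, outDir) {
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
  pathOf <- function(f) file.path(outDir, f)
  outputs <- character()
  state <- new.env(parent = emptyenv())
  needs <- function(what, stage) {
    if (!exists(what, envir = state))
      stop("stage '", stage, "' needs upstream output '", what,
           "'; run its producing stage first")
    get(what, envir = state)
  }

  for (stage in config$stages) {
    switch(stage,
      simulate = {
        se <- simulateCohort(config$cohort)
        assign("se", se, envir = state)
        writeCountMatrix(se, pathOf("counts.tsv"))
        writeSampleMetadata(SummarizedExperiment::colData(se),
                            pathOf("metadata.tsv"))
        jsonlite::write_json(groundTruth(se), pathOf("ground_truth.json"),
                             auto_unbox = TRUE, pretty = TRUE)
        ann <- simulateAnnotation(groundTruth(se), seed = config$seed)
        assign("annotation", ann, envir = state)
        utils::write.table(ann, pathOf("annotation.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        outputs <- c(outputs, "counts.tsv", "metadata.tsv",
                     "ground_truth.json", "annotation.tsv")
      },
      de = {
        se <- needs("se", "de")
        filtered <- filterLowExpression(se)
        assign("filtered", filtered, envir = state)
        md <- as.data.frame(SummarizedExperiment::colData(filtered))
        matched <- filtered[, md$matched & md$tissue_class %in% c("CC", "LM1")]
        deMatched <- testDifferentialExpression(matched,
                                                contrast = c("LM1", "CC"))
        allLM <- filtered[, md$tissue_class %in% c("CC", "LM1", "LM2", "LM3")]
        mdAll <- as.data.frame(SummarizedExperiment::colData(allLM))
        mdAll$tissue_class <- ifelse(mdAll$tissue_class == "CC", "CC", "LM")
        deUnmatched <- testDifferentialExpression(
          SummarizedExperiment::assay(allLM, "counts"), mdAll,
          contrast = c("LM", "CC"))
        assign("deMatched", deMatched, envir = state)
        assign("deUnmatched", deUnmatched, envir = state)
        utils::write.table(deMatched, pathOf("de_matched.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        utils::write.table(deUnmatched, pathOf("de_unmatched.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        outputs <- c(outputs, "de_matched.tsv", "de_unmatched.tsv")
      },
      signature = {
        thr <- dePreset(config$preset)
        gsMatched <- callDE(needs("deMatched", "signature"), thr,
                            "LM1-vs-CC-matched")
        gsUnmatched <- callDE(needs("deUnmatched", "signature"), thr,
                              "LM-vs-CC")
        core <- deriveCoreSignature(gsMatched, gsUnmatched,
                                    name = "synthetic-core")
        assign("signature", core, envir = state)
        writeSignatureSet(core, pathOf("signature.json"))
        ann <- needs("annotation", "signature")
        cls <- classifyTissueEnrichment(signatureUp(core), ann)
        utils::write.table(
          data.frame(gene_id = names(cls$labels), label = cls$labels),
          pathOf("signature_classification.tsv"), sep = "\t",
          quote = FALSE, row.names = FALSE)
        outputs <- c(outputs, "signature.json",
                     "signature_classification.tsv")
      },
      cluster = {
        filtered <- needs("filtered", "cluster")
        db <- simulatePathways(rownames(filtered),
                               nPathways = config$extra$nPathways %||% 20,
                               seed = config$seed)
        stab <- pathwayStability(filtered, db,
                                 nReplicas = config$nReplicas,
                                 conservationThreshold = config$conservation,
                                 seed = config$seed)
        stabTab <- do.call(rbind, lapply(stab, function(s)
          data.frame(pathway_id = s$pathway_id, k = s$k,
                     replicas = s$replicaCount,
                     stability_fraction = s$stabilityFraction,
                     stable = s$stable)))
        utils::write.table(stabTab, pathOf("pathway_stability.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        stable <- Filter(function(s) s$stable && s$k >= 2, stab)
        if (length(stable)) {
          cons <- consensusAssignment(
            stable, SummarizedExperiment::colData(needs("se", "cluster")))
          utils::write.table(cons, pathOf("consensus.tsv"), sep = "\t",
                             quote = FALSE, row.names = FALSE)
          outputs <- c(outputs, "consensus.tsv")
        }
        outputs <- c(outputs, "pathway_stability.tsv")
      },
      connect = {
        sig <- needs("signature", "connect")
        sim <- simulatePerturbationReference(
          sig, nCompounds = config$extra$nCompounds %||% 50,
          nReverters = config$extra$nReverters %||% 2,
          seed = config$seed)
        vq <- validateQuery(sig, sim$reference)
        res <- screenCompounds(vq$query, sim$reference)
        hits <- selectHits(res, cutoff = config$hitCutoff)
        utils::write.table(res, pathOf("connectivity_scores.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        jsonlite::write_json(
          list(hits = hits,
               planted_reverters = sim$truth$reverter_compounds,
               cutoff = config$hitCutoff),
          pathOf("hits.json"), auto_unbox = TRUE, pretty = TRUE)
        cls <- summarizeClasses(res, compoundMeta(sim$reference))
        utils::write.table(cls, pathOf("class_summary.tsv"), sep = "\t",
                           quote = FALSE, row.names = FALSE)
        outputs <- c(outputs, "connectivity_scores.tsv", "hits.json",
                     "class_summary.tsv")
      },
      organoid = {
        sim <- simulateOrganoidExperiment(seed = config$seed)
        rs <- responseScore(sim$t0, sim$t72)
        syn <- blissSynergyScore(sim$doseResponse)
        writeDoseResponseMatrix(sim$doseResponse,
                                pathOf("dose_response.tsv"))
        jsonlite::write_json(
          list(rs = rs$rs, infinite = rs$infinite,
               bliss_score = syn$blissScore,
               classification = syn$classification),
          pathOf("organoid.json"), auto_unbox = TRUE, pretty = TRUE)
        outputs <- c(outputs, "dose_response.tsv", "organoid.json")
      },
      stop("unknown stage: ", stage)
    )
  }

  hashes <- as.list(tools::md5sum(file.path(outDir, outputs)))
  names(hashes) <- outputs
  manifest <- list(
    package_version = as.character(utils::packageVersion("LiverMetSig")),
    seed = config$seed, preset = config$preset, stages = config$stages,
    parameters = list(nReplicas = config$nReplicas,
                      conservation = config$conservation,
                      hitCutoff = config$hitCutoff,
                      cohort = unclass(config$cohort)),
    outputs = hashes)
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
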