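#' Cohort simulation configuration
#'
#' Parameters for a synthetic colon-cancer / liver-metastasis cohort. The
#' simulated biology: a set of liver-program genes highly expressed in
#' adjacent liver (AL) and low in primary colon cancer (CC), a set of
#' colon-program genes with the opposite pattern, and metastasis samples
#' (LM1/LM2/LM3) whose per-gene log2 means are the convex combination
#' \code{(1 - w) * CC + w * AL} of the two tissue programs — the hybrid
#' phenotype in which metastases sit between their tumor of origin and
#' the surrounding liver.
#'
#' @param nPatients number of patients.
#' @param groups named integer vector: samples per patient for each tissue
#'   class (subset of CC, LM1, LM2, LM3, AL, NC).
#' @param nGenes total number of genes.
#' @param nLiverProgram,nColonProgram sizes of the planted liver and
#'   colon expression programs.
#' @param mixtureWeight fraction \code{w} in [0,1] of the liver program
#'   adopted by metastasis samples.
#' @param plantedLogFC planted effect size, log2 units (> 0).
#' @param nbDispersion negative-binomial dispersion phi
#'   (variance \code{mu + phi * mu^2}), shared across genes.
#' @param librarySizeRange two positive numbers; library sizes are drawn
#'   log-uniformly within this range per sample.
#' @param seed integer master seed.
#' @return A validated list of class \code{CohortConfig}.
#' @examples
#' cfg <- cohortConfig(nPatients = 4, nGenes = 200, seed = 1)
#' @export
cohortConfig <- function(nPatients = 8,
                         groups = c(CC = 1, LM1 = 1, AL = 1),
                         nGenes = 2000,
                         nLiverProgram = 40,
                         nColonProgram = 40,
                         mixtureWeight = 0.8,
                         plantedLogFC = 6,
                         nbDispersion = 0.1,
                         librarySizeRange = c(1e6, 2e7),
                         seed = 1) {
  cfg <- list(nPatients = as.integer(nPatients), groups = groups,
              nGenes = as.integer(nGenes),
              nLiverProgram = as.integer(nLiverProgram),
              nColonProgram = as.integer(nColonProgram),
              mixtureWeight = mixtureWeight, plantedLogFC = plantedLogFC,
              nbDispersion = nbDispersion,
              librarySizeRange = librarySizeRange, seed = as.integer(seed))
  classes <- c("CC", "LM1", "LM2", "LM3", "AL", "NC")
  if (is.null(names(groups)) || !all(names(groups) %in% classes))
    stop("'groups' must be named with tissue classes among: ",
         paste(classes, collapse = ", "))
  if (cfg$nLiverProgram + cfg$nColonProgram > cfg$nGenes)
    stop("nLiverProgram + nColonProgram must not exceed nGenes")
  if (mixtureWeight < 0 || mixtureWeight > 1)
    stop("'mixtureWeight' must lie in [0, 1]")
  if (nbDispersion <= 0) stop("'nbDispersion' must be positive")
  if (plantedLogFC < 0) stop("'plantedLogFC' must be non-negative")
  if (length(librarySizeRange) != 2L || any(librarySizeRange <= 0) ||
      librarySizeRange[1] > librarySizeRange[2])
    stop("'librarySizeRange' must be an ascending pair of positive numbers")
  if (nPatients < 1) stop("'nPatients' must be at least 1")
  class(cfg) <- "CohortConfig"
  cfg
}

#' Simulate a matched colon-to-liver metastasis cohort
#'
#' Draws negative-binomial counts for a cohort with tissue-specific
#' expression programs and metastasis profiles that are convex mixtures of
#' the tumor and liver programs in log2-mean space. Library sizes are
#' log-uniform within the configured range so that normalization is
#' exercised. Identical config (including seed) gives identical output.
#'
#' @param config a \code{\link{cohortConfig}}.
#' @return A \link[SummarizedExperiment]{SummarizedExperiment} with a
#'   \code{counts} assay, colData columns \code{patient_id},
#'   \code{tissue_class}, \code{matched}, and metadata entries
#'   \code{groundTruth} (planted DE/enrichment sets), \code{logMeans}
#'   (gene x tissue-class expected log2 means) and \code{config}.
#' @examples
#' se <- simulateCohort(cohortConfig(nPatients = 3, nGenes = 100, seed = 7))
#' table(SummarizedExperiment::colData(se)$tissue_class)
#' @export
simulateCohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  g <- config$nGenes
  geneIds <- sprintf("G%05d", seq_len(g))
  liverIdx <- seq_len(config$nLiverProgram)
  colonIdx <- seq_len(config$nColonProgram) + config$nLiverProgram
  w <- config$mixtureWeight

  .withSeed(.subSeed(config$seed, 1), {
    base <- stats::runif(g, 3, 8)
    muCC <- muAL <- base
    muCC[colonIdx] <- muCC[colonIdx] + config$plantedLogFC
    muAL[liverIdx] <- muAL[liverIdx] + config$plantedLogFC
    muLM <- (1 - w) * muCC + w * muAL
    logMeans <- cbind(CC = muCC, LM1 = muLM, LM2 = muLM, LM3 = muLM,
                      AL = muAL, NC = muCC)
    rownames(logMeans) <- geneIds

    classes <- rep(names(config$groups), times = config$groups)
    sampleClass <- rep(classes, times = config$nPatients)
    patient <- rep(sprintf("P%02d", seq_len(config$nPatients)),
                   each = length(classes))
    sampleIds <- paste(patient, sampleClass, sep = "_")
    libs <- exp(stats::runif(length(sampleIds),
                             log(config$librarySizeRange[1]),
                             log(config$librarySizeRange[2])))
    counts <- matrix(0L, nrow = g, ncol = length(sampleIds),
                     dimnames = list(geneIds, sampleIds))
    size <- 1 / config$nbDispersion
    for (j in seq_along(sampleIds)) {
      p <- 2^logMeans[, sampleClass[j]]
      p <- p / sum(p)
      counts[, j] <- stats::rnbinom(g, mu = p * libs[j], size = size)
    }
    storage.mode(counts) <- "integer"
  })

  planted <- w * config$plantedLogFC > 0
  truth <- list(
    de_up_genes = if (planted) geneIds[liverIdx] else character(),
    de_down_genes = if (planted) geneIds[colonIdx] else character(),
    liver_enriched = geneIds[liverIdx],
    intestine_enriched = geneIds[colonIdx],
    reverter_compounds = character(),
    synergy_pairs = list()
  )
  matchedPatients <- if (all(c("CC", "LM1") %in% names(config$groups)))
    unique(patient) else character()
  cd <- S4Vectors::DataFrame(
    sample_id = sampleIds, patient_id = patient,
    tissue_class = factor(sampleClass,
                          levels = c("CC", "LM1", "LM2", "LM3", "AL", "NC")),
    matched = patient %in% matchedPatients,
    row.names = sampleIds)
  SummarizedExperiment::SummarizedExperiment(
    assays = list(counts = counts), colData = cd,
    metadata = list(groundTruth = truth, logMeans = logMeans,
                    config = config))
}

#' Extract the planted ground truth of a simulated object
#'
#' @param x a SummarizedExperiment from \code{\link{simulateCohort}} or a
#'   list returned by the other simulators.
#' @return The planted ground-truth list.
#' @export
groundTruth <- function(x) {
  if (is(x, "SummarizedExperiment")) S4Vectors::metadata(x)$groundTruth
  else x$truth
}

#' Simulate a tissue-enrichment annotation table
#'
#' Builds a Protein-Atlas style annotation consistent with the planted
#' liver/intestine programs, then corrupts a seeded fraction of rows to
#' emulate annotation noise (a corrupted row is re-labelled "other").
#'
#' @param truth ground-truth list with \code{liver_enriched} and
#'   \code{intestine_enriched} gene sets.
#' @param noiseFraction fraction of rows to corrupt, in [0, 0.5).
#' @param seed integer seed.
#' @return data.frame with columns \code{gene_id}, \code{enriched_tissues}
#'   (semicolon-separated \code{"tissue: level"} entries) and a logical
#'   \code{corrupted} column marking the noise rows.
#' @export
simulateAnnotation <- function(truth, noiseFraction = 0, seed = 1) {
  if (noiseFraction < 0 || noiseFraction >= 0.5)
    stop("'noiseFraction' must lie in [0, 0.5)")
  genes <- sort(union(truth$liver_enriched, truth$intestine_enriched))
  if (!length(genes)) stop("ground truth contains no enriched genes")
  .withSeed(.subSeed(seed, 2), {
    tissues <- vapply(genes, function(gn) {
      tt <- c(if (gn %in% truth$intestine_enriched) "intestine",
              if (gn %in% truth$liver_enriched) "liver")
      lv <- round(10^stats::runif(length(tt), 1.5, 3.3), 1)
      paste(sprintf("%s: %.1f", tt, lv), collapse = ";")
    }, character(1))
    nFlip <- round(noiseFraction * length(genes))
    flip <- sample(seq_along(genes), nFlip)
  })
  tissues[flip] <- sprintf("other: %.1f", 50.0)
  data.frame(gene_id = genes, enriched_tissues = unname(tissues),
             corrupted = seq_along(genes) %in% flip,
             stringsAsFactors = FALSE)
}

#' Simulate a perturbation reference with planted signature reverters
#'
#' Generates a local connectivity-map style score matrix: most compounds
#' carry exchangeable random gene scores; planted reverter compounds push
#' the signature's up genes to the very bottom of their ranking (and down
#' genes to the top) in every context, so that a connectivity screen
#' recovers them as strong negative hits.
#'
#' @param signature a \linkS4class{SignatureSet} (non-empty).
#' @param nCompounds number of compounds.
#' @param nReverters number of planted reverters (<= nCompounds).
#' @param contexts character vector of cell-line context labels.
#' @param nGenes total genes in the reference (signature genes included).
#' @param seed integer seed.
#' @return list with elements \code{reference}
#'   (\linkS4class{PerturbationReference}) and \code{truth} (ground-truth
#'   list whose \code{reverter_compounds} names the planted ids).
#' @export
simulatePerturbationReference <- function(signature, nCompounds = 50,
                                          nReverters = 2,
                                          contexts = c("HEPG2like", "HT29like"),
                                          nGenes = 500, seed = 1) {
  sigGenes <- c(signatureUp(signature), signatureDown(signature))
  if (!length(sigGenes)) stop("signature is empty")
  if (nReverters > nCompounds)
    stop("'nReverters' must not exceed 'nCompounds'")
  nBg <- max(0L, nGenes - length(sigGenes))
  genes <- c(sigGenes, sprintf("BG%05d", seq_len(nBg)))
  compounds <- sprintf("CMP%03d", seq_len(nCompounds))
  classes <- c("COX inhibitor", "dopamine receptor antagonist",
               "histamine receptor antagonist", "PDE inhibitor",
               "EGFR inhibitor", "serotonin receptor antagonist")
  cols <- expand.grid(compound = compounds, context = contexts,
                      stringsAsFactors = FALSE)
  .withSeed(.subSeed(seed, 3), {
    scores <- matrix(stats::rnorm(length(genes) * nrow(cols)),
                     nrow = length(genes),
                     dimnames = list(genes,
                                     paste(cols$compound, cols$context,
                                           sep = "|")))
    reverters <- if (nReverters > 0) sample(compounds, nReverters)
                 else character()
    for (cmp in reverters) {
      jj <- which(cols$compound == cmp)
      up <- match(signatureUp(signature), genes)
      dn <- match(signatureDown(signature), genes)
      scores[up, jj] <- stats::rnorm(length(up) * length(jj), -10, 0.25)
      if (length(dn))
        scores[dn, jj] <- stats::rnorm(length(dn) * length(jj), 10, 0.25)
    }
    meta <- data.frame(compound = compounds,
                       name = paste0("compound-", seq_len(nCompounds)),
                       mechanism_class = sample(classes, nCompounds,
                                                replace = TRUE),
                       stringsAsFactors = FALSE)
  })
  truth <- list(de_up_genes = character(), de_down_genes = character(),
                liver_enriched = character(),
                intestine_enriched = character(),
                reverter_compounds = sort(reverters), synergy_pairs = list())
  list(reference = PerturbationReference(scores, cols$compound, cols$context,
                                         meta),
       truth = truth)
}

#' Simulate an organoid treatment experiment with planted effects
#'
#' Produces paired organoid timepoint measurements whose true response
#' score equals \code{rsEffect}, and a two-agent dose-response grid whose
#' combination cells equal the Bliss independence expectation of the
#' noise-free single-agent margins plus a constant planted excess plus
#' Gaussian noise, clipped to [0, 1].
#'
#' @param rsEffect planted response score (> 0); 1 means no effect.
#' @param blissExcess planted per-combination inhibition excess over Bliss
#'   independence (fraction scale; 0.2 corresponds to a synergy score of 20).
#' @param dosesA,dosesB ascending dose vectors including 0 (defaults
#'   emulate a pentoxifylline 0-100 uM by 5-FU 0-12.5 uM grid).
#' @param noiseSd standard deviation of the Gaussian noise added to
#'   combination cells (margins are noise-free by construction).
#' @param seed integer seed.
#' @return list with \code{t0}, \code{t72}
#'   (\linkS4class{OrganoidTimepoint}), \code{doseResponse}
#'   (\linkS4class{DoseResponseMatrix}) and \code{truth}.
#' @export
simulateOrganoidExperiment <- function(rsEffect = 4, blissExcess = 0.2,
                                       dosesA = c(0, 25, 50, 75, 100),
                                       dosesB = c(0, 3.125, 6.25, 9.375, 12.5),
                                       noiseSd = 0, seed = 1) {
  if (rsEffect <= 0) stop("'rsEffect' must be positive")
  if (noiseSd < 0) stop("'noiseSd' must be non-negative")
  if (dosesA[1] != 0 || dosesB[1] != 0)
    stop("dose grids must include the zero-dose single-agent margins")
  yA <- 0.6 * dosesA / (dosesA + stats::median(dosesA[-1]))
  yB <- 0.6 * dosesB / (dosesB + stats::median(dosesB[-1]))
  inh <- outer(yA, yB, blissExpected)
  combo <- as.matrix(expand.grid(i = seq_along(dosesA)[-1],
                                 j = seq_along(dosesB)[-1]))
  .withSeed(.subSeed(seed, 4), {
    noise <- stats::rnorm(nrow(combo), 0, noiseSd)
  })
  inh[combo] <- pmin(1, pmax(0, inh[combo] + blissExcess + noise))
  t0 <- OrganoidTimepoint(100, 200, 0.9)
  t72 <- OrganoidTimepoint(100, 200 / rsEffect, 0.9)
  truth <- list(rs = rsEffect, bliss_excess = blissExcess,
                synergy_pairs = data.frame(
                  dose_a = dosesA[combo[, 1]], dose_b = dosesB[combo[, 2]],
                  planted_excess = blissExcess))
  list(t0 = t0, t72 = t72,
       doseResponse = DoseResponseMatrix(dosesA, dosesB, inh),
       truth = truth)
}

#' Generate a synthetic pathway collection
#'
#' Draws gene sets of random size from a gene universe, emulating a
#' curated pathway database for clustering and enrichment tests.
#'
#' @param geneIds gene universe to draw from.
#' @param nPathways number of pathways (default emulates a 151-pathway
#'   curated collection).
#' @param sizeRange inclusive pathway size range.
#' @param seed integer seed.
#' @return Named list of character vectors (class \code{PathwayDB});
#'   names are pathway ids, each with a \code{description} attribute.
#' @export
simulatePathways <- function(geneIds, nPathways = 151,
                             sizeRange = c(8, 40), seed = 1) {
  stopifnot(length(geneIds) >= sizeRange[2])
  .withSeed(.subSeed(seed, 5), {
    db <- lapply(seq_len(nPathways), function(i) {
      sz <- sample(seq(sizeRange[1], sizeRange[2]), 1)
      sort(sample(geneIds, sz))
    })
  })
  names(db) <- sprintf("PW%04d", seq_len(nPathways))
  attr(db, "descriptions") <- sprintf("synthetic pathway %d",
                                      seq_len(nPathways))
  class(db) <- "PathwayDB"
  db
}
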