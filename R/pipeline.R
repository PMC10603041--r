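## End-to-end orchestration: normalize -> subset to the analysis gene set ->
## consensus NMF -> core samples -> stability -> Wilcoxon DE -> signatures
## (discovery), and score -> sign-classify -> stratify -> survival
## (classification). Every run writes a manifest recording parameters, the
## master seed, and md5 checksums of file inputs; manifests carry no
## timestamps, so repeated runs at a fixed seed are byte-identical.

PIPELINE_KEYS <- c(
  "counts", "clinical", "geneset", "matrix", "signatures", "outDir", "seed",
  "ranks", "nRuns", "B", "nBins", "nControlsPerGene", "adjPMax", "minLog2fc",
  "topN", "prior", "doTMM", "doHclust", "doStability", "maxIter", "tol",
  "foldMethod", "hclustResamples", "hclustFrac", "stratifyMode", "cutoff",
  "doSurvival")

#' Build and validate a pipeline configuration
#'
#' A flat declarative list; unknown keys are rejected. Input slots
#' (`counts`, `clinical`, `geneset`, `matrix`, `signatures`) accept either
#' file paths or in-memory objects.
#'
#' @param ... configuration entries (see [runDiscovery()] and
#'   [runClassification()] for the keys each stage reads).
#' @return list of class `PipelineConfig`.
#' @export
pipelineConfig <- function(...) {
  cfg <- list(...)
  unknown <- setdiff(names(cfg), PIPELINE_KEYS)
  if (length(unknown))
    stop(sprintf("unknown config key(s): %s", paste(unknown, collapse = ", ")))
  defaults <- list(seed = 1L, ranks = 2:4, nRuns = 30L, B = 50L, nBins = 30L,
                   nControlsPerGene = 100L, adjPMax = 0.05, minLog2fc = 0,
                   topN = 100L, prior = 0.5, doTMM = TRUE, doHclust = FALSE,
                   doStability = TRUE, maxIter = 2000L, tol = 1e-6,
                   foldMethod = "posneg", hclustResamples = 200L,
                   hclustFrac = 0.8, stratifyMode = "none", cutoff = 1.0,
                   doSurvival = FALSE)
  for (k in names(defaults)) if (is.null(cfg[[k]])) cfg[[k]] <- defaults[[k]]
  structure(cfg, class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file with flat keys (see [pipelineConfig()]).
#' @return list of class `PipelineConfig`.
#' @export
readPipelineConfig <- function(path) {
  do.call(pipelineConfig, yaml::read_yaml(path))
}

resolveInput <- function(x, reader) {
  if (is.character(x) && length(x) == 1L) {
    list(value = reader(x), checksum = unname(tools::md5sum(x)), path = x)
  } else {
    list(value = x, checksum = NA_character_, path = NA_character_)
  }
}

writeManifest <- function(outDir, stage, params, inputs, outputs) {
  manifest <- list(stage = stage, parameters = params,
                   inputs = inputs, outputs = outputs)
  jsonlite::write_json(manifest, file.path(outDir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
}

scrubParams <- function(cfg) {
  keep <- setdiff(names(cfg), c("counts", "clinical", "geneset", "matrix",
                                "signatures", "outDir"))
  cfg[keep]
}

logStage <- function(fmt, ...) message(sprintf(paste0("[ecmstates] ", fmt), ...))

#' Run the discovery pipeline
#'
#' Stages: TMM + logCPM normalization (when the input is counts), linear
#' batch removal using the clinical `cohort` column, gene mean-centering,
#' restriction to the analysis gene set, consensus NMF over `ranks`
#' (rank chosen by cophenetic coefficient), core-sample selection, optional
#' hierarchical-consensus cross-check and bootstrap-vs-null stability test,
#' per-cohort Wilcoxon differential expression on core samples, and
#' cross-cohort signature derivation.
#'
#' Config keys read: `counts`, `clinical`, `geneset`, `outDir`, `seed`,
#' `ranks`, `nRuns`, `B`, `nBins`, `adjPMax`, `minLog2fc`, `topN`, `prior`,
#' `doTMM`, `doHclust`, `doStability`, `maxIter`, `tol`, `foldMethod`,
#' `hclustResamples`, `hclustFrac`.
#'
#' @param config a [pipelineConfig()].
#' @return (invisibly) list with `normalized`, `centered`, `consensus`
#'   (per-rank results), `bestRank`, `labels`, `coreMask`, `stability`,
#'   `hclust`, `de`, `signatures`.
#' @export
runDiscovery <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  outDir <- config$outDir
  if (is.null(outDir)) stop("config needs an outDir")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  countsIn <- resolveInput(config$counts, readExpression)
  clinIn <- resolveInput(config$clinical, readClinical)
  gsIn <- resolveInput(config$geneset, function(p) readGMT(p)[[1]])
  counts <- countsIn$value
  clinical <- clinIn$value
  geneset <- gsIn$value
  if (ncol(exprValues(counts)) == 0) stop("stage normalize: empty input matrix")

  idx <- match(sampleIds(counts), clinical$sample_id)
  if (anyNA(idx)) stop("stage normalize: clinical table does not cover all samples")
  batch <- clinical$cohort[idx]

  seeds <- deriveSeeds(config$seed, 4L)  # consensus, hclust, stability, scoring

  ## normalize
  if (exprScale(counts) == "counts") {
    factors <- if (isTRUE(config$doTMM)) tmmFactors(counts) else NULL
    lc <- logCPM(counts, factors, prior = config$prior)
  } else lc <- counts
  lc@batch <- as.character(batch)
  corrected <- removeBatch(lc)
  logStage("normalize: %d genes x %d samples, %d batches",
           nrow(exprValues(corrected)), ncol(exprValues(corrected)),
           length(unique(batch)))
  geneMeans <- rowMeans(exprValues(corrected))
  centered <- centerGenes(corrected)

  gsPresent <- intersect(setGenes(geneset), geneIds(centered))
  if (!length(gsPresent)) stop("stage subset: no analysis gene present")
  sub <- subsetExpression(centered, genes = gsPresent)

  ## consensus NMF + rank selection
  consensus <- consensusNMF(sub, ranks = config$ranks, nRuns = config$nRuns,
                            seed = seeds[1], maxIter = config$maxIter,
                            tol = config$tol, foldMethod = config$foldMethod)
  coph <- vapply(consensus, copheneticCoef, numeric(1))
  best <- consensus[[which.max(coph)]]
  labels <- clusterLabels(best)
  logStage("discover: best rank %d (cophenetic %.4f), %d/%d core samples",
           best@rank, copheneticCoef(best), sum(best@coreMask), length(labels))

  hres <- NULL
  if (isTRUE(config$doHclust)) {
    hres <- consensusHclust(sub, rank = best@rank,
                            nResamples = config$hclustResamples,
                            subsampleFrac = config$hclustFrac, seed = seeds[2])
    logStage("hclust cross-check: ARI vs NMF labels %.3f",
             adjustedRandIndex(clusterLabels(hres), labels))
  }

  stability <- NULL
  if (isTRUE(config$doStability)) {
    stability <- bootstrapStability(centered, gsPresent, geneMeans,
                                    referenceLabels = labels, B = config$B,
                                    nBins = config$nBins, rank = best@rank,
                                    seed = seeds[3], maxIter = config$maxIter,
                                    tol = config$tol,
                                    foldMethod = config$foldMethod)
    logStage("stability: median observed ARI %.3f vs null 95th pct %.3f",
             median(stability@observedARI),
             quantile(stability@nullARI, 0.95))
  }

  ## DE on core samples, signature derivation
  core <- coreSamples(best)
  coreX <- subsetExpression(corrected, samples = core)
  classLab <- ifelse(labels[core] == 1L, "A", "B")
  names(classLab) <- core
  de <- wilcoxonDE(coreX, classLab)
  sigs <- deriveSignatures(de, adjPMax = config$adjPMax,
                           minLog2fc = config$minLog2fc, topN = config$topN)
  logStage("signatures: %d A-genes, %d B-genes",
           length(setGenes(signatureA(sigs))),
           length(setGenes(signatureB(sigs))))

  ## artifacts
  labFile <- file.path(outDir, "labels.tsv")
  write.table(data.frame(sample_id = names(labels), label = labels,
                         silhouette = silhouetteWidths(best),
                         core = best@coreMask),
              labFile, sep = "\t", quote = FALSE, row.names = FALSE)
  cophFile <- file.path(outDir, "cophenetic.tsv")
  write.table(data.frame(rank = as.integer(sub("rank", "", names(coph))),
                         cophenetic = unname(coph)),
              cophFile, sep = "\t", quote = FALSE, row.names = FALSE)
  consFiles <- character(0)
  for (nm in names(consensus)) {
    f <- file.path(outDir, paste0("consensus_", nm, ".tsv"))
    write.table(consensusMatrix(consensus[[nm]]), f, sep = "\t", quote = FALSE)
    consFiles <- c(consFiles, f)
  }
  sigFile <- file.path(outDir, "signatures.gmt")
  sigList <- Filter(function(s) length(s@genes) > 0,
                    list(signatureA(sigs), signatureB(sigs)))
  if (length(sigList)) writeGMT(sigList, sigFile) else sigFile <- NA_character_
  stabFile <- NA_character_
  if (!is.null(stability)) {
    stabFile <- file.path(outDir, "stability.json")
    jsonlite::write_json(list(observed_ari = stability@observedARI,
                              null_ari = stability@nullARI,
                              n_bins = stability@nBins, B = stability@B),
                         stabFile, auto_unbox = TRUE, digits = NA)
  }
  writeManifest(outDir, "discovery", scrubParams(unclass(config)),
                list(counts = countsIn$checksum, clinical = clinIn$checksum,
                     geneset = gsIn$checksum),
                list(labels = basename(labFile),
                     cophenetic = basename(cophFile),
                     consensus = basename(consFiles),
                     signatures = if (is.na(sigFile)) NULL else basename(sigFile),
                     stability = if (is.na(stabFile)) NULL else basename(stabFile)))

  invisible(list(normalized = corrected, centered = centered,
                 consensus = consensus, bestRank = best@rank, best = best,
                 labels = labels, coreMask = best@coreMask,
                 stability = stability, hclust = hres, de = de,
                 signatures = sigs, geneMeans = geneMeans))
}

#' Run the classification pipeline
#'
#' Normalizes the input matrix if it is counts (TMM + logCPM, no batch
#' term), scores every sample against both subtype signatures with
#' bin-matched controls, assigns `A` / `B` / `intermediate` by the sign
#' rule, optionally stratifies scores (quartile or cutoff mode) and runs a
#' log-rank test of the assigned groups against supplied clinical outcomes.
#'
#' Config keys read: `matrix`, `signatures`, `clinical` (optional),
#' `outDir`, `seed`, `nBins`, `nControlsPerGene`, `prior`, `doTMM`,
#' `stratifyMode` (`"none"`, `"quartile"`, `"cutoff"`), `cutoff`,
#' `doSurvival`.
#'
#' @param config a [pipelineConfig()].
#' @return (invisibly) list with `scores` (data.frame), `labels`,
#'   `classifiedFraction`, optional `strata` and `logrank`.
#' @export
runClassification <- function(config) {
  stopifnot(inherits(config, "PipelineConfig"))
  outDir <- config$outDir
  if (is.null(outDir)) stop("config needs an outDir")
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  matIn <- resolveInput(config$matrix, readExpression)
  sigIn <- resolveInput(config$signatures, function(p) {
    sets <- readGMT(p)
    if (length(sets) < 2L) stop("signature GMT needs two sets")
    new("SignatureSet", subtypeA = sets[[1]], subtypeB = sets[[2]],
        evidence = data.frame())
  })
  x <- matIn$value
  sigs <- sigIn$value
  if (ncol(exprValues(x)) == 0) stop("stage classify: empty input matrix")

  if (exprScale(x) == "counts") {
    factors <- if (isTRUE(config$doTMM)) tmmFactors(x) else NULL
    x <- logCPM(x, factors, prior = config$prior)
  }
  seeds <- deriveSeeds(config$seed, 2L)
  scoreA <- signatureScore(x, signatureA(sigs), nBins = config$nBins,
                           nControlsPerGene = config$nControlsPerGene,
                           seed = seeds[1])
  scoreB <- signatureScore(x, signatureB(sigs), nBins = config$nBins,
                           nControlsPerGene = config$nControlsPerGene,
                           seed = seeds[2])
  labels <- classifyBySign(scoreA, scoreB)
  classified <- 1 - mean(labels == "intermediate")
  logStage("classify: %d samples, %.1f%% classified", length(labels),
           100 * classified)

  strata <- NULL
  if (config$stratifyMode %in% c("quartile", "cutoff"))
    strata <- stratifyScores(scoreA, mode = config$stratifyMode,
                             cutoff = config$cutoff)

  lr <- NULL
  if (isTRUE(config$doSurvival) && !is.null(config$clinical)) {
    clinIn <- resolveInput(config$clinical, readClinical)
    clin <- clinIn$value
    grp <- labels[match(clin$sample_id, names(labels))]
    keep <- !is.na(grp) & grp != "intermediate"
    if (length(unique(grp[keep])) >= 2L) {
      lr <- logrankTest(clin$os_time[keep], clin$os_event[keep], grp[keep])
      logStage("survival: log-rank chi2 %.2f, p = %.3g", lr$chi2, lr$p)
    }
  }

  scoreFile <- file.path(outDir, "scores.tsv")
  scoreTab <- data.frame(sample_id = names(labels), score_a = scoreA,
                         score_b = scoreB, label = labels,
                         row.names = NULL)
  if (!is.null(strata)) scoreTab$stratum <- unname(strata)
  write.table(scoreTab, scoreFile, sep = "\t", quote = FALSE,
              row.names = FALSE)
  if (!is.null(lr))
    jsonlite::write_json(list(chi2 = lr$chi2, df = lr$df, p = lr$p,
                              observed = as.list(lr$observed),
                              expected = as.list(lr$expected)),
                         file.path(outDir, "logrank.json"),
                         auto_unbox = TRUE, digits = NA)
  writeManifest(outDir, "classification", scrubParams(unclass(config)),
                list(matrix = matIn$checksum, signatures = sigIn$checksum),
                list(scores = basename(scoreFile)))

  invisible(list(scores = scoreTab, labels = labels,
                 classifiedFraction = classified, strata = strata,
                 logrank = lr))
}
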