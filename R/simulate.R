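## Synthetic multi-cohort study generator. Emulates the structure the
## discovery pipeline assumes: a shared per-gene baseline on the log2 scale,
## additive gene-wise cohort (batch) offsets, two latent subtypes that
## upregulate disjoint "matrisome" signature blocks, negative-binomial
## counts with per-sample library sizes, subtype-dependent exponential
## survival with uniform censoring, and a toy labeled cell x gene matrix
## with planted cell-type markers.

#' Build and validate a simulation configuration
#'
#' @param nGenes total genes.
#' @param nMatrisome size of the planted "matrisome" analysis gene set
#'   (the first `nMatrisome` genes).
#' @param nSignaturePerSubtype planted signature genes per subtype; the hi
#'   signature occupies matrisome genes 1..n, the lo signature the next n.
#' @param nSamplesPerCohort integer vector, samples per cohort.
#' @param subtypeProportion proportion of `hi` samples within each cohort,
#'   allocated deterministically by rounding.
#' @param effectLog2fc log2 fold-change added to a subtype's own signature
#'   genes.
#' @param batchLog2OffsetSd sd of gene-wise additive cohort offsets (log2).
#' @param nbDispersion negative-binomial dispersion (1/size), global.
#' @param libsizeLogMean,libsizeLogSd natural-log mean/sd of per-sample
#'   library sizes.
#' @param hazardRatio hazard of `hi` relative to `lo`.
#' @param baselineHazard event hazard (per month) of the `lo` subtype.
#' @param censorRate target fraction of censored subjects, in \[0, 1).
#' @param seed integer seed.
#' @return A validated config (list, class `SimulationConfig`).
#' @export
simulationConfig <- function(nGenes = 2000L, nMatrisome = 200L,
                             nSignaturePerSubtype = 40L,
                             nSamplesPerCohort = c(50L, 50L, 50L),
                             subtypeProportion = 0.5, effectLog2fc = 1.0,
                             batchLog2OffsetSd = 0.3, nbDispersion = 0.1,
                             libsizeLogMean = log(2e6), libsizeLogSd = 0.3,
                             hazardRatio = 2.0, baselineHazard = 1 / 15,
                             censorRate = 0.2, seed = 1L) {
  cfg <- list(nGenes = as.integer(nGenes), nMatrisome = as.integer(nMatrisome),
              nSignaturePerSubtype = as.integer(nSignaturePerSubtype),
              nSamplesPerCohort = as.integer(nSamplesPerCohort),
              subtypeProportion = subtypeProportion,
              effectLog2fc = effectLog2fc,
              batchLog2OffsetSd = batchLog2OffsetSd,
              nbDispersion = nbDispersion,
              libsizeLogMean = libsizeLogMean, libsizeLogSd = libsizeLogSd,
              hazardRatio = hazardRatio, baselineHazard = baselineHazard,
              censorRate = censorRate, seed = as.integer(seed))
  with(cfg, {
    if (2L * nSignaturePerSubtype > nMatrisome)
      stop("need 2 x nSignaturePerSubtype <= nMatrisome")
    if (nMatrisome > nGenes) stop("need nMatrisome <= nGenes")
    if (subtypeProportion <= 0 || subtypeProportion >= 1)
      stop("subtypeProportion must be in (0,1)")
    if (effectLog2fc < 0 || batchLog2OffsetSd < 0)
      stop("effectLog2fc and batchLog2OffsetSd must be >= 0")
    if (nbDispersion <= 0) stop("nbDispersion must be > 0")
    if (hazardRatio <= 0 || baselineHazard <= 0)
      stop("hazardRatio and baselineHazard must be > 0")
    if (censorRate < 0 || censorRate >= 1)
      stop("censorRate must be in [0,1)")
    if (any(nSamplesPerCohort < 1L)) stop("each cohort needs >= 1 sample")
  })
  structure(cfg, class = "SimulationConfig")
}

geneNames <- function(n) sprintf("gene%05d", seq_len(n))

#' Simulate a multi-cohort bulk RNA-seq study with planted subtypes
#'
#' Per-gene baseline log2 means are drawn once and shared across cohorts;
#' each cohort adds gene-wise Normal(0, `batchLog2OffsetSd`) offsets; `hi`
#' samples add `effectLog2fc` to the hi-signature genes and `lo` samples to
#' the lo-signature genes. Counts are negative-binomial around
#' library-size-scaled expected fractions. Deterministic under a fixed seed.
#'
#' @param config a [simulationConfig()].
#' @return A list (class `SimulatedStudy`) with elements `counts`
#'   ([ExpressionMatrix-class], scale `"counts"`), `truthLabels` (named
#'   `"hi"`/`"lo"` per sample), `truthSignatureHi`, `truthSignatureLo`,
#'   `matrisome` ([GeneSet-class]), `clinical` (data.frame incl. truth
#'   label column), and `config`.
#' @export
simulateBulk <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(config$seed)
  G <- config$nGenes
  genes <- geneNames(G)
  nSig <- config$nSignaturePerSubtype
  sigHi <- genes[seq_len(nSig)]
  sigLo <- genes[nSig + seq_len(nSig)]
  matrisome <- genes[seq_len(config$nMatrisome)]

  baseline <- rnorm(G, mean = 5, sd = 1.8)  # log2 relative abundance
  nCoh <- length(config$nSamplesPerCohort)
  cohorts <- sprintf("cohort%d", seq_len(nCoh))
  batchOffset <- matrix(rnorm(G * nCoh, 0, config$batchLog2OffsetSd),
                        nrow = G, dimnames = list(genes, cohorts))

  counts <- NULL; labels <- character(0); batch <- character(0)
  sampleIds <- character(0)
  for (c in seq_len(nCoh)) {
    n <- config$nSamplesPerCohort[c]
    nHi <- round(config$subtypeProportion * n)
    lab <- c(rep("hi", nHi), rep("lo", n - nHi))
    mu <- baseline + batchOffset[, c]
    lib <- exp(rnorm(n, config$libsizeLogMean, config$libsizeLogSd))
    cm <- matrix(0, nrow = G, ncol = n)
    for (j in seq_len(n)) {
      lmu <- mu
      if (lab[j] == "hi") lmu[seq_len(nSig)] <- lmu[seq_len(nSig)] + config$effectLog2fc
      else lmu[nSig + seq_len(nSig)] <- lmu[nSig + seq_len(nSig)] + config$effectLog2fc
      p <- 2^lmu; p <- p / sum(p)
      cm[, j] <- rnbinom(G, mu = p * lib[j], size = 1 / config$nbDispersion)
    }
    counts <- cbind(counts, cm)
    labels <- c(labels, lab)
    batch <- c(batch, rep(cohorts[c], n))
    sampleIds <- c(sampleIds, sprintf("%s_s%03d", cohorts[c], seq_len(n)))
  }
  dimnames(counts) <- list(genes, sampleIds)
  em <- ExpressionMatrix(counts, batch = batch, scale = "counts")
  names(labels) <- sampleIds

  clinical <- simulateSurvival(labels, config)
  clinical$cohort <- batch

  structure(list(counts = em, truthLabels = labels,
                 truthSignatureHi = GeneSet("truth_sig_hi", sigHi),
                 truthSignatureLo = GeneSet("truth_sig_lo", sigLo),
                 matrisome = GeneSet("matrisome", matrisome),
                 clinical = clinical, config = config),
            class = "SimulatedStudy")
}

## Uniform(0, b) censoring of Exp(h) event times: P(censored) =
## (1 - exp(-h b)) / (h b), solved for b to hit the target rate.
uniformCensorBound <- function(hazard, rate) {
  if (rate <= 0) return(Inf)
  f <- function(b) (1 - exp(-hazard * b)) / (hazard * b) - rate
  stats::uniroot(f, lower = 1e-8, upper = 1e8, tol = 1e-10)$root
}

#' Simulate survival outcomes for labeled samples
#'
#' Event times are exponential with hazard `baselineHazard` for `lo` and
#' `baselineHazard * hazardRatio` for `hi`; censoring times are independent
#' Uniform(0, b) with b chosen per group so the expected censored fraction
#' equals `censorRate`.
#'
#' @param labels named character vector of `"hi"`/`"lo"` per sample.
#' @param config a [simulationConfig()].
#' @return Clinical data.frame: `sample_id`, `cohort`, `os_time`,
#'   `os_event`, `truth_label`.
#' @export
simulateSurvival <- function(labels, config) {
  stopifnot(inherits(config, "SimulationConfig"), length(labels) > 0)
  haz <- ifelse(labels == "hi",
                config$baselineHazard * config$hazardRatio,
                config$baselineHazard)
  t <- rexp(length(labels), rate = haz)
  if (config$censorRate > 0) {
    bHi <- uniformCensorBound(config$baselineHazard * config$hazardRatio,
                              config$censorRate)
    bLo <- uniformCensorBound(config$baselineHazard, config$censorRate)
    cens <- runif(length(labels)) * ifelse(labels == "hi", bHi, bLo)
    event <- as.numeric(t <= cens)
    t <- pmin(t, cens)
  } else {
    event <- rep(1, length(labels))
  }
  data.frame(sample_id = if (is.null(names(labels)))
               sprintf("s%03d", seq_along(labels)) else names(labels),
             cohort = "cohort1", os_time = t, os_event = event,
             truth_label = unname(labels), stringsAsFactors = FALSE)
}

#' Simulate a labeled single-cell count matrix with planted markers
#'
#' Background genes share lognormal Poisson means across cell types. Each
#' planted marker of a type is "on" (Poisson mean `onScale * foldChange`)
#' in `exprProb` of that type's cells and at a near-zero background mean
#' (`backgroundMean`) otherwise, so its detection fraction in its own type
#' tracks `exprProb` and its mean fold-change over other cells exceeds
#' `foldChange`.
#'
#' @param nCellsPerType named integer vector (cell type -> cell count);
#'   types with zero cells are dropped.
#' @param nGenes total genes.
#' @param markerPlan named list (per type) of lists with elements `genes`
#'   (character, must be disjoint across types), `exprProb` in (0,1\],
#'   `foldChange` >= 1.
#' @param seed integer seed.
#' @param onScale Poisson mean, per unit fold-change, of an "on" marker.
#' @param backgroundMean Poisson mean of a marker outside its "on" cells.
#' @return list with `counts` (cells x genes integer matrix), `cellLabels`
#'   (named character), `markerPlan`.
#' @export
simulateSingleCell <- function(nCellsPerType, nGenes, markerPlan, seed,
                               onScale = 2.5, backgroundMean = 0.02) {
  stopifnot(length(nCellsPerType) > 0, !is.null(names(nCellsPerType)))
  allMark <- unlist(lapply(markerPlan, `[[`, "genes"))
  if (anyDuplicated(allMark))
    stop(sprintf("marker gene(s) planted for multiple types: %s",
                 paste(unique(allMark[duplicated(allMark)]), collapse = ", ")))
  genes <- sprintf("scg%05d", seq_len(nGenes))
  for (ty in names(markerPlan)) {
    bad <- setdiff(markerPlan[[ty]]$genes, genes)
    if (length(bad)) stop(sprintf("unknown marker gene(s): %s",
                                  paste(bad, collapse = ", ")))
  }
  set.seed(seed)
  nCellsPerType <- nCellsPerType[nCellsPerType > 0]
  types <- rep(names(nCellsPerType), nCellsPerType)
  nCells <- length(types)
  cells <- sprintf("cell%05d", seq_len(nCells))
  baseMean <- exp(rnorm(nGenes, log(0.5), 0.8))
  names(baseMean) <- genes
  baseMean[allMark] <- backgroundMean
  counts <- matrix(rpois(nCells * nGenes, rep(baseMean, each = nCells)),
                   nrow = nCells, dimnames = list(cells, genes))
  for (ty in names(markerPlan)) {
    plan <- markerPlan[[ty]]
    rows <- which(types == ty)
    if (!length(rows)) next
    for (g in plan$genes) {
      on <- rows[runif(length(rows)) < plan$exprProb]
      counts[on, g] <- rpois(length(on), onScale * plan$foldChange)
    }
  }
  list(counts = counts, cellLabels = setNames(types, cells),
       markerPlan = markerPlan)
}
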