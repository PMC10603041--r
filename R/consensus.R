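## Consensus clustering machinery: repeated-restart consensus NMF with
## cophenetic rank selection, a subsampled hierarchical-consensus
## alternative, silhouette-based core samples, the Adjusted Rand Index,
## bin-matched control gene sets, and the bootstrap-vs-null stability test.

## Derive a reproducible vector of sub-seeds from one master seed.
deriveSeeds <- function(seed, n) {
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

asMatrixInput <- function(x, centered = TRUE) {
  if (is(x, "ExpressionMatrix")) {
    if (centered && exprScale(x) != "centered_logcpm")
      stop("expected a mean-centered matrix (scale 'centered_logcpm')")
    exprValues(x)
  } else {
    stopifnot(is.matrix(x))
    x
  }
}

## Build a ConsensusResult from an accumulated consensus matrix: cut the
## average-linkage tree on 1 - consensus at `rank`, correlate consensus
## dissimilarities with the tree's cophenetic distances, and compute
## silhouettes on 1 - consensus.
consensusFromMatrix <- function(consensus, rank, nRuns, seed) {
  d <- as.dist(1 - consensus)
  tree <- hclust(d, method = "average")
  labels <- cutree(tree, k = rank)
  coph <- cophenetic(tree)
  cc <- if (sd(d) < 1e-12 || sd(coph) < 1e-12) 0 else cor(d, coph)
  sil <- silhouetteWidthsFromDist(labels, as.matrix(d))
  new("ConsensusResult", rank = as.integer(rank), consensus = consensus,
      labels = as.integer(labels), cophenetic = as.numeric(cc),
      silhouette = as.numeric(sil), coreMask = as.numeric(sil) > 0,
      nRuns = as.integer(nRuns), seed = as.integer(seed))
}

## Per-sample silhouette widths for a labeling on a distance matrix
## (cluster::silhouette; singletons get width 0, its convention).
silhouetteWidthsFromDist <- function(labels, dmat) {
  if (length(unique(labels)) < 2L) return(rep(0, length(labels)))
  sil <- cluster::silhouette(as.integer(labels), dmatrix = dmat)
  out <- sil[, "sil_width"]
  names(out) <- colnames(dmat)
  out
}

#' Consensus NMF over a set of ranks
#'
#' For each rank, the mean-centered matrix is folded non-negative
#' ([posnegFold()] by default), factorized `nRuns` times from random
#' restarts, and per-run argmax-of-H sample labels are aggregated into a
#' consensus (co-clustering frequency) matrix. Final labels cut the
#' average-linkage tree on `1 - consensus`; the cophenetic coefficient
#' correlates consensus dissimilarities with the tree's cophenetic
#' distances; silhouettes (and the core-sample mask, silhouette > 0) are
#' computed on `1 - consensus`.
#'
#' @param x mean-centered [ExpressionMatrix-class] (already restricted to
#'   the analysis gene set) or a plain numeric matrix.
#' @param ranks integer vector of ranks to evaluate (each >= 2).
#' @param nRuns NMF restarts per rank (default 30).
#' @param seed integer master seed; run seeds are derived from it.
#' @param maxIter,tol passed to [klNMF()].
#' @param foldMethod `"posneg"` (default) or `"shift-min"`.
#' @return Named list of [ConsensusResult-class], one per rank
#'   (`"rank2"`, ...).
#' @export
consensusNMF <- function(x, ranks = 2:4, nRuns = 30L, seed = 1L,
                         maxIter = 2000L, tol = 1e-6,
                         foldMethod = c("posneg", "shift-min")) {
  foldMethod <- match.arg(foldMethod)
  v <- asMatrixInput(x)
  n <- ncol(v)
  if (n < 10L) stop("consensus clustering needs >= 10 samples")
  if (any(ranks >= n)) stop("rank must be smaller than the number of samples")
  if (any(ranks < 2L)) stop("ranks must be >= 2")
  vf <- foldNonNegative(v, foldMethod)
  seeds <- matrix(deriveSeeds(seed, length(ranks) * nRuns),
                  nrow = length(ranks))
  out <- list()
  for (i in seq_along(ranks)) {
    r <- ranks[i]
    C <- matrix(0, n, n)
    for (run in seq_len(nRuns)) {
      fit <- klNMF(vf, r, seed = seeds[i, run], maxIter = maxIter, tol = tol)
      lab <- nmfLabels(fit$H)
      C <- C + outer(lab, lab, "==")
    }
    C <- C / nRuns
    dimnames(C) <- list(colnames(v), colnames(v))
    out[[paste0("rank", r)]] <- consensusFromMatrix(C, r, nRuns, seed)
  }
  out
}

#' Consensus clustering by subsampled hierarchical clustering
#'
#' Repeatedly subsamples `subsampleFrac` of the samples, clusters them by
#' average-linkage hierarchical clustering on Euclidean distance, and
#' accumulates co-clustered / co-sampled pair frequencies into a consensus
#' matrix; labels, cophenetic coefficient and silhouettes as in
#' [consensusNMF()].
#'
#' @param x mean-centered [ExpressionMatrix-class] or matrix.
#' @param rank number of clusters.
#' @param nResamples subsampling iterations (default 1000).
#' @param subsampleFrac fraction of samples per iteration (default 0.8).
#' @param seed integer seed.
#' @return A [ConsensusResult-class].
#' @export
consensusHclust <- function(x, rank = 2L, nResamples = 1000L,
                            subsampleFrac = 0.8, seed = 1L) {
  v <- asMatrixInput(x)
  n <- ncol(v)
  if (n < 10L) stop("consensus clustering needs >= 10 samples")
  if (rank >= n) stop("rank must be smaller than the number of samples")
  set.seed(as.integer(seed))
  m <- max(2L, round(subsampleFrac * n))
  co <- matrix(0, n, n)   # co-clustered counts
  tog <- matrix(0, n, n)  # co-sampled counts
  for (b in seq_len(nResamples)) {
    idx <- if (m >= n) seq_len(n) else sort(sample.int(n, m))
    lab <- cutree(hclust(dist(t(v[, idx, drop = FALSE])), method = "average"),
                  k = rank)
    conn <- outer(lab, lab, "==")
    co[idx, idx] <- co[idx, idx] + conn
    tog[idx, idx] <- tog[idx, idx] + 1
  }
  C <- ifelse(tog > 0, co / pmax(tog, 1), 0)
  diag(C) <- 1
  dimnames(C) <- list(colnames(v), colnames(v))
  consensusFromMatrix(C, rank, nResamples, seed)
}

#' Cophenetic coefficients averaged over repeated consensus runs
#'
#' Runs [consensusNMF()] `nReps` times with independent derived seeds and
#' averages the per-rank cophenetic coefficients, the basis for rank
#' selection.
#'
#' @inheritParams consensusNMF
#' @param nReps number of consensus repetitions to average over (default 5).
#' @return data.frame with columns `rank`, `mean_cophenetic`, `sd_cophenetic`.
#' @export
selectRank <- function(x, ranks = 2:4, nRuns = 30L, nReps = 5L, seed = 1L,
                       maxIter = 2000L, tol = 1e-6,
                       foldMethod = c("posneg", "shift-min")) {
  foldMethod <- match.arg(foldMethod)
  seeds <- deriveSeeds(seed, nReps)
  cc <- sapply(seeds, function(s) {
    res <- consensusNMF(x, ranks = ranks, nRuns = nRuns, seed = s,
                        maxIter = maxIter, tol = tol, foldMethod = foldMethod)
    vapply(res, copheneticCoef, numeric(1))
  })
  cc <- matrix(cc, nrow = length(ranks))
  data.frame(rank = ranks, mean_cophenetic = rowMeans(cc),
             sd_cophenetic = apply(cc, 1, sd))
}

#' Adjusted Rand Index between two labelings
#'
#' Chance-corrected agreement between two partitions of the same items,
#' computed from the contingency table under the permutation model.
#'
#' @param a,b label vectors of equal length (any types coercible to factor).
#' @return ARI in \[-1, 1\]; 1 for identical partitions.
#' @export
adjustedRandIndex <- function(a, b) {
  if (length(a) != length(b)) stop("labelings must have equal length")
  if (length(a) < 2L) stop("need at least 2 items")
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sumIJ <- sum(choose2(tab))
  sumA <- sum(choose2(rowSums(tab)))
  sumB <- sum(choose2(colSums(tab)))
  nPairs <- choose2(length(a))
  expected <- sumA * sumB / nPairs
  maxIndex <- (sumA + sumB) / 2
  if (abs(maxIndex - expected) < .Machine$double.eps) return(1)
  (sumIJ - expected) / (maxIndex - expected)
}

#' Draw a bin-matched control gene set
#'
#' All analyzed genes are cut into `nBins` equal-frequency bins of their
#' average expression; for every source gene one control is drawn uniformly
#' from the same bin, excluding the source gene itself. Draws are without
#' replacement within the call while bin occupancy allows, otherwise with
#' replacement and a warning.
#'
#' @param geneSet [GeneSet-class] or character vector of source genes; must
#'   be a subset of `names(geneMeans)`.
#' @param geneMeans named numeric vector: average (log-scale) expression of
#'   every analyzed gene across all samples.
#' @param nBins number of expression bins (default 30).
#' @param seed optional integer seed.
#' @param excludeSet exclude *every* source-set gene from the control pools
#'   (default FALSE, which excludes only the gene being matched). The
#'   clustering-stability null uses TRUE: its question is whether a gene set
#'   disjoint from the analysis set recapitulates the clustering.
#' @return Character vector of control genes (same length and order as the
#'   source set, names = source genes). May contain duplicates only in the
#'   with-replacement fallback.
#' @export
binMatchedControls <- function(geneSet, geneMeans, nBins = 30L, seed = NULL,
                               excludeSet = FALSE) {
  genes <- if (is(geneSet, "GeneSet")) setGenes(geneSet) else as.character(geneSet)
  if (!length(genes)) stop("empty source gene set")
  if (is.null(names(geneMeans))) stop("geneMeans must be named")
  missing <- setdiff(genes, names(geneMeans))
  if (length(missing))
    stop(sprintf("source gene(s) absent from geneMeans: %s",
                 paste(head(missing, 3), collapse = ", ")))
  if (nBins < 1L) stop("nBins must be >= 1")
  if (!is.null(seed)) set.seed(as.integer(seed))
  bins <- expressionBins(geneMeans, nBins)
  used <- character(0)
  warned <- FALSE
  out <- character(length(genes))
  for (i in seq_along(genes)) {
    g <- genes[i]
    pool <- names(bins)[bins == bins[g]]
    pool <- setdiff(pool, if (excludeSet) genes else g)
    if (!length(pool))
      stop(sprintf("empty bin after excluding source gene '%s'", g))
    fresh <- setdiff(pool, used)
    if (length(fresh)) {
      pick <- fresh[sample.int(length(fresh), 1L)]
    } else {
      if (!warned) {
        warning("bin occupancy exhausted; sampling controls with replacement")
        warned <- TRUE
      }
      pick <- pool[sample.int(length(pool), 1L)]
    }
    used <- c(used, pick)
    out[i] <- pick
  }
  names(out) <- genes
  out
}

## Equal-frequency (quantile) bin index for every gene mean. Duplicate
## quantile breaks collapse; include.lowest keeps the minimum in bin 1.
expressionBins <- function(geneMeans, nBins) {
  br <- unique(quantile(geneMeans, probs = seq(0, 1, length.out = nBins + 1),
                        type = 7, names = FALSE))
  if (length(br) < 2L) br <- c(br - 1e-9, br + 1e-9)
  bins <- cut(geneMeans, breaks = br, include.lowest = TRUE, labels = FALSE)
  names(bins) <- names(geneMeans)
  bins
}

#' Bootstrap gene-set stability against a bin-matched null
#'
#' Observed arm: `B` bootstrap resamples (with replacement, same size) of
#' the analysis gene set, each re-clustered by a single-restart rank-`rank`
#' KL-NMF on the folded centered matrix; the ARI of the resulting labels
#' against `referenceLabels` is recorded. Null arm: the same procedure on
#' `B` bin-matched control gene sets drawn disjoint from the analysis set
#' (a control set that re-used analysis genes would partially recapitulate
#' the clustering by construction rather than by chance).
#'
#' @param x mean-centered [ExpressionMatrix-class] or matrix containing
#'   **all** analyzed genes (controls are drawn from the full gene space).
#' @param geneSet [GeneSet-class] or character: the analysis gene set.
#' @param geneMeans named average log-expression of all analyzed genes
#'   (uncentered scale), used for binning.
#' @param referenceLabels labels from the reference consensus clustering,
#'   aligned to the samples of `x`.
#' @param B resamples per arm (default 50).
#' @param nBins expression bins (default 30).
#' @param rank clustering rank (default 2).
#' @param seed integer seed; all draws consume one stream seeded once.
#' @param maxIter,tol single-restart NMF controls; defaults (500, 1e-5) are
#'   looser than [klNMF()]'s because argmax label assignments stabilize long
#'   before deep divergence convergence.
#' @param foldMethod see [consensusNMF()].
#' @return A [StabilityReport-class].
#' @export
bootstrapStability <- function(x, geneSet, geneMeans, referenceLabels,
                               B = 50L, nBins = 30L, rank = 2L, seed = 1L,
                               maxIter = 500L, tol = 1e-5,
                               foldMethod = c("posneg", "shift-min")) {
  foldMethod <- match.arg(foldMethod)
  if (B < 1L) stop("B must be >= 1")
  v <- asMatrixInput(x)
  genes <- if (is(geneSet, "GeneSet")) setGenes(geneSet) else as.character(geneSet)
  stopifnot(all(genes %in% rownames(v)),
            length(referenceLabels) == ncol(v))
  set.seed(as.integer(seed))
  reclusterARI <- function(rows) {
    vf <- foldNonNegative(v[rows, , drop = FALSE], foldMethod)
    fit <- klNMF(vf, rank, seed = NULL, maxIter = maxIter, tol = tol)
    adjustedRandIndex(nmfLabels(fit$H), referenceLabels)
  }
  observed <- vapply(seq_len(B), function(b)
    reclusterARI(sample(genes, length(genes), replace = TRUE)), numeric(1))
  null <- vapply(seq_len(B), function(b)
    reclusterARI(unname(binMatchedControls(genes, geneMeans, nBins,
                                           excludeSet = TRUE))),
    numeric(1))
  new("StabilityReport", observedARI = observed, nullARI = null,
      nBins = as.integer(nBins), B = as.integer(B), seed = as.integer(seed))
}
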