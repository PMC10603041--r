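## Cross-cohort signature derivation (per-cohort Wilcoxon + BH, intersection
## of top markers), bin-matched-control signature scoring, sign-based
## classification, single-cell marker selection, quartile/cutoff
## stratification, and pseudobulk aggregation.

#' Per-cohort Wilcoxon differential expression between two classes
#'
#' Two-sided Wilcoxon rank-sum per gene within each cohort: exact
#' enumeration when both groups have <= 25 samples and there are no ties,
#' otherwise the normal approximation with tie and continuity correction.
#' P-values are Benjamini-Hochberg adjusted within each cohort; `log2fc`
#' is the class-A minus class-B mean on the log-scale values.
#'
#' @param x [ExpressionMatrix-class] on a log scale (core samples only).
#' @param labels named vector assigning each sample of `x` to one of two
#'   classes; the *first sorted unique value* is class A.
#' @param cohorts per-sample cohort labels; defaults to `batchLabels(x)`.
#' @return data.frame with columns `gene_id`, `cohort`, `log2fc`, `p`,
#'   `padj`.
#' @export
wilcoxonDE <- function(x, labels, cohorts = NULL) {
  stopifnot(is(x, "ExpressionMatrix"))
  v <- exprValues(x)
  if (!is.null(names(labels))) {
    if (!all(sampleIds(x) %in% names(labels)))
      stop("labels do not cover all samples")
    labels <- labels[sampleIds(x)]
  }
  if (is.null(cohorts)) cohorts <- x@batch
  stopifnot(length(labels) == ncol(v), length(cohorts) == ncol(v))
  classes <- sort(unique(as.character(labels)))
  if (length(classes) != 2L) stop("labels must contain exactly 2 classes")
  out <- list()
  for (coh in unique(cohorts)) {
    inCoh <- cohorts == coh
    ia <- inCoh & labels == classes[1]
    ib <- inCoh & labels == classes[2]
    if (sum(ia) < 2L || sum(ib) < 2L)
      stop(sprintf("cohort '%s' lacks >= 2 samples in each class", coh))
    va <- v[, ia, drop = FALSE]
    vb <- v[, ib, drop = FALSE]
    p <- vapply(seq_len(nrow(v)), function(g) {
      a <- va[g, ]; b <- vb[g, ]
      if (sd(c(a, b)) == 0) return(1)  # degenerate: every value tied
      exact <- length(a) <= 25L && length(b) <= 25L &&
        !anyDuplicated(c(a, b))
      suppressWarnings(
        wilcox.test(a, b, alternative = "two.sided", exact = exact,
                    correct = TRUE)$p.value)
    }, numeric(1))
    out[[coh]] <- data.frame(
      gene_id = rownames(v), cohort = coh,
      log2fc = rowMeans(va) - rowMeans(vb),
      p = p, padj = p.adjust(p, method = "BH"),
      stringsAsFactors = FALSE, row.names = NULL)
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Derive paired subtype signatures by cross-cohort intersection
#'
#' Within each cohort, "top markers" of a class are the genes with
#' `padj <= adjPMax` and class-wise `log2fc > minLog2fc`, ranked by absolute
#' log2 fold-change and truncated to `topN`. A signature is the intersection
#' of a class's top markers across all cohorts; both classes are processed
#' symmetrically.
#'
#' @param de output of [wilcoxonDE()] covering >= 2 cohorts.
#' @param adjPMax BH-adjusted p-value ceiling (default 0.05).
#' @param minLog2fc minimum class-wise log2 fold-change (default 0).
#' @param topN per-cohort marker list length (default 100).
#' @param nameA,nameB names given to the two signatures.
#' @return A [SignatureSet-class]; an empty intersection yields an empty
#'   signature with a warning.
#' @export
deriveSignatures <- function(de, adjPMax = 0.05, minLog2fc = 0, topN = 100L,
                             nameA = "subtypeA", nameB = "subtypeB") {
  stopifnot(all(c("gene_id", "cohort", "log2fc", "padj") %in% names(de)))
  cohorts <- unique(de$cohort)
  if (length(cohorts) < 2L) stop("need DE tables for >= 2 cohorts")
  topMarkers <- function(sign) {
    lapply(cohorts, function(coh) {
      d <- de[de$cohort == coh, ]
      fc <- sign * d$log2fc
      d <- d[d$padj <= adjPMax & fc > minLog2fc, ]
      d <- d[order(-sign * d$log2fc), ]
      head(d$gene_id, topN)
    })
  }
  gsOrEmpty <- function(name, genes) {
    if (!length(genes)) {
      warning(sprintf("signature '%s': empty cross-cohort intersection", name))
      new("GeneSet", name = name, genes = character(0))
    } else GeneSet(name, genes)
  }
  genesA <- Reduce(intersect, topMarkers(+1))
  genesB <- Reduce(intersect, topMarkers(-1))
  new("SignatureSet", subtypeA = gsOrEmpty(nameA, genesA),
      subtypeB = gsOrEmpty(nameB, genesB), evidence = de)
}

#' Score samples against a signature with bin-matched control genes
#'
#' For each signature gene, control genes are drawn from the same
#' equal-frequency average-expression bin (of all genes in the matrix);
#' a sample's score is the mean over signature genes of
#' `value - mean(control values)`. Under exchangeability of a gene with its
#' bin the expected score is 0. When a gene's bin pool is not larger than
#' `nControlsPerGene` the whole pool is used deterministically, otherwise
#' `nControlsPerGene` controls are sampled without replacement.
#'
#' @param x [ExpressionMatrix-class] on a log scale (not centered).
#' @param geneSet [GeneSet-class] or character vector of signature genes;
#'   members absent from the matrix are dropped with a warning.
#' @param nBins expression bins (default 30).
#' @param nControlsPerGene controls per signature gene (default 100).
#' @param seed optional integer seed for the control draws.
#' @param geneMeans optional named per-gene average used for binning;
#'   defaults to the row means of `x`.
#' @param excludeSource drop the source gene from its own control pool
#'   (default TRUE).
#' @return Named numeric vector of per-sample scores.
#' @export
signatureScore <- function(x, geneSet, nBins = 30L, nControlsPerGene = 100L,
                           seed = NULL, geneMeans = NULL,
                           excludeSource = TRUE) {
  stopifnot(is(x, "ExpressionMatrix"))
  if (exprScale(x) == "counts")
    stop("signatureScore needs log-scale values")
  v <- exprValues(x)
  genes <- if (is(geneSet, "GeneSet")) setGenes(geneSet) else as.character(geneSet)
  absent <- setdiff(genes, rownames(v))
  if (length(absent) == length(genes))
    stop("no signature gene present in the matrix")
  if (length(absent)) {
    warning(sprintf("dropping %d signature gene(s) absent from the matrix",
                    length(absent)))
    genes <- setdiff(genes, absent)
  }
  if (is.null(geneMeans)) geneMeans <- rowMeans(v)
  if (!is.null(seed)) set.seed(as.integer(seed))
  bins <- expressionBins(geneMeans, nBins)
  ctrlMeans <- matrix(0, length(genes), ncol(v))
  for (i in seq_along(genes)) {
    g <- genes[i]
    pool <- names(bins)[bins == bins[g]]
    if (excludeSource) pool <- setdiff(pool, g)
    if (!length(pool))
      stop(sprintf("empty control pool for signature gene '%s'", g))
    ctrl <- if (length(pool) <= nControlsPerGene) pool
            else pool[sample.int(length(pool), nControlsPerGene)]
    ctrlMeans[i, ] <- colMeans(v[ctrl, , drop = FALSE])
  }
  score <- colMeans(v[genes, , drop = FALSE] - ctrlMeans)
  names(score) <- colnames(v)
  score
}

#' Classify samples by the sign of paired signature scores
#'
#' A sample scoring strictly above 0 for signature A and strictly below 0
#' for signature B is class `"A"`; the mirror image is `"B"`; every other
#' combination (both positive, both negative, or any exact zero) is
#' `"intermediate"`.
#'
#' @param scoreA,scoreB numeric score vectors (aligned, finite).
#' @return Character vector in `{"A", "B", "intermediate"}`, named like
#'   `scoreA`.
#' @export
classifyBySign <- function(scoreA, scoreB) {
  stopifnot(length(scoreA) == length(scoreB),
            all(is.finite(scoreA)), all(is.finite(scoreB)))
  out <- rep("intermediate", length(scoreA))
  out[scoreA > 0 & scoreB < 0] <- "A"
  out[scoreB > 0 & scoreA < 0] <- "B"
  names(out) <- names(scoreA)
  out
}

#' Select top marker genes of a cell type from labeled single-cell counts
#'
#' Counts are log-normalized per cell (`log1p(count / cell_total * 1e4)`).
#' Candidate markers must be detected in at least `minExprFrac` of the
#' target type's cells and show a fold-change (ratio of
#' `mean(expm1(log-normalized)) + 1` between target and all other cells) of
#' at least `minFC`; survivors are ranked by log2 fold-change and truncated
#' to `topN`.
#'
#' @param counts cells x genes count matrix with dimnames.
#' @param cellLabels named character vector of cell-type labels per cell.
#' @param targetType the cell type to characterize.
#' @param minExprFrac minimum detection fraction in the target (default 0.5).
#' @param minFC minimum fold-change over the complement (default 2).
#' @param topN marker list length (default 50).
#' @return A [GeneSet-class] named `<targetType>_markers`; empty (with a
#'   warning) if nothing passes.
#' @export
selectMarkers <- function(counts, cellLabels, targetType, minExprFrac = 0.5,
                          minFC = 2, topN = 50L) {
  stopifnot(is.matrix(counts), !is.null(colnames(counts)))
  if (!is.null(names(cellLabels)) && !is.null(rownames(counts)))
    cellLabels <- cellLabels[rownames(counts)]
  stopifnot(length(cellLabels) == nrow(counts))
  if (!targetType %in% cellLabels)
    stop(sprintf("cell type '%s' not present", targetType))
  if (length(unique(cellLabels)) < 2L) stop("need >= 2 cell types")
  norm <- log1p(counts / pmax(rowSums(counts), 1) * 1e4)
  inT <- cellLabels == targetType
  detection <- colMeans(counts[inT, , drop = FALSE] > 0)
  meanT <- colMeans(expm1(norm[inT, , drop = FALSE]))
  meanO <- colMeans(expm1(norm[!inT, , drop = FALSE]))
  fc <- (meanT + 1) / (meanO + 1)
  keep <- detection >= minExprFrac & fc >= minFC
  name <- paste0(targetType, "_markers")
  if (!any(keep)) {
    warning(sprintf("no marker passes the filters for '%s'", targetType))
    return(new("GeneSet", name = name, genes = character(0)))
  }
  ranked <- names(sort(log2(fc[keep]), decreasing = TRUE))
  GeneSet(name, head(ranked, topN))
}

#' Stratify samples by signature score
#'
#' Quartile mode labels scores strictly above the third quartile `"high"`,
#' strictly below the first quartile `"low"`, and the rest `"unassigned"`;
#' quartiles use the linear-interpolation (type 7) convention. Cutoff mode
#' labels scores strictly above `cutoff` `"high"` and the rest `"low"`.
#'
#' @param scores numeric vector (>= 4 values for quartile mode).
#' @param mode `"quartile"` or `"cutoff"`.
#' @param cutoff threshold for cutoff mode (default 1.0).
#' @return Character vector in `{"high", "low", "unassigned"}`, named like
#'   `scores`.
#' @export
stratifyScores <- function(scores, mode = c("quartile", "cutoff"),
                           cutoff = 1.0) {
  mode <- match.arg(mode)
  if (mode == "quartile") {
    if (length(scores) < 4L) stop("quartile mode needs >= 4 samples")
    q <- quantile(scores, c(0.25, 0.75), type = 7, names = FALSE)
    out <- rep("unassigned", length(scores))
    out[scores > q[2]] <- "high"
    out[scores < q[1]] <- "low"
  } else {
    out <- ifelse(scores > cutoff, "high", "low")
  }
  names(out) <- names(scores)
  out
}

#' Aggregate single-cell counts into pseudobulk sample profiles
#'
#' @param counts cells x genes count matrix with cell rownames.
#' @param cellToSample named character vector mapping every cell to a
#'   sample id.
#' @return [ExpressionMatrix-class] (genes x samples, scale `"counts"`);
#'   total counts are conserved.
#' @export
pseudobulk <- function(counts, cellToSample) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)))
  unmapped <- setdiff(rownames(counts), names(cellToSample))
  if (length(unmapped))
    stop(sprintf("unmapped cell(s): %s", paste(head(unmapped, 3), collapse = ", ")))
  grp <- as.character(cellToSample[rownames(counts)])
  agg <- rowsum(counts, group = grp)
  ExpressionMatrix(t(agg), batch = rep("pseudobulk", nrow(agg)),
                   scale = "counts")
}
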