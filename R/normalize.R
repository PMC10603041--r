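## Count normalization and batch handling: TMM scaling factors, logCPM
## transform, linear batch-effect removal, gene mean-centering. Scaling
## factors come from the trimmed-mean-of-M-values method (edgeR); batch
## removal is a per-gene least-squares location fit with sum-to-zero
## contrasts (limma::removeBatchEffect).

#' Compute TMM scaling factors
#'
#' Reference sample selection (75th-percentile count fraction closest to the
#' mean), 30%/5% M/A trimming and inverse-variance weighting follow the
#' trimmed-mean-of-M-values defaults; factors are rescaled to geometric
#' mean 1.
#'
#' @param counts an [ExpressionMatrix-class] with scale `"counts"`.
#' @return data.frame (class `NormalizationFactors`) with columns
#'   `sample_id`, `lib_size`, `tmm_factor`.
#' @export
tmmFactors <- function(counts) {
  stopifnot(is(counts, "ExpressionMatrix"))
  if (exprScale(counts) != "counts") stop("tmmFactors needs scale 'counts'")
  v <- exprValues(counts)
  if (ncol(v) < 2L) stop("TMM needs at least 2 samples")
  lib <- colSums(v)
  if (any(lib <= 0))
    stop(sprintf("sample '%s' has zero library size",
                 colnames(v)[which(lib <= 0)[1]]))
  f <- edgeR::calcNormFactors(v, method = "TMM")
  if (anyNA(f)) stop("TMM factor computation failed (NA factor)")
  # defensive: enforce the geometric-mean-1 invariant exactly
  f <- f / exp(mean(log(f)))
  structure(data.frame(sample_id = colnames(v), lib_size = unname(lib),
                       tmm_factor = unname(f), stringsAsFactors = FALSE),
            class = c("NormalizationFactors", "data.frame"))
}

#' Transform counts to log2 counts-per-million
#'
#' `log2((count + prior) / (lib_size * tmm_factor + 2 * prior) * 1e6)`, a
#' symmetric-prior closed form. With `prior = 0` every count must be
#' positive.
#'
#' @param counts [ExpressionMatrix-class] with scale `"counts"`.
#' @param factors a [tmmFactors()] table aligned to the samples; `NULL`
#'   uses library sizes only (all factors 1).
#' @param prior prior count, default 0.5.
#' @return [ExpressionMatrix-class] with scale `"logcpm"`.
#' @export
logCPM <- function(counts, factors = NULL, prior = 0.5) {
  stopifnot(is(counts, "ExpressionMatrix"))
  if (exprScale(counts) != "counts") stop("logCPM needs scale 'counts'")
  v <- exprValues(counts)
  if (is.null(factors)) {
    lib <- colSums(v)
    f <- rep(1, ncol(v))
  } else {
    idx <- match(colnames(v), factors$sample_id)
    if (anyNA(idx)) stop("factors table does not cover all samples")
    lib <- factors$lib_size[idx]
    f <- factors$tmm_factor[idx]
  }
  eff <- lib * f
  if (any(eff <= 0)) stop("non-positive effective library size")
  if (prior <= 0 && any(v == 0))
    stop("prior must be > 0 when zero counts are present")
  out <- log2(sweep(v + prior, 2, eff + 2 * prior, "/") * 1e6)
  ExpressionMatrix(out, batch = counts@batch, scale = "logcpm")
}

#' Remove additive batch effects from a logCPM matrix
#'
#' Per gene, fits a least-squares location model with sum-to-zero batch
#' contrasts and subtracts the fitted batch terms, so per-gene batch means
#' are equalized (at the unweighted mean of batch means). Idempotent.
#'
#' @param x [ExpressionMatrix-class] with scale `"logcpm"`.
#' @param batch batch labels; defaults to the object's own. A named vector
#'   is aligned by sample id (unknown ids are an error).
#' @return Batch-corrected [ExpressionMatrix-class] (scale `"logcpm"`),
#'   batch slot updated to the labels used.
#' @export
removeBatch <- function(x, batch = NULL) {
  stopifnot(is(x, "ExpressionMatrix"))
  if (exprScale(x) != "logcpm") stop("removeBatch needs scale 'logcpm'")
  if (is.null(batch)) batch <- x@batch
  if (!is.null(names(batch))) {
    unknown <- setdiff(names(batch), sampleIds(x))
    if (length(unknown))
      stop(sprintf("unknown sample in batch map: '%s'", unknown[1]))
    if (!all(sampleIds(x) %in% names(batch)))
      stop("batch map does not cover all samples")
    batch <- batch[sampleIds(x)]
  }
  batch <- as.character(batch)
  if (length(batch) != ncol(exprValues(x)))
    stop("batch length must equal the number of samples")
  tab <- table(batch)
  if (length(tab) < 2L) return(x)  # nothing to remove
  if (any(tab == 1L))
    warning(sprintf("batch(es) with a single sample: %s",
                    paste(names(tab)[tab == 1L], collapse = ", ")))
  out <- limma::removeBatchEffect(exprValues(x), batch = factor(batch))
  ExpressionMatrix(out, batch = batch, scale = "logcpm")
}

#' Mean-center every gene
#'
#' @param x [ExpressionMatrix-class] with scale `"logcpm"`.
#' @return [ExpressionMatrix-class] with scale `"centered_logcpm"`; every
#'   gene row has mean 0.
#' @export
centerGenes <- function(x) {
  stopifnot(is(x, "ExpressionMatrix"))
  if (!exprScale(x) %in% c("logcpm", "centered_logcpm"))
    stop("centerGenes needs scale 'logcpm'")
  v <- exprValues(x)
  out <- v - rowMeans(v)
  ExpressionMatrix(out, batch = x@batch, scale = "centered_logcpm")
}
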