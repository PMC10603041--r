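#' @import methods
#' @importFrom stats quantile rnorm runif rbinom rnbinom rexp rpois sd
#'   median cor cutree hclust as.dist cophenetic complete.cases wilcox.test
#'   p.adjust pchisq setNames aggregate
#' @importFrom utils read.delim write.table head
#' @useDynLib ecmstates, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

VALID_SCALES <- c("counts", "logcpm", "centered_logcpm")

#' ExpressionMatrix: a genes x samples expression container
#'
#' Holds a dense real matrix with gene identifiers as rownames, sample
#' identifiers as colnames, a per-sample batch (cohort) label, and a scale
#' flag declaring whether values are raw counts, log2 counts-per-million
#' (logCPM), or gene-mean-centered logCPM.
#'
#' @slot values numeric matrix, genes in rows, samples in columns, with
#'   unique dimnames.
#' @slot batch character vector of per-sample batch labels, parallel to
#'   columns.
#' @slot scale one of `"counts"`, `"logcpm"`, `"centered_logcpm"`.
#'
#' @examples
#' m <- matrix(1:6, nrow = 3, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' em <- ExpressionMatrix(m, batch = c("A", "A"), scale = "counts")
#' geneIds(em)
#' @export
setClass("ExpressionMatrix",
  representation(values = "matrix", batch = "character", scale = "character"),
  validity = function(object) {
    v <- object@values
    msg <- character(0)
    if (is.null(rownames(v)) || is.null(colnames(v)))
      msg <- c(msg, "values must have gene rownames and sample colnames")
    else {
      if (anyDuplicated(rownames(v)))
        msg <- c(msg, sprintf("duplicate gene id: '%s'",
                              rownames(v)[duplicated(rownames(v))][1]))
      if (anyDuplicated(colnames(v)))
        msg <- c(msg, sprintf("duplicate sample id: '%s'",
                              colnames(v)[duplicated(colnames(v))][1]))
    }
    if (!all(is.finite(v)))
      msg <- c(msg, "values must be finite (no NA/NaN/Inf)")
    if (length(object@scale) != 1L || !object@scale %in% VALID_SCALES)
      msg <- c(msg, sprintf("scale must be one of: %s",
                            paste(VALID_SCALES, collapse = ", ")))
    else if (object@scale == "counts" && any(v < 0))
      msg <- c(msg, "scale 'counts' requires all values >= 0")
    if (length(object@batch) != ncol(v))
      msg <- c(msg, "batch length must equal the number of samples")
    if (length(msg)) msg else TRUE
  }
)

#' Construct an ExpressionMatrix
#'
#' @param values numeric matrix (genes x samples) with dimnames.
#' @param batch per-sample batch/cohort labels; defaults to a single batch.
#' @param scale declared value scale (`"counts"`, `"logcpm"` or
#'   `"centered_logcpm"`).
#' @return An [ExpressionMatrix-class] object.
#' @export
ExpressionMatrix <- function(values, batch = rep("batch1", ncol(values)),
                             scale = "logcpm") {
  storage.mode(values) <- "double"
  new("ExpressionMatrix", values = values, batch = as.character(batch),
      scale = scale)
}

#' GeneSet: a named set of gene identifiers
#'
#' @slot name single string naming the set.
#' @slot genes character vector of unique, non-empty gene identifiers.
#' @export
setClass("GeneSet",
  representation(name = "character", genes = "character"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@name) != 1L || !nzchar(object@name))
      msg <- c(msg, "name must be a single non-empty string")
    if (anyDuplicated(object@genes))
      msg <- c(msg, "gene set members must be unique")
    if (length(msg)) msg else TRUE
  }
)

#' Construct a GeneSet
#'
#' @param name set name.
#' @param genes character vector of member gene ids; duplicates are removed
#'   with a warning.
#' @return A [GeneSet-class] object.
#' @export
GeneSet <- function(name, genes) {
  genes <- as.character(genes)
  if (!length(genes)) stop(sprintf("gene set '%s' must be non-empty", name))
  if (anyDuplicated(genes)) {
    warning(sprintf("gene set '%s': removing %d duplicate member(s)",
                    name, sum(duplicated(genes))))
    genes <- unique(genes)
  }
  new("GeneSet", name = name, genes = genes)
}

#' ConsensusResult: one rank of a consensus clustering
#'
#' @slot rank integer factorization/cut rank.
#' @slot consensus samples x samples co-clustering frequency matrix in
#'   \[0,1\], symmetric with unit diagonal.
#' @slot labels integer cluster labels in 1..rank, named by sample.
#' @slot cophenetic Pearson correlation between consensus dissimilarities
#'   and the cophenetic distances of the average-linkage tree cut to give
#'   the labels.
#' @slot silhouette per-sample silhouette width on distance 1 - consensus.
#' @slot coreMask logical, TRUE where silhouette > 0.
#' @slot nRuns number of restarts/resamples aggregated into the consensus.
#' @slot seed seed used.
#' @export
setClass("ConsensusResult",
  representation(rank = "integer", consensus = "matrix", labels = "integer",
                 cophenetic = "numeric", silhouette = "numeric",
                 coreMask = "logical", nRuns = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character(0)
    C <- object@consensus
    n <- ncol(C)
    if (nrow(C) != n) msg <- c(msg, "consensus must be square")
    if (any(C < -1e-12) || any(C > 1 + 1e-12))
      msg <- c(msg, "consensus entries must lie in [0,1]")
    if (max(abs(C - t(C))) > 1e-9) msg <- c(msg, "consensus must be symmetric")
    if (max(abs(diag(C) - 1)) > 1e-9)
      msg <- c(msg, "consensus diagonal must be 1")
    if (length(object@labels) != n || length(object@silhouette) != n ||
        length(object@coreMask) != n)
      msg <- c(msg, "labels, silhouette and coreMask must match sample count")
    if (any(object@labels < 1L | object@labels > object@rank))
      msg <- c(msg, "labels must lie in 1..rank")
    if (!identical(object@coreMask, object@silhouette > 0))
      msg <- c(msg, "coreMask must equal (silhouette > 0)")
    if (length(msg)) msg else TRUE
  }
)

#' StabilityReport: bootstrap vs bin-matched-null clustering stability
#'
#' @slot observedARI ARI of clusterings from bootstrap resamples of the
#'   gene set against the reference labels.
#' @slot nullARI ARI of clusterings from bin-matched control gene sets
#'   against the reference labels.
#' @slot nBins number of expression bins used for control matching.
#' @slot B resamples per arm.
#' @slot seed seed used.
#' @export
setClass("StabilityReport",
  representation(observedARI = "numeric", nullARI = "numeric",
                 nBins = "integer", B = "integer", seed = "integer"),
  validity = function(object) {
    msg <- character(0)
    if (length(object@observedARI) != object@B ||
        length(object@nullARI) != object@B)
      msg <- c(msg, "each arm must contain exactly B values")
    ari <- c(object@observedARI, object@nullARI)
    if (any(ari < -1 - 1e-9 | ari > 1 + 1e-9))
      msg <- c(msg, "ARI values must lie in [-1, 1]")
    if (length(msg)) msg else TRUE
  }
)

#' SignatureSet: paired subtype signatures with differential evidence
#'
#' @slot subtypeA [GeneSet-class] upregulated in subtype A in every cohort.
#' @slot subtypeB [GeneSet-class] upregulated in subtype B in every cohort.
#' @slot evidence data.frame of per-gene, per-cohort statistics
#'   (gene_id, cohort, log2fc, p, padj).
#' @export
setClass("SignatureSet",
  representation(subtypeA = "GeneSet", subtypeB = "GeneSet",
                 evidence = "data.frame"),
  validity = function(object) {
    if (length(intersect(object@subtypeA@genes, object@subtypeB@genes)))
      "subtype signatures must be disjoint" else TRUE
  }
)

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d samples [%s]\n",
              nrow(object@values), ncol(object@values), object@scale))
  cat(sprintf("  batches: %s\n",
              paste(sprintf("%s(%d)", names(table(object@batch)),
                            table(object@batch)), collapse = " ")))
})

setMethod("show", "GeneSet", function(object) {
  cat(sprintf("GeneSet '%s': %d genes\n", object@name, length(object@genes)))
})

setMethod("show", "ConsensusResult", function(object) {
  cat(sprintf(
    "ConsensusResult: rank %d, %d samples, cophenetic %.4f, %d core (%d runs)\n",
    object@rank, length(object@labels), object@cophenetic,
    sum(object@coreMask), object@nRuns))
})

setMethod("show", "StabilityReport", function(object) {
  cat(sprintf(
    "StabilityReport: B=%d, %d bins | median ARI observed %.3f, null %.3f\n",
    object@B, object@nBins, median(object@observedARI),
    median(object@nullARI)))
})

setMethod("show", "SignatureSet", function(object) {
  cat(sprintf("SignatureSet: A='%s' (%d genes), B='%s' (%d genes)\n",
              object@subtypeA@name, length(object@subtypeA@genes),
              object@subtypeB@name, length(object@subtypeB@genes)))
})
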