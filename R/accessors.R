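#' @rdname ExpressionMatrix-class
#' @param x an `ExpressionMatrix`.
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname ExpressionMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname ExpressionMatrix-class
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))
#' @rdname ExpressionMatrix-class
#' @export
setGeneric("batchLabels", function(x) standardGeneric("batchLabels"))
#' @rdname ExpressionMatrix-class
#' @export
setGeneric("exprScale", function(x) standardGeneric("exprScale"))

#' @rdname ExpressionMatrix-class
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x@values))
#' @rdname ExpressionMatrix-class
setMethod("sampleIds", "ExpressionMatrix", function(x) colnames(x@values))
#' @rdname ExpressionMatrix-class
setMethod("exprValues", "ExpressionMatrix", function(x) x@values)
#' @rdname ExpressionMatrix-class
setMethod("batchLabels", "ExpressionMatrix",
          function(x) setNames(x@batch, colnames(x@values)))
#' @rdname ExpressionMatrix-class
setMethod("exprScale", "ExpressionMatrix", function(x) x@scale)

#' @rdname GeneSet-class
#' @param x a `GeneSet`.
#' @export
setGeneric("setName", function(x) standardGeneric("setName"))
#' @rdname GeneSet-class
#' @export
setGeneric("setGenes", function(x) standardGeneric("setGenes"))
#' @rdname GeneSet-class
setMethod("setName", "GeneSet", function(x) x@name)
#' @rdname GeneSet-class
setMethod("setGenes", "GeneSet", function(x) x@genes)

#' Subset an ExpressionMatrix by gene and/or sample ids
#'
#' @param x an `ExpressionMatrix`.
#' @param genes,samples character ids to keep (default: all). Unknown ids
#'   are an error.
#' @return An `ExpressionMatrix` restricted to the requested rows/columns,
#'   in the requested order.
#' @export
subsetExpression <- function(x, genes = geneIds(x), samples = sampleIds(x)) {
  stopifnot(is(x, "ExpressionMatrix"))
  missG <- setdiff(genes, geneIds(x))
  if (length(missG))
    stop(sprintf("unknown gene id(s): %s%s", paste(head(missG, 3), collapse = ", "),
                 if (length(missG) > 3) ", ..." else ""))
  missS <- setdiff(samples, sampleIds(x))
  if (length(missS))
    stop(sprintf("unknown sample id(s): %s", paste(head(missS, 3), collapse = ", ")))
  keep <- match(samples, sampleIds(x))
  ExpressionMatrix(x@values[genes, samples, drop = FALSE],
                   batch = x@batch[keep], scale = x@scale)
}

#' Accessors for ConsensusResult
#'
#' @param x a `ConsensusResult`.
#' @name ConsensusResult-accessors
NULL

#' @rdname ConsensusResult-accessors
#' @export
setGeneric("consensusMatrix", function(x) standardGeneric("consensusMatrix"))
#' @rdname ConsensusResult-accessors
#' @export
setGeneric("clusterLabels", function(x) standardGeneric("clusterLabels"))
#' @rdname ConsensusResult-accessors
#' @export
setGeneric("copheneticCoef", function(x) standardGeneric("copheneticCoef"))
#' @rdname ConsensusResult-accessors
#' @export
setGeneric("silhouetteWidths", function(x) standardGeneric("silhouetteWidths"))
#' @rdname ConsensusResult-accessors
#' @export
setGeneric("coreSamples", function(x) standardGeneric("coreSamples"))

#' @rdname ConsensusResult-accessors
setMethod("consensusMatrix", "ConsensusResult", function(x) x@consensus)
#' @rdname ConsensusResult-accessors
setMethod("clusterLabels", "ConsensusResult",
          function(x) setNames(x@labels, colnames(x@consensus)))
#' @rdname ConsensusResult-accessors
setMethod("copheneticCoef", "ConsensusResult", function(x) x@cophenetic)
#' @rdname ConsensusResult-accessors
setMethod("silhouetteWidths", "ConsensusResult",
          function(x) setNames(x@silhouette, colnames(x@consensus)))
#' @rdname ConsensusResult-accessors
setMethod("coreSamples", "ConsensusResult",
          function(x) colnames(x@consensus)[x@coreMask])

#' Accessors for SignatureSet
#' @param x a `SignatureSet`.
#' @name SignatureSet-accessors
NULL

#' @rdname SignatureSet-accessors
#' @export
setGeneric("signatureA", function(x) standardGeneric("signatureA"))
#' @rdname SignatureSet-accessors
#' @export
setGeneric("signatureB", function(x) standardGeneric("signatureB"))
#' @rdname SignatureSet-accessors
#' @export
setGeneric("signatureEvidence", function(x) standardGeneric("signatureEvidence"))
#' @rdname SignatureSet-accessors
setMethod("signatureA", "SignatureSet", function(x) x@subtypeA)
#' @rdname SignatureSet-accessors
setMethod("signatureB", "SignatureSet", function(x) x@subtypeB)
#' @rdname SignatureSet-accessors
setMethod("signatureEvidence", "SignatureSet", function(x) x@evidence)
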