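#' Fold a real matrix into a non-negative one (positive/negative split)
#'
#' Each gene row `g` becomes two rows `max(g, 0)` and `max(-g, 0)`, so a
#' mean-centered matrix can be factorized by NMF without discarding the
#' sign information. Invertible: row `g` equals the first folded row minus
#' the second.
#'
#' @param v numeric matrix (any sign).
#' @return Non-negative matrix with `2 * nrow(v)` rows; folded rows carry
#'   `.pos` / `.neg` suffixes on the original rownames.
#' @export
posnegFold <- function(v) {
  stopifnot(is.matrix(v))
  out <- rbind(pmax(v, 0), pmax(-v, 0))
  if (!is.null(rownames(v)))
    rownames(out) <- c(paste0(rownames(v), ".pos"), paste0(rownames(v), ".neg"))
  out
}

## Non-negative folding dispatcher used by the consensus machinery.
foldNonNegative <- function(v, method = c("posneg", "shift-min")) {
  method <- match.arg(method)
  if (method == "posneg") posnegFold(v) else v - min(v)
}

#' Factorize a non-negative matrix by KL-divergence NMF
#'
#' Multiplicative updates minimizing the generalized Kullback-Leibler
#' divergence. `W` is initialized uniform at random on (0, 1) scaled to the
#' data magnitude; `H` is initialized at a constant, which makes the whole
#' iteration equivariant under column (sample) permutation — consensus
#' matrices are then exactly invariant to sample reordering.
#'
#' @param v non-negative numeric matrix.
#' @param rank factorization rank, `1 <= rank < min(dim(v))`.
#' @param seed optional integer; when given, `set.seed(seed)` is called
#'   before drawing the initialization (otherwise the current RNG stream is
#'   consumed).
#' @param maxIter maximum multiplicative updates (default 2000).
#' @param tol stop when the per-iteration relative divergence change drops
#'   below this.
#' @param W0,H0 optional explicit initializations (genes x rank,
#'   rank x samples).
#' @param checkEvery evaluate the divergence every this many updates
#'   (default 10; the log terms dominate the iteration cost). Set 1 to
#'   record the full per-iteration trace.
#' @return list with `W`, `H`, `divergence` (final), `trace` (divergence at
#'   each evaluation, non-increasing), `iterations`, `converged`, `status`.
#' @export
klNMF <- function(v, rank, seed = NULL, maxIter = 2000L, tol = 1e-6,
                  W0 = NULL, H0 = NULL, checkEvery = 10L) {
  stopifnot(is.matrix(v), rank >= 1)
  if (any(v < 0)) stop("klNMF needs a non-negative matrix")
  if (all(v == 0)) stop("klNMF: input matrix is all zero")
  if (rank >= min(dim(v))) stop("rank must be < min(dim(v))")
  if (!is.null(seed)) set.seed(seed)
  if (is.null(W0))
    W0 <- matrix(runif(nrow(v) * rank, min = .Machine$double.eps),
                 nrow(v), rank) * sqrt(mean(v) / rank)
  if (is.null(H0)) H0 <- matrix(1, rank, ncol(v))
  fit <- nmf_kl_cpp(v, W0, H0, as.integer(maxIter), tol,
                    as.integer(checkEvery))
  if (!fit$converged)
    fit$status <- "max_iter_reached" else fit$status <- "converged"
  dimnames(fit$W) <- list(rownames(v), NULL)
  dimnames(fit$H) <- list(NULL, colnames(v))
  fit
}

## Hard sample labels from an NMF fit: argmax over the rank components of
## H per sample; ties resolve to the lowest component index.
nmfLabels <- function(H) {
  apply(H, 2L, which.max)
}
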