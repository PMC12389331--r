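# Guilt-by-association propagation: each known interaction of drug i votes
# for candidate partners similar to the known partner, M3 = f(M1, M2).

#' Propagate known interactions through a similarity matrix
#'
#' With the similarity diagonal forced to zero (so a known interaction
#' cannot trivially score itself through self-similarity),
#' \code{sum} mode computes the matrix product
#' \eqn{raw_{ij} = \sum_k M1_{ik} M2'_{kj}} and \code{max} mode the
#' strongest single piece of evidence
#' \eqn{raw_{ij} = \max_k M1_{ik} M2'_{kj}}. The result is symmetrized by
#' the elementwise maximum with its transpose (evidence from either side of
#' an unordered pair counts) and the diagonal forced to zero.
#'
#' @param m1 known-interaction matrix.
#' @param m2 similarity matrix on the same index.
#' @param aggregation \code{"sum"} (default) or \code{"max"}.
#' @return Raw non-negative score matrix (not yet normalized).
#' @export
propagate <- function(m1, m2, aggregation = c("sum", "max")) {
  aggregation <- match.arg(aggregation)
  if (!all(dim(m1) == dim(m2))) {
    stop("dimension mismatch between M1 and M2", call. = FALSE)
  }
  assert_interaction_matrix(m1)
  m2p <- m2
  diag(m2p) <- 0
  if (aggregation == "sum") {
    raw <- m1 %*% m2p
  } else {
    n <- nrow(m1)
    raw <- matrix(0, n, n)
    for (i in seq_len(n)) {
      k <- which(m1[i, ] == 1)
      if (length(k) == 1) {
        raw[i, ] <- m2p[k, ]
      } else if (length(k) > 1) {
        raw[i, ] <- apply(m2p[k, , drop = FALSE], 2, max)
      }
    }
  }
  raw <- pmax(raw, t(raw))
  diag(raw) <- 0
  dimnames(raw) <- dimnames(m1)
  raw
}

#' Normalize a raw score matrix to [0, 1]
#'
#' Divides all entries by the global maximum so relative evidence across
#' drugs with very different interaction degrees is preserved. An all-zero
#' matrix is returned unchanged.
#'
#' @param raw non-negative raw score matrix from \code{\link{propagate}}.
#' @return Score matrix (M3) with entries in \code{[0, 1]}.
#' @export
normalize_scores <- function(raw) {
  if (any(raw < 0)) stop("raw scores must be non-negative", call. = FALSE)
  mx <- max(raw)
  if (mx > 0) raw <- raw / mx
  raw
}

#' Compute all six propagated score matrices (M3)
#'
#' @param m1 known-interaction matrix (possibly fold-masked).
#' @param static_m2 list of CHEM/TECT/ADE/PATHWAY/INTERACTOME similarity
#'   matrices from \code{\link{build_static_m2}}.
#' @param catalog the \code{drug_catalog}.
#' @param aggregation passed to \code{\link{propagate}}.
#' @return Named list of six normalized score matrices (adds IPF, built
#'   from \code{m1} itself).
#' @export
propagate_all <- function(m1, static_m2, catalog,
                          aggregation = c("sum", "max")) {
  aggregation <- match.arg(aggregation)
  m2 <- static_m2
  m2$IPF <- build_m2(ipf_profiles(m1, catalog), catalog, "IPF")
  lapply(m2[SCORE_KINDS], function(s) {
    normalize_scores(propagate(m1, s, aggregation))
  })
}
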