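# PCA integration of the six per-feature score matrices into one unified
# score per unordered drug pair.

#' Enumerate all unordered catalog pairs
#'
#' Pairs are listed in canonical order: \code{i < j} over the
#' lexicographically sorted catalog, \code{drug_a < drug_b} in every row.
#'
#' @param catalog the \code{drug_catalog}.
#' @return Data frame with columns \code{drug_a}, \code{drug_b}, \code{i},
#'   \code{j} (row/column indices into catalog-aligned matrices); one row
#'   per pair, \code{n(n-1)/2} rows total.
#' @export
pair_index <- function(catalog) {
  n <- nrow(catalog)
  idx <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  idx <- idx[order(idx[, "row"], idx[, "col"]), , drop = FALSE]
  data.frame(drug_a = catalog$drug_id[idx[, "row"]],
             drug_b = catalog$drug_id[idx[, "col"]],
             i = idx[, "row"], j = idx[, "col"],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Stack score matrices into a pair-by-feature design table
#'
#' @param score_matrices named list of score matrices sharing the catalog
#'   index.
#' @param pairs a \code{\link{pair_index}} data frame.
#' @return Numeric matrix: one row per pair, one column per feature kind.
#' @export
stack_scores <- function(score_matrices, pairs) {
  dims <- vapply(score_matrices, function(m) dim(m), integer(2))
  if (length(unique(dims[1, ])) != 1 || length(unique(dims[2, ])) != 1) {
    stop("score matrices have inconsistent dimensions", call. = FALSE)
  }
  sel <- cbind(pairs$i, pairs$j)
  out <- vapply(score_matrices, function(m) m[sel],
                numeric(nrow(pairs)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL,
                                                       names(score_matrices)))
  out
}

#' Integrate per-feature scores into one unified score by PCA
#'
#' Columns are standardized to mean 0 / variance 1 (zero-variance columns
#' are dropped with a warning), the first principal component of the
#' standardized table is extracted, its sign is oriented so that it
#' correlates non-negatively with the row mean of the standardized columns
#' (higher = more evidence for interaction), and the projection is min-max
#' rescaled to \code{[0, 1]}.
#'
#' @param design pair-by-feature numeric matrix from
#'   \code{\link{stack_scores}}.
#' @return List with \code{scores} (unified per-pair vector in
#'   \code{[0, 1]}), \code{loadings} (PC1 loadings on retained columns),
#'   \code{dropped} (names of zero-variance columns),
#'   \code{explained_variance} (PC1 share).
#' @export
integrate_pca <- function(design) {
  design <- as.matrix(design)
  if (nrow(design) < 2) stop("need at least 2 pairs for PCA", call. = FALSE)
  sds <- apply(design, 2, stats::sd)
  keep <- sds > 1e-12
  if (!any(keep)) {
    stop("no informative feature scores (all columns constant)",
         call. = FALSE)
  }
  if (any(!keep)) {
    warning("dropping zero-variance feature column(s): ",
            paste(colnames(design)[!keep], collapse = ", "), call. = FALSE)
  }
  z <- scale(design[, keep, drop = FALSE])
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  proj <- as.numeric(z %*% pc$rotation[, 1])
  ref <- rowMeans(z)
  orient <- if (stats::sd(ref) > 0) stats::cor(proj, ref) else NA_real_
  if (is.na(orient) || orient == 0) orient <- stats::cor(proj, z[, 1])
  if (!is.na(orient) && orient < 0) proj <- -proj
  rng <- range(proj)
  scores <- if (rng[2] > rng[1]) (proj - rng[1]) / (rng[2] - rng[1]) else {
    rep(0, length(proj))
  }
  loadings <- pc$rotation[, 1] * sign(if (!is.na(orient) && orient < 0) -1
                                      else 1)
  list(scores = scores, loadings = loadings,
       dropped = colnames(design)[!keep],
       explained_variance = pc$sdev[1]^2 / sum(pc$sdev^2))
}

#' Unified scores as a symmetric matrix
#'
#' @param scores unified per-pair score vector.
#' @param pairs the \code{\link{pair_index}} used to compute them.
#' @param n catalog size.
#' @return Symmetric n-by-n matrix with zero diagonal.
#' @export
unified_matrix <- function(scores, pairs, n) {
  m <- matrix(0, n, n)
  m[cbind(pairs$i, pairs$j)] <- scores
  m[cbind(pairs$j, pairs$i)] <- scores
  m
}
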