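# Masked k-fold cross-validation over known interactions. Each fold's
# positive pairs are zeroed out of the reference matrix before the
# IPF profiles, all six propagated score matrices and the PCA integration
# are recomputed, so the score a held-out pair receives never sees that
# pair's own entry (leakage guard asserted on every fold).

#' Build a cross-validation fold plan
#'
#' Known pairs are shuffled with the seed and split into \code{k}
#' near-equal folds; for each fold, \code{negative_ratio} times as many
#' non-interacting pairs are sampled uniformly without replacement (across
#' all folds, so negatives are never reused).
#'
#' @param m1 known-interaction matrix.
#' @param catalog the \code{drug_catalog}.
#' @param k fold count (>= 2; default 10).
#' @param seed integer RNG seed.
#' @param negative_ratio negatives per positive (default 1).
#' @return A \code{fold_plan}: list of \code{k} folds, each with
#'   \code{positives} and \code{negatives} data frames (\code{i}, \code{j}
#'   index columns), plus the plan parameters.
#' @export
make_folds <- function(m1, catalog, k = 10, seed = 1, negative_ratio = 1) {
  if (k < 2) stop("k must be >= 2", call. = FALSE)
  assert_interaction_matrix(m1)
  pairs <- pair_index(catalog)
  flat <- m1[cbind(pairs$i, pairs$j)]
  pos <- which(flat == 1)
  neg_pool <- which(flat == 0)
  if (length(pos) < k) {
    stop("fewer known pairs (", length(pos), ") than folds (", k, ")",
         call. = FALSE)
  }
  n_neg <- ceiling(length(pos) * negative_ratio)
  if (length(neg_pool) < n_neg) {
    stop("negative pool exhausted: need ", n_neg, ", have ",
         length(neg_pool), call. = FALSE)
  }
  with_seed(seed, {
    pos_shuffled <- sample(pos)
    negs <- sample(neg_pool, n_neg)
  })
  fold_of_pos <- rep(seq_len(k), length.out = length(pos_shuffled))
  fold_of_neg <- rep(seq_len(k), length.out = length(negs))
  folds <- lapply(seq_len(k), function(f) {
    list(positives = pairs[pos_shuffled[fold_of_pos == f], , drop = FALSE],
         negatives = pairs[negs[fold_of_neg == f], , drop = FALSE])
  })
  structure(list(folds = folds, k = k, seed = seed,
                 negative_ratio = negative_ratio),
            class = "fold_plan")
}

#' Score one fold with its positives masked out of the reference matrix
#'
#' Zeroes the fold's positive pairs in M1, rebuilds the IPF similarity and
#' all six propagated score matrices from the masked M1, reruns the PCA
#' integration, and returns the unified scores of the fold's positive and
#' negative pairs. Asserts that no test positive survives in the masked M1.
#'
#' @param fold one element of a \code{fold_plan}'s \code{folds} list.
#' @param m1 full known-interaction matrix.
#' @param static_m2 static similarity matrices from
#'   \code{\link{build_static_m2}}.
#' @param catalog the \code{drug_catalog}.
#' @param aggregation propagation mode.
#' @return Data frame with \code{drug_a}, \code{drug_b}, \code{score},
#'   \code{label} (1 = held-out known pair, 0 = sampled negative).
#' @export
masked_scores <- function(fold, m1, static_m2, catalog,
                          aggregation = "sum") {
  m1_masked <- m1
  sel <- cbind(fold$positives$i, fold$positives$j)
  m1_masked[sel] <- 0
  m1_masked[sel[, c(2, 1), drop = FALSE]] <- 0
  # leakage guard: the pairs being scored must be invisible to the model
  stopifnot(all(m1_masked[sel] == 0),
            all(m1_masked[sel[, c(2, 1), drop = FALSE]] == 0))
  assert_interaction_matrix(m1_masked)
  m3 <- propagate_all(m1_masked, static_m2, catalog, aggregation)
  pairs <- pair_index(catalog)
  design <- stack_scores(m3, pairs)
  unified <- suppressWarnings(integrate_pca(design))$scores
  um <- unified_matrix(unified, pairs, nrow(catalog))
  take <- function(p, label) {
    data.frame(drug_a = p$drug_a, drug_b = p$drug_b,
               score = um[cbind(p$i, p$j)], label = label,
               stringsAsFactors = FALSE)
  }
  rbind(take(fold$positives, 1L), take(fold$negatives, 0L))
}

#' Area under the ROC curve (Mann-Whitney formulation)
#'
#' The probability that a uniformly chosen positive outscores a uniformly
#' chosen negative, with ties counted one half.
#'
#' @param scores numeric score vector.
#' @param labels binary labels (1 positive, 0 negative); both classes must
#'   be present.
#' @return AUROC in \code{[0, 1]}.
#' @export
auroc <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present to compute AUROC", call. = FALSE)
  }
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Operating point maximizing the Youden index
#'
#' Scans cutoffs at the midpoints of adjacent distinct scores (plus one
#' below the minimum and one above the maximum); a pair is called positive
#' when its score is strictly greater than the cutoff. Ties in
#' \eqn{J = sensitivity + specificity - 1} are broken toward the larger
#' cutoff.
#'
#' @inheritParams auroc
#' @return List with \code{sensitivity}, \code{specificity}, \code{cutoff},
#'   \code{youden}.
#' @export
youden_operating_point <- function(scores, labels) {
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) {
    stop("both classes must be present", call. = FALSE)
  }
  s <- sort(unique(scores))
  cutoffs <- c(s[1] - 1,
               if (length(s) > 1) (s[-length(s)] + s[-1]) / 2,
               s[length(s)] + 1)
  best <- NULL
  for (cut in cutoffs) {
    sens <- sum(scores > cut & labels == 1) / n1
    spec <- sum(scores <= cut & labels == 0) / n0
    j <- sens + spec - 1
    if (is.null(best) || j >= best$youden) {
      best <- list(sensitivity = sens, specificity = spec, cutoff = cut,
                   youden = j)
    }
  }
  best
}

#' Third-quartile novelty threshold
#'
#' The 75th percentile of the unified scores of known interacting pairs,
#' with linear interpolation between order statistics
#' (\eqn{h = (n-1) \cdot 0.75}; quantile type 7). Candidate pairs scoring
#' strictly above this value are called novel.
#'
#' @param known_scores unified scores of known pairs (non-empty).
#' @param level quantile level (default 0.75).
#' @return The threshold.
#' @export
q3_threshold <- function(known_scores, level = 0.75) {
  if (length(known_scores) == 0) {
    stop("no known-pair scores to take a quantile of", call. = FALSE)
  }
  unname(stats::quantile(known_scores, probs = level, type = 7,
                         names = FALSE))
}

#' Run masked k-fold cross-validation
#'
#' @param m1 known-interaction matrix.
#' @param static_m2 static similarity matrices.
#' @param catalog the \code{drug_catalog}.
#' @param k folds (default 10).
#' @param seed RNG seed for the fold plan.
#' @param negative_ratio negatives per positive.
#' @param aggregation propagation mode.
#' @return A \code{validation_report}: list with \code{auroc_mean},
#'   \code{auroc_sd}, per-fold AUROCs, pooled \code{sensitivity} /
#'   \code{specificity} at the Youden cutoff, and the pooled fold scores.
#' @export
cross_validate <- function(m1, static_m2, catalog, k = 10, seed = 1,
                           negative_ratio = 1, aggregation = "sum") {
  plan <- make_folds(m1, catalog, k = k, seed = seed,
                     negative_ratio = negative_ratio)
  fold_scores <- lapply(plan$folds, masked_scores, m1 = m1,
                        static_m2 = static_m2, catalog = catalog,
                        aggregation = aggregation)
  aucs <- vapply(fold_scores, function(fs) auroc(fs$score, fs$label),
                 numeric(1))
  pooled <- do.call(rbind, fold_scores)
  op <- youden_operating_point(pooled$score, pooled$label)
  structure(list(auroc_mean = mean(aucs), auroc_sd = stats::sd(aucs),
                 fold_auroc = aucs, sensitivity = op$sensitivity,
                 specificity = op$specificity, cutoff = op$cutoff,
                 k = k, seed = seed, scores = pooled),
            class = "validation_report")
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf("Masked %d-fold cross-validation (seed %d)\n", x$k, x$seed))
  cat(sprintf("  AUROC: %.4f +/- %.4f\n", x$auroc_mean, x$auroc_sd))
  cat(sprintf("  Youden operating point: sensitivity %.3f, specificity %.3f (cutoff %.4f)\n",
              x$sensitivity, x$specificity, x$cutoff))
  invisible(x)
}
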