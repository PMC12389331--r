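# End-to-end pipeline: configuration record, full-data prediction run and
# cross-validation-only run. These are the programmatic equivalents of the
# command-line subcommands in inst/scripts/ddipredict.

#' Pipeline configuration
#'
#' @param aggregation propagation mode, \code{"sum"} or \code{"max"}.
#' @param radius interactome neighbourhood radius (>= 0).
#' @param n_bits chemical fingerprint width.
#' @param max_path_length chemical fingerprint maximum path length.
#' @param k cross-validation folds (>= 2).
#' @param seed RNG seed for fold construction and negative sampling.
#' @param negative_ratio sampled negatives per positive.
#' @param quantile_level novelty-threshold quantile over known-pair scores
#'   (default 0.75, the third quartile).
#' @param effect_keywords ordered keyword lists for
#'   \code{\link{classify_effect}}.
#' @return A validated \code{ddi_config} list.
#' @export
ddi_config <- function(aggregation = "sum", radius = 1, n_bits = 1024,
                       max_path_length = 7, k = 10, seed = 1,
                       negative_ratio = 1, quantile_level = 0.75,
                       effect_keywords = EFFECT_KEYWORDS) {
  aggregation <- match.arg(aggregation, c("sum", "max"))
  stopifnot(radius >= 0, k >= 2, quantile_level > 0, quantile_level < 1,
            negative_ratio > 0, n_bits >= 64, max_path_length >= 1)
  structure(list(aggregation = aggregation, radius = radius,
                 n_bits = n_bits, max_path_length = max_path_length,
                 k = as.integer(k), seed = as.integer(seed),
                 negative_ratio = negative_ratio,
                 quantile_level = quantile_level,
                 effect_keywords = effect_keywords),
            class = "ddi_config")
}

#' @keywords internal
#' @noRd
stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop("[", name, "] ", conditionMessage(e), call. = FALSE)
  })
}

#' Run the full prediction pipeline
#'
#' Builds the five static similarity matrices and the IPF matrix, propagates
#' the known-interaction matrix through each, integrates the six score
#' matrices by PCA, fixes the novelty threshold at the configured quantile
#' of known-pair unified scores, runs masked cross-validation, and calls,
#' classifies and summarises novel interactions.
#'
#' @param universe a universe list as produced by
#'   \code{\link{generate_universe}} or \code{\link{read_universe}}.
#' @param config a \code{\link{ddi_config}}.
#' @param out_dir optional directory; when given, writes
#'   \code{predictions.tsv}, \code{validation.tsv},
#'   \code{discovery_rates.tsv}, \code{group_summary.tsv} and
#'   \code{config.yaml}.
#' @return List with \code{predictions}, \code{validation},
#'   \code{threshold}, \code{unified}, \code{pairs}, \code{design},
#'   \code{discovery}, \code{groups}.
#' @export
run_predict <- function(universe, config = ddi_config(), out_dir = NULL) {
  catalog <- universe$catalog
  m1 <- universe$m1
  static_m2 <- stage("similarity", build_static_m2(universe$features,
                                                   catalog, universe$ppi,
                                                   radius = config$radius))
  m3 <- stage("propagation", propagate_all(m1, static_m2, catalog,
                                           config$aggregation))
  pairs <- pair_index(catalog)
  design <- stage("integration", stack_scores(m3, pairs))
  unified <- stage("integration",
                   suppressWarnings(integrate_pca(design))$scores)
  known_scores <- unified[m1[cbind(pairs$i, pairs$j)] == 1]
  threshold <- stage("validation",
                     q3_threshold(known_scores, config$quantile_level))
  validation <- stage("validation",
                      cross_validate(m1, static_m2, catalog, k = config$k,
                                     seed = config$seed,
                                     negative_ratio = config$negative_ratio,
                                     aggregation = config$aggregation))
  validation$q3_threshold <- threshold
  predictions <- stage("reporting",
                       call_novel(unified, pairs, m1, threshold,
                                  design = design,
                                  interactions = universe$interactions))
  discovery <- stage("reporting", discovery_table(predictions, m1, catalog))
  groups <- stage("reporting", group_summary(predictions, catalog))
  result <- list(predictions = predictions, validation = validation,
                 threshold = threshold, unified = unified, pairs = pairs,
                 design = design, discovery = discovery, groups = groups)
  if (!is.null(out_dir)) write_run_outputs(result, config, out_dir)
  result
}

#' Run masked cross-validation only
#'
#' @inheritParams run_predict
#' @return A \code{validation_report} with the \code{q3_threshold} of the
#'   full-data fit attached.
#' @export
run_validate <- function(universe, config = ddi_config(), out_dir = NULL) {
  catalog <- universe$catalog
  static_m2 <- stage("similarity", build_static_m2(universe$features,
                                                   catalog, universe$ppi,
                                                   radius = config$radius))
  validation <- stage("validation",
                      cross_validate(universe$m1, static_m2, catalog,
                                     k = config$k, seed = config$seed,
                                     negative_ratio = config$negative_ratio,
                                     aggregation = config$aggregation))
  m3 <- stage("propagation", propagate_all(universe$m1, static_m2, catalog,
                                           config$aggregation))
  pairs <- pair_index(catalog)
  unified <- stage("integration",
                   suppressWarnings(
                     integrate_pca(stack_scores(m3, pairs)))$scores)
  known_scores <- unified[universe$m1[cbind(pairs$i, pairs$j)] == 1]
  validation$q3_threshold <- q3_threshold(known_scores,
                                          config$quantile_level)
  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_validation_report(validation, file.path(out_dir,
                                                  "validation.tsv"))
  }
  validation
}

#' @keywords internal
#' @noRd
write_validation_report <- function(validation, path) {
  df <- data.frame(
    key = c("auroc_mean", "auroc_sd", "sensitivity", "specificity",
            "youden_cutoff", "q3_threshold", "k", "seed"),
    value = c(format_score(c(validation$auroc_mean, validation$auroc_sd,
                             validation$sensitivity,
                             validation$specificity, validation$cutoff,
                             validation$q3_threshold %||% NA_real_)),
              as.character(c(validation$k, validation$seed))),
    stringsAsFactors = FALSE)
  write_tsv_strict(df, path)
}

#' @keywords internal
#' @noRd
write_run_outputs <- function(result, config, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  write_predictions(result$predictions, file.path(out_dir,
                                                  "predictions.tsv"))
  write_validation_report(result$validation,
                          file.path(out_dir, "validation.tsv"))
  disc <- result$discovery
  disc$rate <- sprintf("%.2f", disc$rate)
  write_tsv_strict(disc, file.path(out_dir, "discovery_rates.tsv"))
  grp <- result$groups
  grp$rate_per_drug <- sprintf("%.1f", grp$rate_per_drug)
  write_tsv_strict(grp, file.path(out_dir, "group_summary.tsv"))
  cfg <- unclass(config)
  yaml::write_yaml(cfg, file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Rank held-out truth pairs against random non-pairs
#'
#' Convenience evaluation of synthetic-signal recovery: scores the
#' universe's held-out true pairs and an equal number of seeded random
#' non-interacting, non-held-out pairs with the full-data unified score and
#' returns the AUROC.
#'
#' @param universe a \code{synthetic_universe} with a \code{truth} table.
#' @param result a \code{\link{run_predict}} result for that universe.
#' @param seed seed for negative sampling.
#' @return AUROC of truth pairs versus sampled non-pairs.
#' @export
holdout_auroc <- function(universe, result, seed = 1) {
  stopifnot(!is.null(universe$truth), nrow(universe$truth) > 0)
  pairs <- result$pairs
  um <- unified_matrix(result$unified, pairs, nrow(universe$catalog))
  key <- paste(pairs$drug_a, pairs$drug_b, sep = "\t")
  truth_key <- paste(universe$truth$drug_a, universe$truth$drug_b,
                     sep = "\t")
  truth_idx <- match(truth_key, key)
  stopifnot(!anyNA(truth_idx))
  flat_known <- universe$m1[cbind(pairs$i, pairs$j)]
  neg_pool <- setdiff(which(flat_known == 0), truth_idx)
  neg_idx <- with_seed(seed, sample(neg_pool, length(truth_idx)))
  scores <- c(result$unified[truth_idx], result$unified[neg_idx])
  labels <- rep(c(1L, 0L), c(length(truth_idx), length(neg_idx)))
  auroc(scores, labels)
}
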