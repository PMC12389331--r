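# Cluster-structured synthetic drug universe. Drugs in the same cluster
# share noisy copies of a prototype token set for every feature kind and
# interact densely, so the pipeline's central premise -- feature-similar
# drugs interact with similar partners -- is planted explicitly and its
# recovery can be measured against a held-out truth list.

#' Parameters of the synthetic drug universe
#'
#' @param n_drugs number of drugs (default 120).
#' @param n_clusters number of planted clusters; drugs are assigned
#'   round-robin (default 8).
#' @param tokens_per_kind size of the token universe per feature kind
#'   (default 200).
#' @param prototype_set_size tokens drawn for each cluster prototype
#'   (default 12).
#' @param token_flip_rate per-token mutation probability when a drug copies
#'   its cluster prototype: a flipped token is dropped or replaced by a
#'   random token with equal chance (default 0.05).
#' @param within_cluster_ddi_prob Bernoulli probability of an interaction
#'   between two same-cluster drugs (default 0.6).
#' @param cross_cluster_ddi_prob probability between different clusters
#'   (default 0.02).
#' @param holdout_fraction fraction of sampled positives moved to the
#'   held-out truth list (default 0.2).
#' @param wrhd_fraction fraction of drugs flagged as women's reproductive
#'   health drugs and given reproductive group labels (default 0.25).
#' @param ppi_within_prob edge probability between same-cluster protein
#'   tokens in the synthetic interactome (default 0.3).
#' @param ppi_cross_prob edge probability across clusters (default 0.01).
#' @param seed master RNG seed; all component sub-streams are derived from
#'   it by fixed offsets.
#' @return A validated \code{universe_params} list.
#' @export
universe_params <- function(n_drugs = 120, n_clusters = 8,
                            tokens_per_kind = 200, prototype_set_size = 12,
                            token_flip_rate = 0.05,
                            within_cluster_ddi_prob = 0.6,
                            cross_cluster_ddi_prob = 0.02,
                            holdout_fraction = 0.2, wrhd_fraction = 0.25,
                            ppi_within_prob = 0.3, ppi_cross_prob = 0.01,
                            seed = 1) {
  p <- list(n_drugs = n_drugs, n_clusters = n_clusters,
            tokens_per_kind = tokens_per_kind,
            prototype_set_size = prototype_set_size,
            token_flip_rate = token_flip_rate,
            within_cluster_ddi_prob = within_cluster_ddi_prob,
            cross_cluster_ddi_prob = cross_cluster_ddi_prob,
            holdout_fraction = holdout_fraction,
            wrhd_fraction = wrhd_fraction,
            ppi_within_prob = ppi_within_prob,
            ppi_cross_prob = ppi_cross_prob, seed = as.integer(seed))
  probs <- c(p$token_flip_rate, p$within_cluster_ddi_prob,
             p$cross_cluster_ddi_prob, p$wrhd_fraction, p$ppi_within_prob,
             p$ppi_cross_prob)
  stopifnot(all(probs >= 0 & probs <= 1),
            p$holdout_fraction > 0, p$holdout_fraction < 1,
            p$n_clusters >= 1, p$n_clusters <= p$n_drugs,
            p$tokens_per_kind >= p$prototype_set_size,
            p$prototype_set_size >= 1, p$n_drugs >= 2)
  class(p) <- "universe_params"
  p
}

# Sub-stream seed offsets; adding a component never perturbs earlier draws.
#' @keywords internal
#' @noRd
SEED_OFFSETS <- c(catalog = 1L, CHEM = 11L, TECT = 12L, ADE = 13L,
                  PATHWAY = 14L, TARGET = 15L, ppi = 51L,
                  interactions = 61L, holdout = 71L, descriptions = 81L)

#' @keywords internal
#' @noRd
substream_seed <- function(seed, component) {
  (as.integer(seed) * 1009L + SEED_OFFSETS[[component]]) %% 2147483647L
}

# DrugBank-style description templates, one pool per effect class. Each
# template is class-tagged; classify_effect() must recover the tag.
#' @keywords internal
#' @noRd
DESCRIPTION_TEMPLATES <- list(
  ADE = c("Augmented risk or severity of %s when %s is combined with %s.",
          "%s may increase the risk or severity of %s caused by %s."),
  PK = c("%s can slow the metabolism of %s, raising exposure to %s.",
         "The serum concentration of %s can be increased when combined with %s (%s)."),
  PD = c("The therapeutic efficacy of %s can be increased when combined with %s (%s).",
         "The therapeutic efficacy of %s can be decreased when combined with %s (%s).")
)

#' @keywords internal
#' @noRd
ADVERSE_EVENTS <- c("cardiac arrhythmia", "liver damage", "hypertension",
                    "QTc prolongation", "bleeding", "nephrotoxicity")

#' Generate a synthetic drug universe
#'
#' Drugs are assigned to clusters round-robin; each cluster draws a random
#' prototype token set per feature kind and each drug copies its cluster's
#' prototypes with per-token mutations at \code{token_flip_rate}. The PPI
#' network is built as cluster-wise random graphs over the TARGET token
#' universe plus sparse cross edges. Interactions are sampled pairwise
#' Bernoulli with within/cross cluster probabilities;
#' \code{round(holdout_fraction * n_positives)} of them are moved (uniform,
#' seeded) to a held-out truth list. Description strings are sampled from
#' class-tagged DrugBank-style templates. The whole universe is a
#' deterministic function of the parameter record.
#'
#' @param params a \code{\link{universe_params}} record.
#' @return A \code{synthetic_universe}: list with \code{catalog},
#'   \code{features} (named \code{feature_table}s), \code{ppi},
#'   \code{interactions} (visible canonical table), \code{m1},
#'   \code{truth} (held-out pair table), \code{params}, and
#'   \code{intended_effects} (the class tag each description was generated
#'   from, for benchmarking the classifier).
#' @export
generate_universe <- function(params = universe_params()) {
  stopifnot(inherits(params, "universe_params"))
  n <- params$n_drugs
  ids <- sprintf("D%04d", seq_len(n))
  cluster <- rep(seq_len(params$n_clusters), length.out = n)

  # catalog: WRHD flags and group labels
  repro_groups <- setdiff(DRUG_GROUPS, "non_gynecological")
  cat_parts <- with_seed(substream_seed(params$seed, "catalog"), {
    n_wrhd <- round(params$wrhd_fraction * n)
    wrhd_ids <- sort(sample(ids, n_wrhd))
    groups <- lapply(ids, function(d) {
      if (d %in% wrhd_ids) {
        sample(repro_groups, sample(1:2, 1))
      } else "non_gynecological"
    })
    list(wrhd = ids %in% wrhd_ids, groups = groups)
  })
  catalog <- drug_catalog(ids, paste0("drug_", sub("^D", "", ids)),
                          cat_parts$groups, cat_parts$wrhd)

  # per-kind cluster prototypes and mutated per-drug copies
  features <- list()
  for (kind in FEATURE_KINDS) {
    features[[kind]] <- with_seed(substream_seed(params$seed, kind), {
      token_ids <- sprintf("%s_%04d", kind, seq_len(params$tokens_per_kind))
      protos <- lapply(seq_len(params$n_clusters), function(cl) {
        sample(token_ids, params$prototype_set_size)
      })
      assignments <- lapply(seq_len(n), function(d) {
        tok <- protos[[cluster[d]]]
        flip <- which(stats::runif(length(tok)) < params$token_flip_rate)
        if (length(flip) > 0) {
          dropped <- flip[stats::runif(length(flip)) < 0.5]
          replaced <- setdiff(flip, dropped)
          tok[replaced] <- sample(token_ids, length(replaced),
                                  replace = TRUE)
          if (length(dropped) > 0) tok <- tok[-dropped]
        }
        sort(unique(tok))
      })
      names(assignments) <- ids
      structure(list(feature_kind = kind,
                     assignments = assignments[catalog$drug_id]),
                class = "feature_table")
    })
  }

  # PPI over the TARGET token universe: tokens partitioned round-robin into
  # clusters, dense within, sparse across
  ppi <- with_seed(substream_seed(params$seed, "ppi"), {
    token_ids <- sprintf("TARGET_%04d", seq_len(params$tokens_per_kind))
    tok_cluster <- rep(seq_len(params$n_clusters),
                       length.out = params$tokens_per_kind)
    pr <- utils::combn(params$tokens_per_kind, 2)
    same <- tok_cluster[pr[1, ]] == tok_cluster[pr[2, ]]
    p_edge <- ifelse(same, params$ppi_within_prob, params$ppi_cross_prob)
    keep <- stats::runif(ncol(pr)) < p_edge
    el <- cbind(token_ids[pr[1, keep]], token_ids[pr[2, keep]])
    g <- igraph::graph_from_edgelist(el, directed = FALSE)
    g + igraph::vertices(setdiff(token_ids, igraph::V(g)$name))
  })

  # pairwise Bernoulli interactions, block-structured by cluster
  pairs <- pair_index(catalog)
  cluster_of <- cluster[match(catalog$drug_id, ids)]
  same <- cluster_of[pairs$i] == cluster_of[pairs$j]
  pos_idx <- with_seed(substream_seed(params$seed, "interactions"), {
    p_int <- ifelse(same, params$within_cluster_ddi_prob,
                    params$cross_cluster_ddi_prob)
    which(stats::runif(nrow(pairs)) < p_int)
  })
  if (length(pos_idx) == 0) {
    stop("parameter combination produced zero interactions", call. = FALSE)
  }
  held <- with_seed(substream_seed(params$seed, "holdout"), {
    n_hold <- round(params$holdout_fraction * length(pos_idx))
    if (n_hold >= length(pos_idx)) {
      stop("holdout_fraction leaves no visible interactions", call. = FALSE)
    }
    sort(sample(pos_idx, n_hold))
  })
  visible <- setdiff(pos_idx, held)

  make_descriptions <- function(pp) {
    classes <- sample(names(DESCRIPTION_TEMPLATES), nrow(pp),
                      replace = TRUE)
    text <- vapply(seq_len(nrow(pp)), function(r) {
      tpl <- sample(DESCRIPTION_TEMPLATES[[classes[r]]], 1)
      a <- pp$drug_a[r]; b <- pp$drug_b[r]
      if (classes[r] == "ADE") {
        sprintf(tpl, sample(ADVERSE_EVENTS, 1), a, b)
      } else {
        sprintf(tpl, a, b, a)
      }
    }, character(1))
    list(text = text, classes = classes)
  }
  desc <- with_seed(substream_seed(params$seed, "descriptions"), {
    list(visible = make_descriptions(pairs[visible, , drop = FALSE]),
         held = make_descriptions(pairs[held, , drop = FALSE]))
  })

  interactions <- data.frame(drug_a = pairs$drug_a[visible],
                             drug_b = pairs$drug_b[visible],
                             description = desc$visible$text,
                             stringsAsFactors = FALSE)
  truth <- data.frame(drug_a = pairs$drug_a[held],
                      drug_b = pairs$drug_b[held],
                      description = desc$held$text, stringsAsFactors = FALSE)
  parsed <- interactions_from_table(interactions, catalog)
  structure(list(catalog = catalog, features = features, ppi = ppi,
                 interactions = parsed$table, m1 = parsed$matrix,
                 truth = truth, params = params,
                 intended_effects = data.frame(
                   drug_a = c(pairs$drug_a[visible], pairs$drug_a[held]),
                   drug_b = c(pairs$drug_b[visible], pairs$drug_b[held]),
                   description = c(desc$visible$text, desc$held$text),
                   effect_class = c(desc$visible$classes,
                                    desc$held$classes),
                   stringsAsFactors = FALSE)),
            class = "synthetic_universe")
}

#' Write a synthetic universe to a directory
#'
#' Emits \code{drugs.tsv}, \code{ddis.tsv}, \code{features_<KIND>.tsv} for
#' every feature kind, \code{ppi.tsv}, \code{truth.tsv} and
#' \code{params.yaml}, all in the exact formats the readers expect, so a
#' written universe round-trips through the I/O layer and the
#' \code{params.yaml} alone reproduces it.
#'
#' @param universe a \code{synthetic_universe}.
#' @param dir output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_universe <- function(universe, dir) {
  if (!dir.exists(dir)) {
    ok <- dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create directory ", dir, call. = FALSE)
  }
  write_drug_catalog(universe$catalog, file.path(dir, "drugs.tsv"))
  write_interactions(universe$interactions, file.path(dir, "ddis.tsv"))
  for (kind in names(universe$features)) {
    write_feature_table(universe$features[[kind]],
                        file.path(dir, paste0("features_", kind, ".tsv")))
  }
  write_ppi(universe$ppi, file.path(dir, "ppi.tsv"))
  write_tsv_strict(universe$truth, file.path(dir, "truth.tsv"))
  yaml::write_yaml(unclass(universe$params),
                   file.path(dir, "params.yaml"))
  invisible(dir)
}

#' Read a universe directory written by \code{\link{write_universe}}
#'
#' @param dir directory containing the universe files.
#' @return A list with the same shape as \code{\link{generate_universe}}'s
#'   output (without the \code{synthetic_universe} class when
#'   \code{params.yaml} is absent).
#' @export
read_universe <- function(dir) {
  catalog <- read_drug_catalog(file.path(dir, "drugs.tsv"))
  features <- list()
  for (kind in FEATURE_KINDS) {
    path <- file.path(dir, paste0("features_", kind, ".tsv"))
    if (file.exists(path)) {
      features[[kind]] <- read_feature_table(path, kind, catalog)
    }
  }
  parsed <- read_interactions(file.path(dir, "ddis.tsv"), catalog)
  ppi <- read_ppi(file.path(dir, "ppi.tsv"))
  truth_path <- file.path(dir, "truth.tsv")
  truth <- if (file.exists(truth_path)) {
    read_tsv_strict(truth_path, c("drug_a", "drug_b"))
  } else NULL
  params_path <- file.path(dir, "params.yaml")
  params <- if (file.exists(params_path)) {
    p <- yaml::read_yaml(params_path)
    do.call(universe_params, p)
  } else NULL
  out <- list(catalog = catalog, features = features, ppi = ppi,
              interactions = parsed$table, m1 = parsed$matrix,
              truth = truth, params = params)
  if (!is.null(params)) class(out) <- "synthetic_universe"
  out
}
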