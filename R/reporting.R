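# Novelty calling above the third-quartile threshold, effect-class
# annotation of interaction descriptions, and the summary tables:
# per-drug discovery rates and per-group novel-DDI counts.

#' Default effect-classification keyword lists
#'
#' Ordered, case-insensitive rules applied to DrugBank-style interaction
#' descriptions. Adverse-event phrases are matched first because wordings
#' like "risk or severity of ..." may also contain pharmacokinetic or
#' pharmacodynamic vocabulary.
#'
#' @export
EFFECT_KEYWORDS <- list(
  ADE = c("risk or severity", "adverse effects"),
  PK = c("metabolism", "serum concentration", "absorption", "excretion"),
  PD = c("therapeutic efficacy", "efficacy", "activities")
)

#' Classify an interaction description into an effect class
#'
#' @param description free-text description (vectorized).
#' @param keywords named list of keyword vectors, checked in list order
#'   (default \code{\link{EFFECT_KEYWORDS}}).
#' @return Character vector over \code{\{"ADE", "PK", "PD",
#'   "UNCLASSIFIED"\}}.
#' @export
classify_effect <- function(description, keywords = EFFECT_KEYWORDS) {
  description <- tolower(as.character(description))
  out <- rep("UNCLASSIFIED", length(description))
  for (cls in rev(names(keywords))) {
    hit <- Reduce(`|`, lapply(keywords[[cls]], function(kw) {
      grepl(kw, description, fixed = TRUE)
    }))
    out[hit] <- cls
  }
  out
}

#' Call novel interactions above the confidence threshold
#'
#' Novel calls are pairs with no known interaction (\code{M1 = 0}) and a
#' unified score strictly greater than the threshold. All known pairs are
#' carried along with \code{known_flag = 1}; their \code{above_threshold}
#' column records whether the model also recovers them ("known predicted").
#' Known pairs are annotated with the effect class of their description;
#' novel pairs have no description and are \code{UNCLASSIFIED}.
#'
#' @param unified unified per-pair score vector.
#' @param pairs the \code{\link{pair_index}} it is aligned to.
#' @param m1 known-interaction matrix.
#' @param threshold novelty threshold in \code{[0, 1]} (strict inequality).
#' @param design optional pair-by-feature matrix from
#'   \code{\link{stack_scores}}; its columns become \code{score_*} columns.
#' @param interactions optional canonical interaction table supplying
#'   descriptions for known pairs.
#' @return A \code{prediction_set} data frame: \code{drug_a}, \code{drug_b},
#'   per-feature \code{score_*} columns, \code{score_unified},
#'   \code{known_flag}, \code{above_threshold}, \code{effect_class},
#'   \code{description}; attribute \code{threshold}.
#' @export
call_novel <- function(unified, pairs, m1, threshold, design = NULL,
                       interactions = NULL) {
  stopifnot(threshold >= 0, threshold <= 1,
            length(unified) == nrow(pairs))
  known <- m1[cbind(pairs$i, pairs$j)] == 1
  above <- unified > threshold
  keep <- known | above
  out <- data.frame(drug_a = pairs$drug_a[keep], drug_b = pairs$drug_b[keep],
                    stringsAsFactors = FALSE)
  if (!is.null(design)) {
    for (kind in colnames(design)) {
      out[[paste0("score_", kind)]] <- design[keep, kind]
    }
  } else {
    for (kind in SCORE_KINDS) {
      out[[paste0("score_", kind)]] <- rep(NA_real_, nrow(out))
    }
  }
  out$score_unified <- unified[keep]
  out$known_flag <- as.integer(known[keep])
  out$above_threshold <- above[keep]
  out$description <- rep("", nrow(out))
  if (!is.null(interactions) && nrow(interactions) > 0) {
    key <- paste(out$drug_a, out$drug_b, sep = "\t")
    ikey <- paste(interactions$drug_a, interactions$drug_b, sep = "\t")
    hit <- match(key, ikey)
    out$description[!is.na(hit)] <- interactions$description[stats::na.omit(hit)]
  }
  out$effect_class <- ifelse(out$known_flag == 1,
                             classify_effect(out$description),
                             "UNCLASSIFIED")
  stopifnot(all(out$known_flag == 1 | out$score_unified > threshold))
  attr(out, "threshold") <- threshold
  class(out) <- c("prediction_set", class(out))
  out
}

#' Discovery rate of novel predictions
#'
#' The percentage of a drug's above-threshold predictions that are novel
#' rather than already known:
#' \eqn{100 \cdot new / (known\_predicted + new)}, rounded to 2 decimals.
#'
#' @param known_predicted number of known interactions recovered above the
#'   threshold.
#' @param new_predicted number of novel above-threshold calls.
#' @return Discovery rate in percent.
#' @export
discovery_rate <- function(known_predicted, new_predicted) {
  stopifnot(known_predicted >= 0, new_predicted >= 0)
  if (known_predicted + new_predicted == 0) {
    stop("discovery rate undefined: no predictions", call. = FALSE)
  }
  round(100 * new_predicted / (known_predicted + new_predicted), 2)
}

#' Per-drug discovery-rate table
#'
#' For every WRHD in the catalog, counts its known interactions
#' (\code{known_described}), the known interactions the model recovers
#' above the threshold (\code{known_predicted}), its novel calls
#' (\code{new_predicted}), and the discovery rate. Drugs with no known or
#' predicted interactions are excluded (rate undefined). Rows are sorted by
#' descending rate, ties broken lexicographically by drug id.
#'
#' @param predictions a \code{prediction_set}.
#' @param m1 known-interaction matrix with catalog dimnames.
#' @param catalog the \code{drug_catalog}.
#' @param top truncate to this many rows (default all).
#' @return Data frame of \code{DiscoveryRateRow}s.
#' @export
discovery_table <- function(predictions, m1, catalog, top = Inf) {
  wrhd <- catalog$drug_id[catalog$is_wrhd]
  novel <- predictions[predictions$known_flag == 0, , drop = FALSE]
  known_pred <- predictions[predictions$known_flag == 1 &
                              predictions$above_threshold, , drop = FALSE]
  rows <- lapply(wrhd, function(d) {
    kd <- sum(m1[d, ])
    kp <- sum(known_pred$drug_a == d | known_pred$drug_b == d)
    np <- sum(novel$drug_a == d | novel$drug_b == d)
    if (kp + np == 0) return(NULL)
    data.frame(drug_id = d, known_described = kd, known_predicted = kp,
               new_predicted = np, rate = discovery_rate(kp, np),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(drug_id = character(0), known_described = integer(0),
                      known_predicted = integer(0),
                      new_predicted = integer(0), rate = numeric(0)))
  }
  out <- out[order(-out$rate, out$drug_id, method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, top)
}

#' Per-group novel-DDI summary
#'
#' A novel DDI contributes to a group when either endpoint drug carries the
#' group label, so a pair bridging two groups is counted once in each.
#' \code{n_drugs} is the number of distinct group members involved in at
#' least one novel call, and \code{rate_per_drug} the novel count per such
#' drug (1 decimal).
#'
#' @param predictions a \code{prediction_set}.
#' @param catalog the \code{drug_catalog}.
#' @param groups which group labels to report (default: all labels present
#'   in the catalog).
#' @return Data frame with \code{group}, \code{novel_count},
#'   \code{n_drugs}, \code{rate_per_drug}, \code{known_described},
#'   \code{known_predicted}.
#' @export
group_summary <- function(predictions, catalog, groups = NULL) {
  if (is.null(groups)) {
    groups <- intersect(DRUG_GROUPS, unique(unlist(catalog$groups)))
  }
  membership <- lapply(groups, function(g) {
    catalog$drug_id[vapply(catalog$groups, function(gs) g %in% gs,
                           logical(1))]
  })
  names(membership) <- groups
  novel <- predictions[predictions$known_flag == 0, , drop = FALSE]
  known <- predictions[predictions$known_flag == 1, , drop = FALSE]
  rows <- lapply(groups, function(g) {
    members <- membership[[g]]
    in_novel <- novel$drug_a %in% members | novel$drug_b %in% members
    involved <- unique(intersect(c(novel$drug_a[in_novel],
                                   novel$drug_b[in_novel]), members))
    kd <- known$drug_a %in% members | known$drug_b %in% members
    kp <- kd & known$above_threshold
    data.frame(group = g, novel_count = sum(in_novel),
               n_drugs = length(involved),
               rate_per_drug = if (length(involved) > 0) {
                 round(sum(in_novel) / length(involved), 1)
               } else 0,
               known_described = sum(kd), known_predicted = sum(kp),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
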