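# Data model: drug catalog, feature tables, interaction table/matrix, PPI
# network, and the strict-TSV readers/writers for all of them. All matrices
# produced downstream are aligned to the canonical (lexicographic) catalog
# order, so the catalog is the single source of indexing truth.

#' Controlled vocabulary of drug group labels
#'
#' Seven women's-reproductive-health categories plus the
#' \code{non_gynecological} bucket for all other approved drugs.
#'
#' @export
DRUG_GROUPS <- c("preconception", "infertility_ivf", "menopause", "uterine",
                 "ovarian", "menstrual", "other_reproductive",
                 "non_gynecological")

#' Feature kinds handled by the pipeline
#'
#' \code{CHEM} chemical fingerprint bits, \code{TECT} merged
#' targets/enzymes/carriers/transporters, \code{ADE} adverse drug events,
#' \code{PATHWAY} biological pathways, \code{TARGET} protein targets (used
#' only to derive the interactome-proximity feature), and the two derived
#' kinds \code{INTERACTOME} and \code{IPF}.
#'
#' @export
FEATURE_KINDS <- c("CHEM", "TECT", "ADE", "PATHWAY", "TARGET")

#' @keywords internal
#' @noRd
SCORE_KINDS <- c("CHEM", "TECT", "ADE", "PATHWAY", "INTERACTOME", "IPF")

#' Construct a drug catalog
#'
#' @param drug_id character vector of unique, non-empty drug identifiers.
#' @param name character vector of human-readable names.
#' @param groups list of character vectors, each a subset of
#'   \code{\link{DRUG_GROUPS}}.
#' @param is_wrhd logical vector flagging women's-reproductive-health drugs.
#'
#' @return A \code{drug_catalog}: a data frame sorted lexicographically by
#'   \code{drug_id} with a list-column \code{groups}.
#' @export
drug_catalog <- function(drug_id, name, groups, is_wrhd) {
  drug_id <- as.character(drug_id)
  if (any(!nzchar(drug_id))) stop("empty drug_id", call. = FALSE)
  dup <- drug_id[duplicated(drug_id)]
  if (length(dup) > 0) {
    stop("duplicate drug_id: ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  bad <- setdiff(unique(unlist(groups)), DRUG_GROUPS)
  if (length(bad) > 0) {
    stop("unknown group label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  is_wrhd <- as.logical(is_wrhd)
  repro <- vapply(groups, function(g) {
    any(g != "non_gynecological")
  }, logical(1))
  if (any(is_wrhd & !repro)) {
    stop("WRHD drug(s) without a reproductive group label: ",
         paste(drug_id[is_wrhd & !repro], collapse = ", "), call. = FALSE)
  }
  ord <- order(drug_id, method = "radix")
  cat <- data.frame(drug_id = drug_id[ord], name = as.character(name)[ord],
                    is_wrhd = is_wrhd[ord], stringsAsFactors = FALSE)
  cat$groups <- unname(lapply(groups[ord], function(g) sort(unique(g))))
  class(cat) <- c("drug_catalog", class(cat))
  cat
}

#' Read a drug catalog from TSV
#'
#' Expects columns \code{drug_id}, \code{name}, \code{groups}
#' (semicolon-separated labels) and \code{is_wrhd} (\code{TRUE}/\code{FALSE}
#' or 0/1). The returned catalog is sorted lexicographically by
#' \code{drug_id} regardless of file row order.
#'
#' @param path path to the TSV file.
#' @return A \code{drug_catalog}.
#' @export
read_drug_catalog <- function(path) {
  df <- read_tsv_strict(path, c("drug_id", "name", "groups", "is_wrhd"))
  groups <- lapply(strsplit(df$groups, ";", fixed = TRUE), function(g) {
    g[nzchar(g)]
  })
  is_wrhd <- df$is_wrhd %in% c("TRUE", "true", "1")
  drug_catalog(df$drug_id, df$name, groups, is_wrhd)
}

#' Write a drug catalog to TSV
#'
#' @param catalog a \code{drug_catalog}.
#' @param path output path.
#' @export
write_drug_catalog <- function(catalog, path) {
  df <- data.frame(
    drug_id = catalog$drug_id,
    name = catalog$name,
    groups = vapply(catalog$groups, paste, character(1), collapse = ";"),
    is_wrhd = ifelse(catalog$is_wrhd, "TRUE", "FALSE"),
    stringsAsFactors = FALSE)
  write_tsv_strict(df, path)
}

#' Read a drug feature table from TSV
#'
#' Long format: one \code{drug_id<TAB>feature_token} row per assignment.
#' Every catalog drug is retained in the result; drugs absent from the file
#' get an empty token set, so all similarity matrices share one index.
#'
#' @param path path to the TSV file.
#' @param feature_kind one of \code{\link{FEATURE_KINDS}}.
#' @param catalog the \code{drug_catalog} defining the drug universe.
#' @return A \code{feature_table}: list with \code{feature_kind} and
#'   \code{assignments}, a named list of sorted token character vectors over
#'   the full catalog.
#' @export
read_feature_table <- function(path, feature_kind, catalog) {
  feature_kind <- match.arg(feature_kind, FEATURE_KINDS)
  df <- read_tsv_strict(path, c("drug_id", "feature_token"))
  unknown <- setdiff(unique(df$drug_id), catalog$drug_id)
  if (length(unknown) > 0) {
    stop("feature table references drug(s) not in catalog: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  if (any(!nzchar(df$feature_token))) {
    stop("empty feature token for drug(s): ",
         paste(unique(df$drug_id[!nzchar(df$feature_token)]), collapse = ", "),
         call. = FALSE)
  }
  assignments <- rep(list(character(0)), nrow(catalog))
  names(assignments) <- catalog$drug_id
  if (nrow(df) > 0) {
    by_drug <- split(df$feature_token, df$drug_id)
    assignments[names(by_drug)] <- lapply(by_drug,
                                          function(t) sort(unique(t)))
  }
  structure(list(feature_kind = feature_kind, assignments = assignments),
            class = "feature_table")
}

#' Write a feature table to TSV
#'
#' @param table a \code{feature_table}.
#' @param path output path.
#' @export
write_feature_table <- function(table, path) {
  n <- lengths(table$assignments)
  df <- data.frame(
    drug_id = rep(names(table$assignments), n),
    feature_token = unlist(table$assignments, use.names = FALSE) %||%
      character(0),
    stringsAsFactors = FALSE)
  write_tsv_strict(df, path)
}

#' @keywords internal
#' @noRd
canonicalize_pairs <- function(a, b) {
  swap <- a > b
  tmp <- a[swap]; a[swap] <- b[swap]; b[swap] <- tmp
  list(a = a, b = b)
}

# Invariant assertion used on every interaction-matrix construction.
#' @keywords internal
#' @noRd
assert_interaction_matrix <- function(m1) {
  stopifnot(is.matrix(m1), nrow(m1) == ncol(m1),
            all(m1 %in% c(0, 1)), all(diag(m1) == 0),
            identical(m1, t(m1)))
  invisible(m1)
}

#' Build the known-interaction reference matrix from a pair table
#'
#' @param interactions data frame with columns \code{drug_a}, \code{drug_b}
#'   (and optionally \code{description}).
#' @param catalog the \code{drug_catalog}.
#' @return Symmetric binary n-by-n matrix with zero diagonal, dimnames set
#'   to catalog drug ids.
#' @export
interaction_matrix <- function(interactions, catalog) {
  n <- nrow(catalog)
  m1 <- matrix(0, n, n, dimnames = list(catalog$drug_id, catalog$drug_id))
  if (nrow(interactions) > 0) {
    i <- match(interactions$drug_a, catalog$drug_id)
    j <- match(interactions$drug_b, catalog$drug_id)
    m1[cbind(i, j)] <- 1
    m1[cbind(j, i)] <- 1
  }
  assert_interaction_matrix(m1)
}

#' Read known drug-drug interactions from TSV
#'
#' Expects columns \code{drug_a}, \code{drug_b}, \code{description}. Pairs
#' are canonicalized (\code{drug_a < drug_b}), duplicates collapsed (first
#' description kept), self-pairs and unknown drugs are hard errors.
#'
#' @param path path to the TSV file.
#' @param catalog the \code{drug_catalog}.
#' @return List with \code{table} (canonical pair data frame) and
#'   \code{matrix} (the symmetric binary reference matrix).
#' @export
read_interactions <- function(path, catalog) {
  df <- read_tsv_strict(path, c("drug_a", "drug_b", "description"))
  interactions_from_table(df, catalog)
}

#' @rdname read_interactions
#' @param df in-memory interaction data frame (same columns as the file).
#' @export
interactions_from_table <- function(df, catalog) {
  if (any(df$drug_a == df$drug_b)) {
    stop("self-interaction pair(s): ",
         paste(unique(df$drug_a[df$drug_a == df$drug_b]), collapse = ", "),
         call. = FALSE)
  }
  unknown <- setdiff(unique(c(df$drug_a, df$drug_b)), catalog$drug_id)
  if (length(unknown) > 0) {
    stop("interaction table references drug(s) not in catalog: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  cp <- canonicalize_pairs(df$drug_a, df$drug_b)
  tab <- data.frame(drug_a = cp$a, drug_b = cp$b,
                    description = if ("description" %in% names(df)) {
                      as.character(df$description)
                    } else "",
                    stringsAsFactors = FALSE)
  tab <- tab[!duplicated(paste(tab$drug_a, tab$drug_b, sep = "\t")), ,
             drop = FALSE]
  tab <- tab[order(tab$drug_a, tab$drug_b, method = "radix"), , drop = FALSE]
  rownames(tab) <- NULL
  list(table = tab, matrix = interaction_matrix(tab, catalog))
}

#' Write an interaction table to TSV
#'
#' @param table canonical interaction data frame.
#' @param path output path.
#' @export
write_interactions <- function(table, path) {
  write_tsv_strict(table[, c("drug_a", "drug_b", "description")], path)
}

#' Read a protein-protein interaction network from TSV
#'
#' Two-column edge list of protein tokens (\code{protein_a},
#' \code{protein_b}). Repeated and reversed edges are collapsed; self-loop
#' rows are skipped with a warning.
#'
#' @param path path to the TSV file.
#' @return An undirected simple \code{igraph} graph.
#' @export
read_ppi <- function(path) {
  df <- read_tsv_strict(path, c("protein_a", "protein_b"))
  loops <- df$protein_a == df$protein_b
  if (any(loops)) {
    warning(sum(loops), " self-loop edge(s) skipped in ", path,
            call. = FALSE)
    df <- df[!loops, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(df, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a PPI network to TSV
#'
#' @param network an undirected \code{igraph} graph.
#' @param path output path.
#' @export
write_ppi <- function(network, path) {
  el <- igraph::as_edgelist(network, names = TRUE)
  cp <- canonicalize_pairs(el[, 1], el[, 2])
  df <- data.frame(protein_a = cp$a, protein_b = cp$b,
                   stringsAsFactors = FALSE)
  df <- df[order(df$protein_a, df$protein_b, method = "radix"), ,
           drop = FALSE]
  write_tsv_strict(df, path)
}

#' Write a prediction set to TSV
#'
#' Columns: \code{drug_a}, \code{drug_b}, the six per-feature scores
#' (\code{score_CHEM}, \code{score_TECT}, \code{score_ADE},
#' \code{score_PATHWAY}, \code{score_INTERACTOME}, \code{score_IPF}),
#' \code{score_unified}, \code{known_flag}, \code{effect_class}. Rows are
#' sorted by descending unified score, ties broken by canonical pair id.
#' Scores are written with 12 decimal digits so a written file re-read
#' reproduces the values exactly at that precision.
#'
#' @param predictions a \code{prediction_set} data frame (see
#'   \code{\link{call_novel}}).
#' @param path output path.
#' @export
write_predictions <- function(predictions, path) {
  cols <- c("drug_a", "drug_b", paste0("score_", SCORE_KINDS),
            "score_unified", "known_flag", "effect_class")
  df <- predictions[, cols, drop = FALSE]
  ord <- order(-df$score_unified, df$drug_a, df$drug_b, method = "radix")
  df <- df[ord, , drop = FALSE]
  for (col in grep("^score_", cols, value = TRUE)) {
    df[[col]] <- format_score(df[[col]])
  }
  write_tsv_strict(df, path)
}

#' Read a predictions TSV back into a data frame
#'
#' @param path path written by \code{\link{write_predictions}}.
#' @return Data frame with numeric score columns.
#' @export
read_predictions <- function(path) {
  df <- read_tsv_strict(path, c("drug_a", "drug_b", "score_unified",
                                "known_flag", "effect_class"))
  for (col in grep("^score_", names(df), value = TRUE)) {
    df[[col]] <- as.numeric(df[[col]])
  }
  df$known_flag <- as.integer(df$known_flag)
  df
}
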