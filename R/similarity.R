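# Per-feature drug-drug similarity (the M2 matrices). Every feature is a set
# of opaque tokens per drug; similarity is the Tanimoto (Jaccard) index.
# Featureless drugs get zero similarity to everything, including themselves,
# so missing data never manufactures evidence.

#' Tanimoto index of two token sets
#'
#' \eqn{T(A,B) = |A \cap B| / |A \cup B|}; 0 when the union is empty, so
#' drugs with no feature data never gain similarity-driven scores.
#'
#' @param a,b character vectors (token sets; duplicates ignored).
#' @return Similarity in \code{[0, 1]}.
#' @export
tanimoto <- function(a, b) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  length(intersect(a, b)) / u
}

#' Build a per-feature similarity matrix (M2)
#'
#' Computes all pairwise Tanimoto similarities through a drugs-by-tokens
#' incidence matrix (intersections via a cross-product), which is exactly
#' equivalent to the elementwise \code{\link{tanimoto}} double loop.
#'
#' @param profiles named list of token character vectors, complete over the
#'   catalog (names must equal \code{catalog$drug_id}).
#' @param catalog the \code{drug_catalog}.
#' @param feature_kind label stored on the matrix (one of CHEM, TECT, ADE,
#'   PATHWAY, INTERACTOME, IPF).
#' @return Symmetric n-by-n matrix in \code{[0, 1]} with attribute
#'   \code{feature_kind}; diagonal is 1 for drugs with a non-empty profile
#'   and 0 otherwise.
#' @export
build_m2 <- function(profiles, catalog, feature_kind) {
  missing <- setdiff(catalog$drug_id, names(profiles))
  if (length(missing) > 0) {
    stop("profiles incomplete over catalog; missing: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  profiles <- lapply(profiles[catalog$drug_id], unique)
  n <- nrow(catalog)
  tokens <- unique(unlist(profiles, use.names = FALSE))
  if (length(tokens) == 0) {
    m2 <- matrix(0, n, n, dimnames = list(catalog$drug_id, catalog$drug_id))
  } else {
    inc <- matrix(0, n, length(tokens),
                  dimnames = list(catalog$drug_id, tokens))
    for (i in seq_len(n)) inc[i, profiles[[i]]] <- 1
    inter <- tcrossprod(inc)
    sizes <- rowSums(inc)
    un <- outer(sizes, sizes, "+") - inter
    m2 <- ifelse(un > 0, inter / un, 0)
    dimnames(m2) <- list(catalog$drug_id, catalog$drug_id)
  }
  attr(m2, "feature_kind") <- feature_kind
  m2
}

#' Interaction profile fingerprints from the reference matrix
#'
#' Each drug is represented by the set of drugs it is known to interact
#' with; two drugs sharing interaction partners are then similar even if no
#' other feature connects them.
#'
#' @param m1 the known-interaction matrix.
#' @param catalog the \code{drug_catalog}.
#' @return Named list mapping each drug id to the character vector of its
#'   known interactors.
#' @export
ipf_profiles <- function(m1, catalog) {
  assert_interaction_matrix(m1)
  ids <- catalog$drug_id
  profs <- lapply(seq_len(nrow(m1)), function(i) ids[m1[i, ] == 1])
  names(profs) <- ids
  profs
}

#' Interactome-proximity profile of a drug
#'
#' Expands a drug's protein targets to every protein within graph distance
#' \code{radius} in the protein-protein interaction network, making target
#' proximity comparable as a token-set feature. Targets absent from the
#' network contribute only themselves.
#'
#' @param targets character vector of protein tokens.
#' @param network undirected \code{igraph} PPI graph.
#' @param radius non-negative neighbourhood radius (0 returns the targets).
#' @return Character vector: the expanded protein token set.
#' @export
interactome_profile <- function(targets, network, radius = 1) {
  if (radius < 0) stop("radius must be >= 0", call. = FALSE)
  targets <- unique(targets)
  if (length(targets) == 0 || radius == 0) return(sort(targets))
  present <- intersect(targets, igraph::V(network)$name)
  expanded <- character(0)
  if (length(present) > 0) {
    nb <- igraph::ego(network, order = radius, nodes = present)
    expanded <- unique(unlist(lapply(nb, function(v) v$name)))
  }
  sort(union(targets, expanded))
}

#' Build all static per-feature similarity matrices
#'
#' Constructs the M2 matrices for CHEM, TECT, ADE, PATHWAY and the
#' interactome-proximity feature (TARGET profiles expanded through the PPI
#' network). The IPF matrix is not built here because it depends on the
#' (possibly masked) reference matrix; see \code{\link{ipf_profiles}}.
#'
#' @param features named list of \code{feature_table}s for CHEM, TECT, ADE,
#'   PATHWAY, TARGET.
#' @param catalog the \code{drug_catalog}.
#' @param ppi undirected \code{igraph} PPI graph.
#' @param radius interactome neighbourhood radius (default 1).
#' @return Named list of similarity matrices: CHEM, TECT, ADE, PATHWAY,
#'   INTERACTOME.
#' @export
build_static_m2 <- function(features, catalog, ppi, radius = 1) {
  needed <- c("CHEM", "TECT", "ADE", "PATHWAY", "TARGET")
  missing <- setdiff(needed, names(features))
  if (length(missing) > 0) {
    stop("missing feature table(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  m2 <- list()
  for (kind in c("CHEM", "TECT", "ADE", "PATHWAY")) {
    m2[[kind]] <- build_m2(features[[kind]]$assignments, catalog, kind)
  }
  prof <- lapply(features$TARGET$assignments, interactome_profile,
                 network = ppi, radius = radius)
  m2$INTERACTOME <- build_m2(prof, catalog, "INTERACTOME")
  m2
}

# --- chemical fingerprints -------------------------------------------------

# FNV-1a-style string hash reduced mod n_bits. State kept below 2^25 so the
# multiply stays exact in double precision; deterministic across platforms.
#' @keywords internal
#' @noRd
hash_token <- function(s, n_bits) {
  h <- 21661362
  for (code in utf8ToInt(s)) {
    h <- bitwXor(as.integer(h), code)
    h <- (h * 16777619) %% 33554432
  }
  as.integer(h %% n_bits)
}

#' Hash a SMILES string into a linear-path fingerprint
#'
#' Enumerates all linear atom/bond paths of 1 to \code{max_path_length}
#' atoms in the molecular graph (parsed with \pkg{ChemmineR}) and hashes
#' each canonical path string into \code{n_bits} buckets. The resulting bit
#' set is a deterministic substructure fingerprint suitable for Tanimoto
#' comparison; precomputed fingerprint bits can be supplied to the pipeline
#' instead whenever structures are unavailable.
#'
#' @param smiles a single SMILES string.
#' @param n_bits fingerprint width (>= 64; default 1024).
#' @param max_path_length maximum path length in atoms (default 7).
#' @return Character vector of bit tokens (\code{"bit<k>"}), usable as a
#'   CHEM profile.
#' @export
smiles_to_fingerprint <- function(smiles, n_bits = 1024,
                                  max_path_length = 7) {
  if (n_bits < 64) stop("n_bits must be >= 64", call. = FALSE)
  if (!requireNamespace("ChemmineR", quietly = TRUE)) {
    stop("ChemmineR is required for SMILES parsing", call. = FALSE)
  }
  # syntax pre-check: the OpenBabel-backed converter silently repairs some
  # malformed inputs, so reject obviously broken strings up front
  chk <- gsub("[^][()]", "", smiles)
  balanced <- function(s, open, close) {
    depth <- 0
    for (ch in strsplit(s, "")[[1]]) {
      if (ch == open) depth <- depth + 1
      if (ch == close) depth <- depth - 1
      if (depth < 0) return(FALSE)
    }
    depth == 0
  }
  if (!nzchar(smiles) || !balanced(chk, "(", ")") ||
      !balanced(chk, "[", "]") ||
      grepl("[^]A-Za-z0-9@+[()=#$/%.:*\\-]", smiles)) {
    stop("unparsable SMILES: ", smiles, call. = FALSE)
  }
  single_atom <- grepl("^\\[?[A-Za-z][a-z]?[0-9+-]*\\]?$", smiles)
  if (single_atom) {
    elem <- sub("^\\[?([A-Za-z][a-z]?).*$", "\\1", smiles)
    return(paste0("bit", hash_token(elem, n_bits)))
  }
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(smiles)),
    error = function(e) NULL)
  ok <- !is.null(sdf) && length(sdf) == 1 &&
    nrow(ChemmineR::atomblock(sdf[[1]])) > 0 &&
    all(grepl("^[A-Za-z]+_[0-9]+$",
              rownames(ChemmineR::atomblock(sdf[[1]]))))
  if (!ok) stop("unparsable SMILES: ", smiles, call. = FALSE)
  mol <- sdf[[1]]
  elements <- sub("_\\d+$", "", rownames(ChemmineR::atomblock(mol)))
  bb <- ChemmineR::bondblock(mol)
  n_atoms <- length(elements)
  adj <- vector("list", n_atoms)
  bond_order <- list()
  if (!is.null(bb) && nrow(bb) > 0 && ncol(bb) >= 3) {
    for (r in seq_len(nrow(bb))) {
      i <- bb[r, 1]; j <- bb[r, 2]; o <- bb[r, 3]
      if (i < 1 || j < 1) next  # padding rows in bond-free molecules
      adj[[i]] <- c(adj[[i]], j)
      adj[[j]] <- c(adj[[j]], i)
      bond_order[[paste(min(i, j), max(i, j))]] <- o
    }
  }
  paths <- character(0)
  # DFS over simple paths starting at every atom; a path and its reverse
  # encode the same fragment, so keep the lexicographically smaller string.
  walk <- function(path, label) {
    paths <<- c(paths, label)
    if (length(path) >= max_path_length) return()
    last <- path[length(path)]
    for (nxt in adj[[last]]) {
      if (nxt %in% path) next
      o <- bond_order[[paste(min(last, nxt), max(last, nxt))]]
      walk(c(path, nxt), paste0(label, "-", o, "-", elements[nxt]))
    }
  }
  for (a in seq_len(n_atoms)) walk(a, elements[a])
  canon <- vapply(paths, function(p) {
    parts <- strsplit(p, "-", fixed = TRUE)[[1]]
    rev_p <- paste(rev(parts), collapse = "-")
    if (rev_p < p) rev_p else p
  }, character(1), USE.NAMES = FALSE)
  bits <- sort(unique(vapply(canon, hash_token, integer(1),
                             n_bits = n_bits, USE.NAMES = FALSE)))
  paste0("bit", bits)
}
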