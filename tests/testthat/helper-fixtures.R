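# Fixture builders shared across test files. Everything is generated in
# code; no fixture files on disk.

# Minimal catalog of n drugs named a, b, c, ...; all WRHDs in "ovarian".
tiny_catalog <- function(n = 3) {
  ids <- letters[seq_len(n)]
  drug_catalog(ids, toupper(ids),
               groups = rep(list("ovarian"), n),
               is_wrhd = rep(TRUE, n))
}

# Random token sets for property-style tests.
random_profiles <- function(n, n_tokens = 10, p = 0.4) {
  profs <- lapply(seq_len(n), function(i) {
    tok <- paste0("t", seq_len(n_tokens))
    tok[stats::runif(n_tokens) < p]
  })
  names(profs) <- letters[seq_len(n)]
  profs
}

# Random symmetric binary interaction matrix over a tiny catalog.
random_m1 <- function(n, p = 0.3) {
  m <- matrix(0, n, n)
  up <- which(upper.tri(m))
  m[up] <- as.numeric(stats::runif(length(up)) < p)
  m <- m + t(m)
  dimnames(m) <- list(letters[seq_len(n)], letters[seq_len(n)])
  m
}

# Small fast synthetic universe for pipeline-level tests.
small_universe <- function(seed = 1, ...) {
  generate_universe(universe_params(n_drugs = 40, n_clusters = 4,
                                    tokens_per_kind = 60,
                                    prototype_set_size = 8,
                                    seed = seed, ...))
}

# Brute-force oracles, kept deliberately naive and independent of the
# implementation paths they check.
oracle_tanimoto_m2 <- function(profiles, ids) {
  n <- length(ids)
  m <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      a <- unique(profiles[[ids[i]]])
      b <- unique(profiles[[ids[j]]])
      u <- length(union(a, b))
      m[i, j] <- if (u == 0) 0 else length(intersect(a, b)) / u
    }
  }
  m
}

oracle_propagate_sum <- function(m1, m2) {
  n <- nrow(m1)
  m2p <- m2
  diag(m2p) <- 0
  raw <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      acc <- 0
      for (k in seq_len(n)) acc <- acc + m1[i, k] * m2p[k, j]
      raw[i, j] <- acc
    }
  }
  out <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) out[i, j] <- max(raw[i, j], raw[j, i])
  }
  diag(out) <- 0
  out
}

oracle_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}
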