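# Independent oracles, implemented before and apart from the package code
# paths they check.

# Brute-force affine-gap local alignment (Gotoh recurrences, zero floor on
# the match state). A gap of length L costs gap_open + L * gap_extend,
# matching the package's parameter convention.
sw_oracle <- function(a, b, submat, gap_open = 10, gap_extend = 0.5) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  M <- matrix(0, n + 1, m + 1)
  Ix <- matrix(-Inf, n + 1, m + 1)
  Iy <- matrix(-Inf, n + 1, m + 1)
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- submat[av[i], bv[j]]
      M[i + 1, j + 1] <- max(0,
                             M[i, j] + s, Ix[i, j] + s, Iy[i, j] + s)
      Ix[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                              Ix[i, j + 1] - gap_extend)
      Iy[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                              Iy[i + 1, j] - gap_extend)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# Exhaustive pairwise concordance (ties count one half).
auc_oracle <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
  }
  total / (length(pos) * length(neg))
}

# Exhaustive balanced-accuracy scan: every achievable positive-call
# partition of the score axis (cutoff at each distinct score, plus calling
# everything positive / negative).
ba_oracle <- function(labels, scores) {
  cuts <- sort(unique(c(-Inf, scores)))
  n_pos <- sum(labels == 1); n_neg <- sum(labels == 0)
  best <- -Inf
  for (cut in cuts) {
    pred <- scores > cut
    ba <- (sum(pred & labels == 1) / n_pos +
             sum(!pred & labels == 0) / n_neg) / 2
    best <- max(best, ba)
  }
  best
}

# Quadratic all-pairs MMP oracle: compares every pair of compounds' cut
# sets directly (pairing logic independent of find_mmps's core index).
mmp_oracle <- function(compounds, ...) {
  cuts <- lapply(compounds$smiles, pcmscreen::enumerate_cuts, ...)
  out <- list()
  for (i in seq_len(nrow(compounds) - 1)) {
    for (j in seq(i + 1, nrow(compounds))) {
      ci <- cuts[[i]]; cj <- cuts[[j]]
      if (nrow(ci) == 0 || nrow(cj) == 0) next
      shared <- intersect(unique(ci$core), unique(cj$core))
      for (core in shared) {
        si <- sort(unique(ci$substituent[ci$core == core]))
        sj <- sort(unique(cj$substituent[cj$core == core]))
        hit <- FALSE
        for (x in si) for (y in sj) if (x != y) hit <- TRUE
        if (hit) {
          ids <- sort(c(compounds$id[i], compounds$id[j]))
          out[[length(out) + 1]] <- paste(ids[1], ids[2], core, sep = "|")
        }
      }
    }
  }
  sort(unique(unlist(out)))
}

# Union-find connected components, independent of igraph.
components_oracle <- function(ids, edges_a, edges_b) {
  parent <- setNames(ids, ids)
  find <- function(x) {
    while (parent[[x]] != x) x <- parent[[x]]
    x
  }
  for (k in seq_along(edges_a)) {
    ra <- find(edges_a[k]); rb <- find(edges_b[k])
    if (ra != rb) parent[[ra]] <- rb
  }
  length(unique(vapply(ids, find, character(1))))
}

random_aa_seq <- function(len) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], len,
               replace = TRUE), collapse = "")
}
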