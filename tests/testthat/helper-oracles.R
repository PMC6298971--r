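# Independent oracles used by the tests. Each is deliberately naive and
# shares no code with the implementation it checks.

# --- Needleman-Wunsch affine-gap DP, score only -------------------------
# Gap of length k costs open + k * extend (matching the aligner's
# convention). Used to certify that the optimal global alignment of a toy
# pair is gapless, so its identity can be counted by hand.
nw_affine_score <- function(a, b, open = 11, extend = 1) {
  S <- get_blosum62()
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)   # ends in match/mismatch
  X <- matrix(NEG, n + 1L, m + 1L)   # ends in gap in b (a consumed)
  Y <- matrix(NEG, n + 1L, m + 1L)   # ends in gap in a
  M[1, 1] <- 0
  for (i in seq_len(n)) X[i + 1L, 1L] <- -(open + i * extend)
  for (j in seq_len(m)) Y[1L, j + 1L] <- -(open + j * extend)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- S[av[i], bv[j]]
      M[i + 1, j + 1] <- max(M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - extend,
                             X[i, j + 1] - extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - extend,
                             Y[i + 1, j] - extend)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

ungapped_score <- function(a, b) {
  S <- get_blosum62()
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  stopifnot(length(av) == length(bv))
  sum(vapply(seq_along(av), function(i) S[av[i], bv[i]], numeric(1)))
}

# fraction of equal positions of two equal-length ungapped sequences
site_identity <- function(a, b) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  100 * mean(av == bv)
}

# --- exhaustive least-squares topology search ---------------------------
# For a distance matrix D over n taxa, fit branch lengths by ordinary
# least squares on every unrooted topology and return the topology with
# minimal SSE. On additive matrices the generating topology fits exactly.
path_design_matrix <- function(tree, tip_order) {
  n <- length(tree$tip.label)
  pairs <- t(utils::combn(n, 2))
  A <- matrix(0, nrow(pairs), nrow(tree$edge))
  edge_key <- paste(tree$edge[, 1], tree$edge[, 2])
  for (r in seq_len(nrow(pairs))) {
    i <- match(tip_order[pairs[r, 1]], tree$tip.label)
    j <- match(tip_order[pairs[r, 2]], tree$tip.label)
    np <- ape::nodepath(tree, i, j)
    for (k in seq_len(length(np) - 1L)) {
      e <- match(paste(np[k], np[k + 1L]), edge_key)
      if (is.na(e)) e <- match(paste(np[k + 1L], np[k]), edge_key)
      A[r, e] <- 1
    }
  }
  A
}

ls_best_topology <- function(D, topologies, designs) {
  n <- nrow(D)
  pairs <- t(utils::combn(n, 2))
  b <- D[pairs]
  sse <- vapply(seq_along(topologies), function(t) {
    A <- designs[[t]]
    x <- qr.solve(crossprod(A), crossprod(A, b))
    sum((A %*% x - b)^2)
  }, numeric(1))
  topologies[[which.min(sse)]]
}

same_topology <- function(t1, t2) {
  phangorn::RF.dist(ape::unroot(t1), ape::unroot(t2)) == 0
}

# --- brute-force consensus recount --------------------------------------
# Re-derives, by direct counting over the raw evidence table, the set of
# CAZyme families each gene should be annotated with under the 2-of-3
# consensus rule.
brute_force_families <- function(evidence, thresholds) {
  caz <- c("pfam", "dbcan", "cazy_blast")
  genes <- unique(evidence$gene_id)
  out <- list()
  for (g in genes) {
    ev <- evidence[evidence$gene_id == g & evidence$source %in% caz, ]
    if (nrow(ev) == 0) next
    fams <- unique(pulpredict::normalize_family(
      ev$label[grepl("^(GH|PL|CE|CBM|AA)[0-9]+", ev$label)]))
    keep <- character()
    for (f in fams) {
      srcs <- character()
      for (r in seq_len(nrow(ev))) {
        if (pulpredict::normalize_family(ev$label[r]) == f &&
            ev$score[r] >= thresholds[[ev$source[r]]]) {
          srcs <- union(srcs, ev$source[r])
        }
      }
      if (length(srcs) >= 2) keep <- c(keep, f)
    }
    if (length(keep) > 0) out[[g]] <- sort(keep)
  }
  out
}

# expected pairwise identity of a mutated family:
# sites match when neither member mutated or both hit the same residue
expected_family_identity <- function(p) {
  100 * ((1 - p)^2 + p^2 / 19)
}
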