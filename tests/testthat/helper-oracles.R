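# Independent oracles used across tests; deliberately written against the
# bare definitions, sharing no code with the package implementation.

# brute-force auto-cross-correlation of Z-scales: explicit double loop
brute_force_acc <- function(sequence, j, k, lag) {
  Z <- zscale_table()
  s <- strsplit(sequence, "")[[1]]
  n <- length(s)
  total <- 0
  for (i in 1:(n - lag)) {
    total <- total + Z[s[i], j] * Z[s[i + lag], k]
  }
  total / (n - lag)
}

# reference MCL: dense literal implementation of the algorithm (no
# pruning), clusters read as connected components of the limit support
# via igraph
reference_mcl <- function(edges, all_nodes, inflation, iters = 200) {
  ids <- sort(unique(c(all_nodes, edges$node_a, edges$node_b)))
  n <- length(ids)
  A <- matrix(0, n, n, dimnames = list(ids, ids))
  for (r in seq_len(nrow(edges))) {
    a <- edges$node_a[r]; b <- edges$node_b[r]
    if (a == b) next
    A[a, b] <- max(A[a, b], edges$weight[r])
    A[b, a] <- A[a, b]
  }
  for (i in seq_len(n)) A[i, i] <- max(A[, i], 1e-12)
  M <- A %*% diag(1 / colSums(A))
  for (s in seq_len(iters)) {
    M2 <- (M %*% M)^inflation
    M2 <- M2 %*% diag(1 / colSums(M2))
    if (max(abs(M2 - M)) < 1e-8) { M <- M2; break }
    M <- M2
  }
  g <- igraph::graph_from_adjacency_matrix(M > 1e-5 | t(M) > 1e-5,
                                           mode = "max")
  comp <- igraph::components(g)$membership
  stats::setNames(as.integer(comp), ids)
}

# do two partitions (named membership vectors) agree up to relabeling?
same_partition <- function(a, b) {
  a <- a[sort(names(a))]; b <- b[sort(names(b))]
  length(a) == length(b) &&
    all(outer(a, a, "==") == outer(b, b, "=="))
}

# exhaustive exact-tandem-repeat finder for short sequences: every pair of
# equal non-overlapping substrings of length >= min_len
has_exact_tandem <- function(sequence, min_len) {
  s <- strsplit(sequence, "")[[1]]
  n <- length(s)
  for (start in seq_len(n - 2 * min_len + 1)) {
    seg <- paste(s[start:(start + min_len - 1)], collapse = "")
    rest <- substr(sequence, start + min_len, n)
    if (grepl(seg, rest, fixed = TRUE)) return(TRUE)
  }
  FALSE
}

# tiny deterministic random amino-acid sequence
random_aa <- function(n, seed) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  withr::with_seed(seed, paste(sample(aa, n, replace = TRUE), collapse = ""))
}
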