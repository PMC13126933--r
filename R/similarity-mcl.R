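# Karlin-Altschul parameters for gapped BLOSUM62, gap open 11 / extend 1
# (the BLASTP defaults the alignment adapter emulates).
.KA_LAMBDA <- 0.267
.KA_K <- 0.041

#' Adaptive E-value threshold for a motif set of size X
#'
#' The all-against-all comparison threshold scales with the motif-set size:
#' with `10^(n-1) <= X <= 10^n`, the threshold is `t = 10^-n`.  At exact
#' powers of ten both brackets hold; the smaller (more permissive) `n` is
#' chosen.
#'
#' @param X Number of motifs in the current set (positive integer).
#' @return A list with elements `X`, `n` and `t = 10^-n`.
#' @export
adaptive_evalue_threshold <- function(X) {
  if (length(X) != 1L || !is.finite(X) || X < 1) {
    stop("X must be a positive integer")
  }
  # ceiling() already lands on the smaller of the two admissible n when X
  # is an exact power of ten (the more permissive threshold)
  n <- ceiling(log10(X))
  list(X = as.integer(X), n = as.integer(n), t = 10^(-n))
}

# Smith-Waterman alignment of one motif against a set, with BLOSUM62 and
# affine gaps, plus Karlin-Altschul E-values for the given search space.
# Returns a tibble of hit statistics per pair.
sw_align <- function(query, subjects, search_space) {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(subjects),
    subject = query,
    type = "local", substitutionMatrix = BLOSUM62,
    gapOpening = 11, gapExtension = 1)
  score <- Biostrings::score(al)
  aln_len <- Biostrings::nchar(al)
  pid <- Biostrings::pid(al, type = "PID1")
  # coverage of each partner by the aligned region
  pr <- as.data.frame(Biostrings::pattern(al)@range)
  sr <- as.data.frame(Biostrings::subject(al)@range)
  evalue <- .KA_K * search_space * exp(-.KA_LAMBDA * score)
  tibble::tibble(
    score = score, evalue = evalue, pident = pid, aln_len = aln_len,
    q_cov = (sr$end - sr$start + 1) / nchar(query),
    s_cov = (pr$end - pr$start + 1) / nchar(subjects))
}

#' All-against-all motif similarity edges
#'
#' Performs local (Smith-Waterman, BLOSUM62, gap 11/1) comparison of every
#' motif pair and keeps edges whose E-value is below the threshold.  Edge
#' weight is `-log10(E-value)`, capped for E-values of numerical zero.
#' Symmetric duplicates are collapsed keeping the best E-value.
#'
#' @param motifs A tibble with columns `id` and `sequence`.
#' @param t E-value threshold; edges require `evalue < t`.  Defaults to the
#'   adaptive threshold for the motif-set size.
#' @param max_weight Weight cap for vanishing E-values (default 200).
#' @return A tibble of edges `node_a`, `node_b`, `weight` (no self-edges).
#' @export
pairwise_motif_similarity <- function(motifs,
                                      t = adaptive_evalue_threshold(nrow(motifs))$t,
                                      max_weight = 200) {
  stopifnot(all(c("id", "sequence") %in% names(motifs)))
  m <- nrow(motifs)
  if (m < 2L) {
    return(tibble::tibble(node_a = character(), node_b = character(),
                          weight = numeric()))
  }
  space <- sum(nchar(motifs$sequence))
  rows <- purrr::map(seq_len(m - 1L), function(i) {
    idx <- (i + 1L):m
    st <- sw_align(motifs$sequence[i], motifs$sequence[idx],
                   search_space = nchar(motifs$sequence[i]) * space)
    st$node_a <- motifs$id[i]
    st$node_b <- motifs$id[idx]
    st
  })
  hits <- dplyr::bind_rows(rows)
  hits <- hits[hits$evalue < t, , drop = FALSE]
  w <- -log10(pmax(hits$evalue, 10^(-max_weight)))
  tibble::tibble(node_a = hits$node_a, node_b = hits$node_b,
                 weight = pmin(w, max_weight))
}

#' Percent-identity edges over near-full-length hits
#'
#' Variant of [pairwise_motif_similarity()] used for the final motif
#' clustering: edges are weighted by percent identity and kept only when
#' the aligned region covers at least `min_length_coverage` of *both*
#' motifs.
#'
#' @inheritParams pairwise_motif_similarity
#' @param min_length_coverage Minimum mutual coverage fraction (default 0.9).
#' @return A tibble of edges `node_a`, `node_b`, `weight` (percent identity).
#' @export
identity_edges <- function(motifs, min_length_coverage = 0.9) {
  stopifnot(all(c("id", "sequence") %in% names(motifs)))
  m <- nrow(motifs)
  if (m < 2L) {
    return(tibble::tibble(node_a = character(), node_b = character(),
                          weight = numeric()))
  }
  space <- sum(nchar(motifs$sequence))
  rows <- purrr::map(seq_len(m - 1L), function(i) {
    idx <- (i + 1L):m
    st <- sw_align(motifs$sequence[i], motifs$sequence[idx],
                   search_space = nchar(motifs$sequence[i]) * space)
    keep <- st$q_cov >= min_length_coverage & st$s_cov >= min_length_coverage
    tibble::tibble(node_a = motifs$id[i], node_b = motifs$id[idx],
                   weight = st$pident)[keep, , drop = FALSE]
  })
  dplyr::bind_rows(rows)
}

#' Markov clustering (MCL) of a weighted undirected graph
#'
#' Canonical MCL: the weighted adjacency matrix (with self-loops) is made
#' column-stochastic, then expansion (matrix power) and inflation
#' (entrywise power followed by column renormalization) alternate, with
#' pruning of small entries, until the matrix is (near) idempotent.
#' Clusters are read off as connected components of the limit matrix's
#' support.  Isolated nodes become singletons.
#'
#' @param edges Tibble with columns `node_a`, `node_b`, `weight >= 0`.
#' @param inflation Inflation exponent (> 1); larger values give more,
#'   smaller clusters.  Values > 10 are interpreted as tenths (e.g. an
#'   inflation written 50 means 5.0), matching the convention used when
#'   inflation is quoted as an integer.
#' @param nodes Optional character vector of all node ids (so isolated
#'   nodes appear as singletons).
#' @param expansion Expansion power (default 2).
#' @param self_loop_weight Either `"max"` (each node's loop gets its
#'   maximum incident edge weight; degree-balanced, the default) or a
#'   positive number.
#' @param prune_threshold Entries below this are zeroed each iteration.
#' @param max_iterations,convergence_tol Iteration controls.
#' @return An object of class `mcl_clustering`: a list with `partition`
#'   (tibble `node`, `cluster`), `inflation`, `n_clusters`, `converged`,
#'   `iterations`.
#' @export
markov_cluster <- function(edges, inflation, nodes = NULL, expansion = 2L,
                           self_loop_weight = "max",
                           prune_threshold = 1e-5,
                           max_iterations = 200L,
                           convergence_tol = 1e-6) {
  if (inflation > 10) inflation <- inflation / 10
  if (inflation <= 1) stop("inflation must exceed 1")
  ids <- unique(c(nodes, edges$node_a, edges$node_b))
  if (length(ids) == 0L) stop("empty node set")
  n <- length(ids)
  M <- matrix(0, n, n, dimnames = list(ids, ids))
  if (nrow(edges) > 0L) {
    ia <- match(edges$node_a, ids)
    ib <- match(edges$node_b, ids)
    keep <- ia != ib
    M[cbind(ia, ib)[keep, , drop = FALSE]] <- edges$weight[keep]
    M[cbind(ib, ia)[keep, , drop = FALSE]] <- edges$weight[keep]
    M <- pmax(M, t(M))
  }
  loop <- if (identical(self_loop_weight, "max")) {
    apply(M, 2, function(col) max(col, 1e-12))
  } else {
    rep(self_loop_weight, n)
  }
  diag(M) <- loop
  normalize <- function(A) sweep(A, 2, pmax(colSums(A), .Machine$double.xmin), "/")
  M <- normalize(M)
  converged <- FALSE
  it <- 0L
  while (it < max_iterations) {
    it <- it + 1L
    M_new <- M
    for (k in seq_len(expansion - 1L)) M_new <- M_new %*% M
    M_new <- M_new^inflation
    M_new[M_new < prune_threshold] <- 0
    M_new <- normalize(M_new)
    delta <- max(abs(M_new - M))
    M <- M_new
    if (delta < convergence_tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    warning("MCL did not converge within ", max_iterations, " iterations")
  }
  # components of the limit support (attractor systems plus their basins)
  supp <- (M > prune_threshold) | (t(M) > prune_threshold)
  cluster <- components_of(supp)
  # renumber clusters 1..k by first appearance
  cluster <- match(cluster, unique(cluster))
  structure(list(
    partition = tibble::tibble(node = ids, cluster = as.integer(cluster)),
    inflation = inflation, n_clusters = length(unique(cluster)),
    converged = converged, iterations = it),
    class = "mcl_clustering")
}

# connected components of a logical adjacency matrix (simple BFS;
# fixture-scale graphs only)
components_of <- function(adj) {
  n <- nrow(adj)
  comp <- rep(NA_integer_, n)
  cur <- 0L
  for (s in seq_len(n)) {
    if (!is.na(comp[s])) next
    cur <- cur + 1L
    queue <- s
    comp[s] <- cur
    while (length(queue) > 0L) {
      v <- queue[[1L]]
      queue <- queue[-1L]
      nb <- which(adj[v, ] & is.na(comp))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' @export
print.mcl_clustering <- function(x, ...) {
  cat("Markov clustering: ", nrow(x$partition), " nodes in ", x$n_clusters,
      " clusters (inflation ", x$inflation,
      if (!x$converged) ", NOT converged" else "", ")\n", sep = "")
  invisible(x)
}

#' Tidy a Markov clustering into a node-cluster tibble
#' @param x An `mcl_clustering` object.
#' @param ... Unused.
#' @return The partition tibble with columns `node`, `cluster`.
#' @export
tidy.mcl_clustering <- function(x, ...) x$partition

#' One-row summary of a Markov clustering
#' @inheritParams tidy.mcl_clustering
#' @return A one-row tibble with `n_nodes`, `n_clusters`, `inflation`,
#'   `converged`, `iterations`.
#' @export
glance.mcl_clustering <- function(x, ...) {
  tibble::tibble(n_nodes = nrow(x$partition), n_clusters = x$n_clusters,
                 inflation = x$inflation, converged = x$converged,
                 iterations = x$iterations)
}

#' Write an edge list in the ABC format understood by the external mcl tool
#' @param edges Edge tibble (`node_a`, `node_b`, `weight`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_abc <- function(edges, path) {
  utils::write.table(edges, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read BLAST tabular (outfmt 6) output into hit statistics
#'
#' Adapter for parity runs with an external BLASTP: reads the standard
#' 12-column tabular format and computes mutual coverage from the hit
#' coordinates and supplied sequence lengths.
#'
#' @param path BLAST `-outfmt 6` file.
#' @param lengths Named integer vector of sequence lengths (names are
#'   sequence ids) used for coverage; optional.
#' @return A tibble with the BLAST columns plus `q_cov`/`s_cov` when
#'   lengths are given.
#' @export
read_blast_tab <- function(path, lengths = NULL) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tab <- utils::read.delim(path, header = FALSE, col.names = cols,
                           stringsAsFactors = FALSE)
  tab <- tibble::as_tibble(tab)
  if (!is.null(lengths)) {
    tab$q_cov <- (tab$qend - tab$qstart + 1) / lengths[tab$qseqid]
    tab$s_cov <- (abs(tab$send - tab$sstart) + 1) / lengths[tab$sseqid]
  }
  tab
}
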