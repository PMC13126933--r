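# canonical motif lengths per family; the length filter keeps -6/+2 aa
FAMILY_CANONICAL <- c(OPR = 38L, PPR = 35L)
# per-family cap on the gap load of a cluster alignment (about half a motif)
FAMILY_GAP_CAP <- c(OPR = 18L, PPR = 16L)

family_length_window <- function(family) {
  canonical <- FAMILY_CANONICAL[[family]]
  c(canonical - 6L, canonical + 2L)
}

#' Assemble seed motifs for the iterative search
#'
#' @param ids,sequences,family,protein_id,start,end Parallel vectors
#'   describing the seed motifs; `family` is `"OPR"` or `"PPR"` (one
#'   family per seed set).
#' @return A motif tibble (`id`, `family`, `sequence`, `protein_id`,
#'   `start`, `end`, `iteration = 0`); errors if a sequence falls outside
#'   the family's accepted length window.
#' @export
motif_seeds <- function(ids, sequences, family, protein_id = NA_character_,
                        start = NA_integer_, end = NA_integer_) {
  stopifnot(all(family %in% names(FAMILY_CANONICAL)))
  out <- tibble::tibble(id = ids, family = family, sequence = sequences,
                        protein_id = protein_id, start = start, end = end,
                        iteration = 0L)
  win <- vapply(out$family, function(f) family_length_window(f),
                integer(2))
  len <- nchar(out$sequence)
  bad <- len < win[1L, ] | len > win[2L, ]
  if (any(bad)) {
    stop("seed motif length outside the family window: ",
         paste(out$id[bad], collapse = ", "))
  }
  out
}

# ---- multiple alignment (built-in center-star adapter) ----

# global pairwise alignment of each sequence to a center sequence, merged
# into one MSA by taking per-position maxima of insertion runs.  Motifs
# are short and near-equal length, so this is adequate for gap counting
# and profile construction.
center_star_msa <- function(seqs) {
  k <- length(seqs)
  if (k == 1L) return(seqs)
  lens <- nchar(seqs)
  center <- which.min(abs(lens - stats::median(lens)))
  others <- setdiff(seq_len(k), center)
  data("BLOSUM62", package = "Biostrings", envir = environment())
  al <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAStringSet(seqs[others]),
    subject = seqs[center], type = "global",
    substitutionMatrix = BLOSUM62, gapOpening = 10, gapExtension = 1)
  pat <- strsplit(as.character(Biostrings::alignedPattern(al)), "")
  sub <- strsplit(as.character(Biostrings::alignedSubject(al)), "")
  L <- lens[center]
  # insertion counts relative to the center: gaps in the center string
  # after having consumed p center residues, p = 0..L
  ins_of <- function(sv) {
    ins <- integer(L + 1L)
    p <- 0L
    for (ch in sv) {
      if (ch == "-") ins[p + 1L] <- ins[p + 1L] + 1L else p <- p + 1L
    }
    ins
  }
  ins_all <- vapply(sub, ins_of, integer(L + 1L))
  ins <- apply(ins_all, 1L, max)
  pad <- function(chunk, width) {
    c(chunk, rep("-", width - length(chunk)))
  }
  build_row <- function(pv, sv) {
    # split the aligned pattern into chunks: insertions before center
    # residue p+1, then the column aligned to each center residue
    chunks <- vector("list", 2L * L + 1L)
    for (q in seq_along(chunks)) chunks[[q]] <- character(0)
    p <- 0L
    for (q in seq_along(sv)) {
      if (sv[q] == "-") {
        chunks[[2L * p + 1L]] <- c(chunks[[2L * p + 1L]], pv[q])
      } else {
        p <- p + 1L
        chunks[[2L * p]] <- pv[q]
      }
    }
    out <- character(0)
    for (p in 0:L) {
      out <- c(out, pad(chunks[[2L * p + 1L]], ins[p + 1L]))
      if (p < L) out <- c(out, chunks[[2L * (p + 1L)]])
    }
    paste(out, collapse = "")
  }
  rows <- character(k)
  rows[center] <- {
    cv <- strsplit(seqs[center], "")[[1L]]
    out <- character(0)
    for (p in 0:L) {
      out <- c(out, rep("-", ins[p + 1L]))
      if (p < L) out <- c(out, cv[p + 1L])
    }
    paste(out, collapse = "")
  }
  for (j in seq_along(others)) {
    rows[others[j]] <- build_row(pat[[j]], sub[[j]])
  }
  names(rows) <- names(seqs)
  rows
}

#' Remove gap-dominated alignment columns
#'
#' Columns whose gap fraction is strictly above `max_gap_fraction` are
#' dropped; row order is preserved.  Used before sequence-logo export and
#' profile construction.
#'
#' @param msa Character vector of equal-length aligned sequences.
#' @param max_gap_fraction Strict threshold (default 0.8: a column with
#'   exactly 80% gaps is kept).
#' @return The filtered alignment (same class and names).
#' @export
filter_gap_columns <- function(msa, max_gap_fraction = 0.8) {
  if (length(msa) == 0L) return(msa)
  mat <- do.call(rbind, strsplit(msa, ""))
  gap_frac <- colMeans(mat == "-")
  keep <- gap_frac <= max_gap_fraction
  out <- apply(mat[, keep, drop = FALSE], 1L, paste, collapse = "")
  names(out) <- names(msa)
  out
}

# maximum number of gap characters carried by any single sequence of the
# alignment ("per-motif slippage"); the inflation-selection criterion
gap_load <- function(msa) {
  if (length(msa) <= 1L) return(0L)
  max(stringr::str_count(msa, stringr::fixed("-")))
}

#' Select the MCL inflation by the alignment-gap criterion
#'
#' Clusters the motif graph at every inflation of the grid (1.1 upward in
#' steps of 0.1), aligns each cluster's members, and chooses the
#' inflation maximizing the number of clusters whose gap load (maximum
#' gaps in any aligned member) is at most `gap_cap` — 18 for OPR, 16 for
#' PPR, about half a motif, so member motifs resemble the seeds over at
#' least half their length.  Ties break toward the lower inflation.
#'
#' @param motifs Motif tibble (`id`, `sequence`, ...).
#' @param edges Similarity edges from [pairwise_motif_similarity()].
#' @param gap_cap Maximum tolerated gap load (default OPR's 18).
#' @param inflation_grid Candidate inflations (default `seq(1.1, 5, 0.1)`).
#' @return A list: `clustering` (an `mcl_clustering`), `inflation`,
#'   `msas` (list of per-cluster alignments), `n_within_cap`.
#' @export
select_inflation <- function(motifs, edges, gap_cap = 18L,
                             inflation_grid = seq(1.1, 5, by = 0.1)) {
  if (nrow(motifs) == 0L) stop("empty motif set")
  seqs <- stats::setNames(motifs$sequence, motifs$id)
  clusterings <- purrr::map(inflation_grid, function(I) {
    suppressWarnings(markov_cluster(edges, inflation = I, nodes = motifs$id))
  })
  # many inflations give the same partition; align each distinct one once
  signature <- vapply(clusterings, function(cl) {
    paste(cl$partition$cluster[match(motifs$id, cl$partition$node)],
          collapse = ",")
  }, character(1))
  distinct <- !duplicated(signature)
  score_of <- new.env(parent = emptyenv())
  msas_of <- new.env(parent = emptyenv())
  for (i in which(distinct)) {
    part <- clusterings[[i]]$partition
    msas <- purrr::map(split(part$node, part$cluster), function(members) {
      center_star_msa(seqs[members])
    })
    assign(signature[i], sum(vapply(msas, gap_load, integer(1)) <= gap_cap),
           envir = score_of)
    assign(signature[i], msas, envir = msas_of)
  }
  scores <- vapply(signature, function(s) get(s, envir = score_of),
                   numeric(1))
  best <- which.max(scores)  # first maximum = lowest inflation
  list(clustering = clusterings[[best]],
       inflation = inflation_grid[[best]],
       msas = get(signature[best], envir = msas_of),
       n_within_cap = scores[[best]])
}

# ---- built-in profile adapter ----

# background residue frequencies of a protein set (canonical letters,
# floored and renormalized so log-odds stay finite)
background_frequencies <- function(proteins) {
  s <- strsplit(paste(proteins$sequence, collapse = ""), "")[[1L]]
  s <- s[s != "X"]
  counts <- table(factor(s, levels = .AA_ORDER))
  bg <- (as.numeric(counts) + 1) / (length(s) + 20)
  bg <- pmax(bg, 1e-3)
  stats::setNames(bg / sum(bg), .AA_ORDER)
}

#' Build a position-specific log-odds profile from a cluster alignment
#'
#' The built-in stand-in for an external profile-HMM builder: columns
#' with more than 50% gaps are dropped, each remaining column gets
#' pseudocount-smoothed residue probabilities, and scores are natural-log
#' odds against the background.  The exact null distribution of the
#' sliding-window score under iid background residues is precomputed by
#' convolving the per-column score distributions, giving hit E-values
#' without a normal-tail approximation.
#'
#' @param msa Character vector of aligned member motifs.
#' @param background Named background frequencies over the 20 residues.
#' @param id Profile identifier.
#' @param pseudocount Dirichlet pseudocount mass (default 1).
#' @param step Score discretization for the null (default 0.02 nats).
#' @return An object of class `motif_profile`: `id`, `width`, `scores`
#'   (width x 21 matrix, `X` column zero), `null_tail` (tail probability
#'   lookup), `n_members`.
#' @export
build_profile <- function(msa, background, id = "profile", pseudocount = 1,
                          step = 0.02) {
  msa <- filter_gap_columns(msa, max_gap_fraction = 0.5)
  mat <- do.call(rbind, strsplit(msa, ""))
  W <- ncol(mat)
  scores <- matrix(0, W, 21L, dimnames = list(NULL, c(.AA_ORDER, "X")))
  for (w in seq_len(W)) {
    col <- mat[, w]
    col <- col[col %in% .AA_ORDER]
    counts <- table(factor(col, levels = .AA_ORDER))
    p <- (as.numeric(counts) + pseudocount * background) /
      (length(col) + pseudocount)
    scores[w, seq_len(20L)] <- log(p / background)
  }
  null_tail <- profile_null_tail(scores[, seq_len(20L), drop = FALSE],
                                 background, step)
  structure(list(id = id, width = W, scores = scores,
                 null_tail = null_tail, step = step,
                 n_members = nrow(mat)),
            class = "motif_profile")
}

# exact distribution of the window score under iid background: convolve
# the per-column discrete score distributions; returns a lookup for
# P(score >= s)
profile_null_tail <- function(scores, background, step) {
  si <- round(scores / step)
  lo <- sum(apply(si, 1L, min))
  hi <- sum(apply(si, 1L, max))
  dist <- c(1)  # mass at offset 0; vector index k = score lo0 + k - 1
  off <- 0L
  for (w in seq_len(nrow(si))) {
    rng <- range(si[w, ])
    new_len <- length(dist) + (rng[2L] - rng[1L])
    new <- numeric(new_len)
    for (a in seq_len(20L)) {
      sh <- si[w, a] - rng[1L]
      new[(1L + sh):(length(dist) + sh)] <-
        new[(1L + sh):(length(dist) + sh)] + background[a] * dist
    }
    dist <- new
    off <- off + rng[1L]
  }
  tail_p <- rev(cumsum(rev(dist)))
  list(offset = off, step = step, tail = tail_p)
}

# P(window score >= s) under the profile's null
null_pvalue <- function(null_tail, s) {
  k <- ceiling(s / null_tail$step) - null_tail$offset + 1L
  k <- pmin(pmax(k, 1L), length(null_tail$tail))
  out <- null_tail$tail[k]
  out[ceiling(s / null_tail$step) - null_tail$offset + 1L >
        length(null_tail$tail)] <- 0
  out
}

#' Search motif profiles against a protein set
#'
#' Slides each profile over every protein, scores windows of the profile
#' width with the position-specific log-odds, converts scores to E-values
#' against the whole scanned window space, and keeps windows with
#' `E-value < significance`.  Overlapping windows of one profile are
#' reduced to non-overlapping score peaks (greedy best-first), mimicking
#' domain envelopes.
#'
#' @param profiles A list of [build_profile()] objects.
#' @param proteins Protein tibble (`id`, `sequence`).
#' @param significance Domain E-value acceptance threshold (default 1e-3;
#'   the method's own cutoff is unstated, so it is a recorded parameter).
#' @param family Family tag stored on the hits (default `"OPR"`).
#' @return A hit tibble: `protein_id`, `start`, `end`, `length`,
#'   `family`, `profile_id`, `score`, `evalue`.
#' @export
search_profiles <- function(profiles, proteins, significance = 1e-3,
                            family = "OPR") {
  empty <- tibble::tibble(protein_id = character(), start = integer(),
                          end = integer(), length = integer(),
                          family = character(), profile_id = character(),
                          score = numeric(), evalue = numeric())
  if (length(profiles) == 0L || nrow(proteins) == 0L) return(empty)
  enc <- purrr::map(proteins$sequence, function(s) {
    match(strsplit(s, "")[[1L]], c(.AA_ORDER, "X"))
  })
  rows <- list()
  for (prof in profiles) {
    W <- prof$width
    n_windows <- sum(pmax(nchar(proteins$sequence) - W + 1L, 0L))
    if (n_windows == 0L) next
    for (i in seq_len(nrow(proteins))) {
      v <- enc[[i]]
      n <- length(v)
      if (n < W) next
      ws <- numeric(n - W + 1L)
      for (w in seq_len(W)) {
        ws <- ws + prof$scores[w, v[w:(n - W + w)]]
      }
      ev <- null_pvalue(prof$null_tail, ws) * n_windows
      cand <- which(ev < significance)
      if (length(cand) == 0L) next
      # greedy non-overlapping peaks, best score first
      cand <- cand[order(-ws[cand])]
      taken <- integer(0)
      for (s0 in cand) {
        if (any(abs(taken - s0) < W)) next
        taken <- c(taken, s0)
        rows[[length(rows) + 1L]] <- tibble::tibble(
          protein_id = proteins$id[i], start = s0,
          end = s0 + W - 1L, length = W, family = family,
          profile_id = prof$id, score = ws[s0], evalue = ev[s0])
      }
    }
  }
  if (length(rows) == 0L) return(empty)
  dplyr::arrange(dplyr::bind_rows(rows), .data$protein_id, .data$start)
}

#' Keep hits within the family's accepted length window
#'
#' New motifs must be within -6/+2 residues of the family's canonical
#' motif length: 32..40 aa for OPR (canonical 38), 29..37 aa for PPR
#' (canonical 35).  Idempotent.
#'
#' @param hits Hit tibble with a `length` column (or `start`/`end`).
#' @param family `"OPR"` or `"PPR"`.
#' @return The filtered hit tibble.
#' @export
filter_hit_length <- function(hits, family) {
  win <- family_length_window(family)
  len <- if ("length" %in% names(hits)) hits$length else hits$end - hits$start + 1L
  hits[len >= win[1L] & len <= win[2L], , drop = FALSE]
}

#' Resolve overlapping motif hits on one protein
#'
#' Pairwise rule on the overlap fraction (intersection length over the
#' shorter motif's length): above 80%, the two hits are considered the
#' same motif and merge into their minimum overlapping region
#' (intersection), keeping the better E-value's attribution; below 20%
#' they are different motifs and both stay; from 20% to 80% inclusive
#' both are eliminated as no longer representative.  Applied iteratively
#' until stable.
#'
#' @param hits Hit tibble for a single protein (`start`, `end`, ...).
#' @return The resolved hit tibble, sorted by `start`; no surviving pair
#'   overlaps by more than 80%.
#' @export
resolve_overlaps <- function(hits) {
  h <- dplyr::arrange(hits, .data$start, .data$end)
  repeat {
    n <- nrow(h)
    if (n < 2L) return(h)
    changed <- FALSE
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        inter <- min(h$end[i], h$end[j]) - max(h$start[i], h$start[j]) + 1L
        if (inter <= 0L) next
        len_i <- h$end[i] - h$start[i] + 1L
        len_j <- h$end[j] - h$start[j] + 1L
        frac <- inter / min(len_i, len_j)
        if (frac > 0.8) {
          keep <- if (!is.null(h$evalue) && h$evalue[j] < h$evalue[i]) j else i
          merged <- h[keep, , drop = FALSE]
          merged$start <- max(h$start[i], h$start[j])
          merged$end <- min(h$end[i], h$end[j])
          if ("length" %in% names(merged)) {
            merged$length <- merged$end - merged$start + 1L
          }
          h <- dplyr::bind_rows(h[-c(i, j), , drop = FALSE], merged)
        } else if (frac >= 0.2) {
          h <- h[-c(i, j), , drop = FALSE]
        } else {
          next
        }
        changed <- TRUE
        break
      }
      if (changed) break
    }
    if (!changed) return(dplyr::arrange(h, .data$start))
    h <- dplyr::arrange(h, .data$start, .data$end)
  }
}

#' Run the iterative profile-based motif discovery loop
#'
#' Each iteration: set the adaptive E-value threshold from the motif-set
#' size, build the all-against-all similarity graph, cluster it with MCL
#' at the inflation chosen by the alignment-gap criterion, build one
#' profile per motif cluster, search every protein, filter hit lengths to
#' the family window, resolve overlaps, and add the new motifs.  The loop
#' stops when an iteration yields no new organelle-targeted (pto)
#' candidate protein, or at `max_iterations` (reported, not an error).
#'
#' @param seeds Seed motif tibble from [motif_seeds()] (one family).
#' @param proteins Protein tibble (`id`, `sequence`, `length`, optional
#'   `species`).
#' @param votes Targeting-vote tibble (see [consensus_pto()]).
#' @param max_iterations Iteration cap (default 10).
#' @param significance Profile-hit E-value threshold (default 1e-3).
#' @param min_votes Organelle-vote quorum for the pto flag (default 2).
#' @param inflation_grid Passed to [select_inflation()].
#' @return An object of class `ipb_result`: `motifs` (seeds plus accepted
#'   new motifs), `candidates` (per protein: `n_motifs`, `pto`,
#'   semicolon-joined motif coordinates), `history` (per-iteration
#'   thresholds, inflation, counts), `converged`, `iterations`.
#' @export
run_ipb <- function(seeds, proteins, votes, max_iterations = 10L,
                    significance = 1e-3, min_votes = 2L,
                    inflation_grid = seq(1.1, 5, by = 0.1)) {
  stopifnot(nrow(seeds) > 0L)
  family <- unique(seeds$family)
  if (length(family) != 1L) stop("seeds must be a single family")
  gap_cap <- FAMILY_GAP_CAP[[family]]
  background <- background_frequencies(proteins)
  pto <- consensus_pto(votes, ids = proteins$id, min_votes = min_votes)
  pto_flag <- stats::setNames(pto$pto, pto$protein_id)
  motifs <- seeds
  known_candidates <- character(0)
  history <- list()
  converged <- FALSE
  it <- 0L
  while (it < max_iterations) {
    it <- it + 1L
    t <- adaptive_evalue_threshold(nrow(motifs))
    edges <- pairwise_motif_similarity(motifs, t = t$t)
    sel <- select_inflation(motifs, edges, gap_cap = gap_cap,
                            inflation_grid = inflation_grid)
    profiles <- purrr::imap(sel$msas, function(msa, cl) {
      build_profile(msa, background, id = paste0("it", it, "_c", cl))
    })
    hits <- search_profiles(profiles, proteins, significance = significance,
                            family = family)
    hits <- filter_hit_length(hits, family)
    new_motifs <- hits |>
      dplyr::group_by(.data$protein_id) |>
      dplyr::group_modify(~ resolve_overlaps(.x)) |>
      dplyr::ungroup()
    # drop hits already present as motifs (same protein, >80% overlap)
    if (nrow(new_motifs) > 0L) {
      dup <- vapply(seq_len(nrow(new_motifs)), function(i) {
        prev <- motifs[!is.na(motifs$protein_id) &
                         motifs$protein_id == new_motifs$protein_id[i], ]
        if (nrow(prev) == 0L) return(FALSE)
        inter <- pmin(prev$end, new_motifs$end[i]) -
          pmax(prev$start, new_motifs$start[i]) + 1L
        shorter <- pmin(prev$end - prev$start,
                        new_motifs$end[i] - new_motifs$start[i]) + 1L
        any(inter / shorter > 0.8)
      }, logical(1))
      new_motifs <- new_motifs[!dup, , drop = FALSE]
    }
    if (nrow(new_motifs) > 0L) {
      seq_map <- stats::setNames(proteins$sequence, proteins$id)
      added <- tibble::tibble(
        id = paste0(new_motifs$protein_id, ":", new_motifs$start, "-",
                    new_motifs$end),
        family = family,
        sequence = substr(seq_map[new_motifs$protein_id],
                          new_motifs$start, new_motifs$end),
        protein_id = new_motifs$protein_id,
        start = new_motifs$start, end = new_motifs$end, iteration = it)
      added <- added[!added$id %in% motifs$id, , drop = FALSE]
      motifs <- dplyr::bind_rows(motifs, added)
    }
    cand_now <- unique(stats::na.omit(motifs$protein_id))
    cand_now <- cand_now[cand_now %in% proteins$id]
    new_cand <- setdiff(cand_now, known_candidates)
    n_new_pto <- sum(pto_flag[new_cand], na.rm = TRUE)
    known_candidates <- cand_now
    history[[it]] <- tibble::tibble(
      iteration = it, threshold = t$t, inflation = sel$inflation,
      n_clusters = sel$clustering$n_clusters, n_motifs = nrow(motifs),
      n_new_candidates = length(new_cand), n_new_pto = n_new_pto)
    if (n_new_pto == 0L) {
      converged <- TRUE
      break
    }
  }
  on_prot <- motifs[!is.na(motifs$protein_id) &
                      motifs$protein_id %in% proteins$id, , drop = FALSE]
  candidates <- if (nrow(on_prot) == 0L) {
    tibble::tibble(protein_id = character(), family = character(),
                   n_motifs = integer(), coordinates = character(),
                   first_iteration = integer(), pto = logical())
  } else on_prot |>
    dplyr::arrange(.data$protein_id, .data$start) |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      family = .env$family, n_motifs = dplyr::n(),
      coordinates = paste0(.data$start, "-", .data$end, collapse = ";"),
      first_iteration = min(.data$iteration), .groups = "drop") |>
    dplyr::mutate(pto = unname(pto_flag[.data$protein_id]))
  if ("species" %in% names(proteins)) {
    candidates <- dplyr::left_join(
      candidates, proteins[c("id", "species")],
      by = c(protein_id = "id"))
  }
  structure(list(motifs = motifs, candidates = candidates,
                 history = dplyr::bind_rows(history),
                 converged = converged, iterations = it,
                 significance = significance, family = family),
            class = "ipb_result")
}

#' @export
print.ipb_result <- function(x, ...) {
  cat("Iterative profile-based search (", x$family, "): ",
      x$iterations, " iteration(s), ",
      nrow(x$motifs), " motifs, ", nrow(x$candidates), " candidate(s)",
      if (!x$converged) " [iteration cap reached]" else "", "\n", sep = "")
  invisible(x)
}

#' Tidy an IPB run into its candidate table
#'
#' The "at least 2 motifs" reporting convention is a view filter, applied
#' here through `min_motifs`, never a deletion from the state.
#'
#' @param x An `ipb_result`.
#' @param min_motifs Minimum motif count for a row to be shown
#'   (default 1).
#' @param ... Unused.
#' @return The candidate tibble.
#' @export
tidy.ipb_result <- function(x, min_motifs = 1L, ...) {
  x$candidates[x$candidates$n_motifs >= min_motifs, , drop = FALSE]
}

#' One-row summary of an IPB run
#' @inheritParams tidy.ipb_result
#' @return A one-row tibble of iteration counts and totals.
#' @export
glance.ipb_result <- function(x, ...) {
  tibble::tibble(family = x$family, iterations = x$iterations,
                 converged = x$converged, n_motifs = nrow(x$motifs),
                 n_candidates = nrow(x$candidates),
                 n_pto_candidates = sum(x$candidates$pto, na.rm = TRUE))
}
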