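#' Call linkers from per-residue linker-propensity scores
#'
#' A residue is linker-eligible when its score is strictly above the
#' cutoff (0.15 by default).  Each maximal run of consecutive eligible
#' residues yields exactly one linker, positioned at the run's
#' maximum-score residue (leftmost on ties).  Inter-linker distances are
#' measured between consecutive linker positions.
#'
#' @param linker_scores Numeric vector of per-residue scores in `[0, 1]`.
#' @param cutoff Eligibility cutoff; strict `>` (default 0.15).
#' @return A list with `positions` (strictly increasing integer vector),
#'   `count`, and `distances` (length `count - 1`).
#' @export
call_linkers <- function(linker_scores, cutoff = 0.15) {
  stopifnot(is.numeric(linker_scores))
  eligible <- linker_scores > cutoff
  runs <- rle(eligible)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  positions <- integer(0)
  for (k in which(runs$values)) {
    idx <- starts[k]:ends[k]
    positions <- c(positions, idx[which.max(linker_scores[idx])])
  }
  list(positions = positions, count = length(positions),
       distances = if (length(positions) > 1L) diff(positions) else integer(0))
}

#' Naive tandem-repeat detection by ungapped self-comparison
#'
#' Built-in stand-in for an external repeat detector: scans every
#' off-diagonal of the sequence-against-itself comparison for windows of
#' length `>= min_len` whose residue identity is `>= min_identity`, and
#' reports the merged union of both copies of every such self-similar
#' segment pair.  Deterministic; intended for fixtures and tests, with
#' production runs consuming externally computed repeat annotations.
#'
#' @param sequence Amino-acid string.
#' @param min_len Minimum repeat unit length in residues (default 29).
#' @param min_identity Minimum fractional identity between the two copies
#'   (default 0.5).
#' @return A tibble of non-overlapping repeat intervals (`start`, `end`),
#'   empty for short or repeat-free sequences.
#' @export
detect_repeats_naive <- function(sequence, min_len = 29L, min_identity = 0.5) {
  n <- nchar(sequence)
  empty <- tibble::tibble(start = integer(), end = integer())
  if (n < 2L * min_len) return(empty)
  s <- strsplit(sequence, "")[[1L]]
  segs <- list()
  for (d in seq_len(n - min_len)) {
    len <- n - d
    if (len < min_len) break
    match_vec <- s[seq_len(len)] == s[(d + 1L):n] & s[seq_len(len)] != "X"
    # sliding-window identity over windows of exactly min_len; extend greedily
    cs <- c(0L, cumsum(match_vec))
    nwin <- len - min_len + 1L
    ident <- (cs[(min_len + 1L):(len + 1L)] - cs[seq_len(nwin)]) / min_len
    hit <- which(ident >= min_identity)
    while (length(hit) > 0L) {
      i0 <- hit[[1L]]
      # grow the window right while overall identity stays above threshold
      j <- i0 + min_len - 1L
      while (j < len &&
             (cs[j + 2L] - cs[i0]) / (j + 2L - i0) >= min_identity) {
        j <- j + 1L
      }
      segs[[length(segs) + 1L]] <- c(i0, j, d)
      hit <- hit[hit > j]
    }
  }
  if (length(segs) == 0L) return(empty)
  iv <- do.call(rbind, lapply(segs, function(x) {
    rbind(c(x[1L], x[2L]), c(x[1L] + x[3L], x[2L] + x[3L]))
  }))
  merge_intervals(tibble::tibble(start = iv[, 1L], end = iv[, 2L]))
}

# union of possibly overlapping 1-based inclusive intervals
merge_intervals <- function(iv) {
  if (nrow(iv) == 0L) return(iv)
  iv <- iv[order(iv$start, iv$end), , drop = FALSE]
  out_s <- iv$start[1L]
  out_e <- iv$end[1L]
  starts <- ends <- integer(0)
  for (i in seq_len(nrow(iv))[-1L]) {
    if (iv$start[i] <= out_e + 1L) {
      out_e <- max(out_e, iv$end[i])
    } else {
      starts <- c(starts, out_s)
      ends <- c(ends, out_e)
      out_s <- iv$start[i]
      out_e <- iv$end[i]
    }
  }
  tibble::tibble(start = as.integer(c(starts, out_s)),
                 end = as.integer(c(ends, out_e)))
}

#' Helix fraction between the two most extreme linkers
#'
#' Fraction of residues called `H` within the inclusive span from the
#' first to the last linker position.  Undefined (`NA`) with fewer than
#' two linkers, which the decision tree treats as a failure.
#'
#' @param ss Character vector of per-residue labels (`"H"` or other).
#' @param linker_positions Integer vector of linker positions.
#' @return Fraction in `[0, 1]`, or `NA_real_` when fewer than 2 linkers.
#' @export
helix_fraction_between_extreme_linkers <- function(ss, linker_positions) {
  if (length(linker_positions) < 2L) return(NA_real_)
  span <- min(linker_positions):max(linker_positions)
  mean(ss[span] == "H")
}

#' Transmembrane-helix exclusion rule
#'
#' Soluble-protein filter: a protein is excluded when any predicted
#' transmembrane helix starts after the N-terminal part, whose end is the
#' 78th residue by default.  A helix fully within the N-terminal part is
#' tolerated (a targeting peptide is often mis-predicted as a TM helix);
#' a helix straddling the boundary triggers exclusion because its
#' membrane-spanning body lies after the N-terminal part.
#'
#' @param tm_helices Tibble of TM helix intervals (`start`, `end`).
#' @param boundary Last residue of the N-terminal part (default 78).
#' @return `TRUE` when the protein is excluded.
#' @export
exclude_tm_after_boundary <- function(tm_helices, boundary = 78L) {
  nrow(tm_helices) > 0L && any(tm_helices$end > boundary)
}
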