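# Three-component Z-scales per amino acid (Hellberg, Sjostrom, Skagerberg
# & Wold 1987, J Med Chem 30:1126-1135): z1 ~ hydrophilicity, z2 ~ steric
# bulk/polarizability, z3 ~ polarity/electronic properties.  X (unknown
# residue) maps to the zero vector so it contributes nothing to ACC terms.
.AA_ORDER <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
               "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

.Z_SCALES <- matrix(c(
  #  z1     z2     z3
   0.07, -1.73,  0.09,  # A
   0.71, -0.97,  4.13,  # C
   3.64,  1.13,  2.36,  # D
   3.08,  0.39, -0.07,  # E
  -4.92,  1.30,  0.45,  # F
   2.23, -5.36,  0.30,  # G
   2.41,  1.74,  1.11,  # H
  -4.44, -1.68, -1.03,  # I
   2.84,  1.41, -3.14,  # K
  -4.19, -1.03, -0.98,  # L
  -2.49, -0.27, -0.41,  # M
   3.22,  1.45,  0.84,  # N
  -1.22,  0.88,  2.23,  # P
   2.18,  0.53, -1.14,  # Q
   2.88,  2.52, -3.44,  # R
   1.96, -1.63,  0.57,  # S
   0.92, -2.09, -1.40,  # T
  -2.69, -2.53, -1.29,  # V
  -4.75,  3.65,  0.85,  # W
  -1.39,  2.32,  0.01   # Y
), ncol = 3, byrow = TRUE,
  dimnames = list(.AA_ORDER, c("z1", "z2", "z3")))

#' Z-scale physico-chemical descriptors per amino acid
#'
#' @return A 21 x 3 matrix of the three Z-scales (`z1`, `z2`, `z3`) for the
#'   20 canonical residues in alphabetical one-letter order, plus an `X`
#'   row of zeros.
#' @export
zscale_table <- function() {
  rbind(.Z_SCALES, X = c(0, 0, 0))
}

#' Amino-acid frequencies of a sequence
#'
#' Counts of each canonical residue divided by the number of canonical
#' residues; `X` positions are excluded from both numerator and
#' denominator.
#'
#' @param sequence Amino-acid string (canonical residues plus `X`).
#' @return Named numeric vector of the 20 frequencies in alphabetical
#'   one-letter order (`freq_A` ... `freq_Y`); sums to 1 for X-free input.
#' @export
aa_frequencies <- function(sequence) {
  s <- strsplit(sequence, "")[[1L]]
  s <- s[s != "X"]
  if (length(s) == 0L) stop("sequence contains no canonical residues")
  counts <- table(factor(s, levels = .AA_ORDER))
  out <- as.numeric(counts) / length(s)
  names(out) <- paste0("freq_", .AA_ORDER)
  out
}

#' Auto-cross-correlation of Z-scales along a sequence
#'
#' The 36 ACC terms feeding the random-forest descriptor:
#' `acc(j, k, lag) = 1/(n - lag) * sum_i z_j(aa_i) * z_k(aa_(i+lag))` over
#' scales `j, k` in 1..3 and `lag` in `1..n_lags` (uncentered products; a
#' centered variant subtracting per-scale sequence means is available).
#' `X` positions carry zero Z-scales, so they contribute zero products
#' while still counting toward `n`.
#'
#' @param sequence Amino-acid string of canonical length `n > n_lags`.
#' @param n_lags Number of lags (default 4, the "window of 4 residues").
#' @param centered Subtract per-scale sequence means first (default
#'   `FALSE`; the convention is recorded with trained models because they
#'   are bound to it).
#' @return Named numeric vector of `3 * 3 * n_lags` components in
#'   lexicographic `(j, k, lag)` order, named like `acc_z1_z2_lag3`.
#' @export
acc_zscales <- function(sequence, n_lags = 4L, centered = FALSE) {
  s <- strsplit(sequence, "")[[1L]]
  n <- length(s)
  if (n <= n_lags) {
    stop("sequence length ", n, " must exceed n_lags = ", n_lags)
  }
  Z <- zscale_table()[s, , drop = FALSE]
  if (centered) {
    Z <- sweep(Z, 2, colMeans(Z), "-")
  }
  out <- numeric(0)
  for (j in 1:3) {
    for (k in 1:3) {
      for (lag in seq_len(n_lags)) {
        v <- sum(Z[seq_len(n - lag), j] * Z[(1L + lag):n, k]) / (n - lag)
        out <- c(out, v)
        names(out)[length(out)] <- paste0("acc_z", j, "_z", k, "_lag", lag)
      }
    }
  }
  out
}

#' Repeat- and linker-geometry descriptors of an annotated protein
#'
#' The four components that directly describe the alpha-solenoid
#' architecture: proportion of residues covered by at least one repeat,
#' median repeat length (aa), number of linkers, and median inter-linker
#' distance (aa).  Empty tracks give 0; even-count medians are the mean of
#' the two middle values.
#'
#' @param repeats Tibble of repeat intervals (`start`, `end`).
#' @param linkers A linker call from [call_linkers()].
#' @param length Protein length in residues.
#' @return Named numeric vector `repeat_proportion`, `median_repeat_len`,
#'   `n_linkers`, `median_linker_dist`.
#' @export
solenoid_descriptors <- function(repeats, linkers, length) {
  covered <- rep(FALSE, length)
  for (i in seq_len(nrow(repeats))) {
    covered[repeats$start[i]:repeats$end[i]] <- TRUE
  }
  c(repeat_proportion = sum(covered) / length,
    median_repeat_len = if (nrow(repeats) > 0L) {
      stats::median(repeats$end - repeats$start + 1)
    } else 0,
    n_linkers = linkers$count,
    median_linker_dist = if (linkers$count > 1L) {
      stats::median(linkers$distances)
    } else 0)
}

#' Proportion of residues predicted disordered
#'
#' @param disorder_scores Per-residue disorder propensities in `[0, 1]`.
#' @param cutoff Residues with score strictly `> cutoff` count as
#'   disordered (default 0.5).
#' @return Fraction in `[0, 1]`.
#' @export
disorder_proportion <- function(disorder_scores, cutoff = 0.5) {
  if (length(disorder_scores) == 0L) return(0)
  mean(disorder_scores > cutoff)
}

# frozen component order of the descriptor; bump when the layout changes
DESCRIPTOR_VERSION <- "ss61-v1"

#' Build the 61-variable descriptor of one protein
#'
#' Concatenates, in frozen order: 4 solenoid-geometry components, the 20
#' amino-acid frequencies, the disorder proportion, and the 36 Z-scale
#' auto-cross-correlation terms (`4 + 20 + 1 + 36 = 61`).
#'
#' @param sequence Amino-acid string.
#' @param repeats Tibble of repeat intervals (`start`, `end`).
#' @param linker_scores Per-residue linker propensities.
#' @param disorder_scores Per-residue disorder propensities.
#' @param linker_cutoff Cutoff passed to [call_linkers()].
#' @param centered Passed to [acc_zscales()].
#' @return Named numeric vector of exactly 61 components.
#' @export
build_descriptor <- function(sequence, repeats, linker_scores,
                             disorder_scores, linker_cutoff = 0.15,
                             centered = FALSE) {
  linkers <- call_linkers(linker_scores, cutoff = linker_cutoff)
  out <- c(solenoid_descriptors(repeats, linkers, nchar(sequence)),
           aa_frequencies(sequence),
           disorder_prop = disorder_proportion(disorder_scores),
           acc_zscales(sequence, centered = centered))
  stopifnot(length(out) == 61L)
  out
}

#' Descriptor matrix for a set of annotated proteins
#'
#' @param proteins Tibble with columns `id`, `sequence`.
#' @param annotations Long annotation tibble (see [read_annotations()]).
#' @param linker_cutoff,centered Passed to [build_descriptor()].
#' @return A tibble with `protein_id` plus the 61 named descriptor
#'   columns; attribute `descriptor_version` records the frozen layout.
#' @export
build_descriptor_matrix <- function(proteins, annotations,
                                    linker_cutoff = 0.15, centered = FALSE) {
  rows <- purrr::map(seq_len(nrow(proteins)), function(i) {
    tr <- annotation_tracks(annotations, proteins$id[i], proteins$length[i])
    d <- build_descriptor(proteins$sequence[i], tr$repeats,
                          tr$linker_scores, tr$disorder_scores,
                          linker_cutoff = linker_cutoff, centered = centered)
    tibble::as_tibble_row(c(list(protein_id = proteins$id[i]), as.list(d)))
  })
  out <- dplyr::bind_rows(rows)
  attr(out, "descriptor_version") <- DESCRIPTOR_VERSION
  out
}
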