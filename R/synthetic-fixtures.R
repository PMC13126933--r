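#' Consensus repeat motif of the synthetic solenoid generator
#'
#' Fixed 38-aa amphipathic helix-pair consensus used by all generators:
#' two helices (positions 1-16 and 21-36) joined by a short linker, with
#' hydrophobic residues spaced at helical periodicity.  Fixed in code and
#' versioned with the package so fixture experiments are reproducible.
#' @export
SOLENOID_CONSENSUS <- "PEWLELARSLAEKGDVEGALKAYREAIELDPRNAEAWQ"

# helix segments of one repeat unit, relative 1-based coordinates
.MOTIF_HELICES <- list(c(1L, 16L), c(21L, 36L))

#' Mutate a sequence by random substitutions
#'
#' Each position is substituted, independently with probability `rate`,
#' by a uniformly drawn *different* canonical residue.  A pure function
#' of the seed.
#'
#' @param sequence Amino-acid string.
#' @param rate Per-position substitution probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return The mutated sequence.
#' @export
mutate_sequence <- function(sequence, rate, seed) {
  stopifnot(rate >= 0, rate < 1)
  with_seed_(seed, {
    s <- strsplit(sequence, "")[[1L]]
    hit <- stats::runif(length(s)) < rate
    for (i in which(hit)) {
      s[i] <- sample(setdiff(.AA_ORDER, s[i]), 1L)
    }
    paste(s, collapse = "")
  })
}

# random sequence with a globular-like residue composition
random_globular_sequence <- function(length) {
  # approximate Swiss-Prot background, alphabetical order
  comp <- c(0.083, 0.014, 0.055, 0.067, 0.039, 0.071, 0.023, 0.059,
            0.058, 0.097, 0.024, 0.040, 0.047, 0.039, 0.055, 0.066,
            0.053, 0.069, 0.011, 0.029)
  paste(sample(.AA_ORDER, length, replace = TRUE, prob = comp),
        collapse = "")
}

# targeting-vote rows for one protein under the four mock predictors
mock_votes <- function(protein_id, organelle_votes = 0L) {
  tools <- c("deeploc", "localizer", "targetp", "wolfpsort")
  labels <- rep("other", 4L)
  if (organelle_votes > 0L) {
    labels[seq_len(min(organelle_votes, 4L))] <-
      rep(c("chloroplast", "mitochondrion"), 2L)[seq_len(min(organelle_votes, 4L))]
  }
  tibble::tibble(protein_id = protein_id, tool = tools, label = labels)
}

# sparse annotation rows; unset cells NA, dense defaults are 0 / "other"
ann_row <- function(protein_id, type, start = NA, end = NA,
                    position = NA, score = NA, label = NA) {
  tibble::tibble(protein_id = protein_id, annotation_type = type,
                 start = start, end = end, position = position,
                 score = score, label = label, tool = NA_character_)
}

#' Generate one synthetic alpha-solenoid protein with its annotations
#'
#' The sequence is an N-flank, `n_repeats` independently mutated copies
#' of the fixed consensus motif, and a C-flank.  Annotation tracks are
#' derived from the construction truth: the planted repeat intervals,
#' linker-propensity 0.9 at the junction residue between consecutive
#' repeats (0.02 background), helix calls over the two helices of each
#' repeat, disorder 0.7 over the flanks, and no transmembrane helix.
#' When `targeting` is set the protein receives two organelle votes.
#'
#' @param id Protein id.
#' @param n_repeats Number of repeat copies (>= 2; default 5).
#' @param substitution_rate Per-position divergence of each copy from the
#'   consensus (default 0.15).
#' @param flanks Integer vector `c(n_flank, c_flank)` (default 50, 30).
#' @param targeting Logical: organelle-targeted protein (default TRUE).
#' @param seed Integer seed; output is a pure function of it.
#' @param motif_pool Optional character vector of template motifs; each
#'   repeat mutates a cyclically chosen template instead of the
#'   consensus (used for staged-divergence fixtures).
#' @return A list: `record` (one-row protein tibble), `annotations`,
#'   `votes`, `truth` (planted motif intervals, linker positions, helix
#'   segments, realized motif sequences).
#' @export
make_solenoid_record <- function(id, n_repeats = 5L,
                                 substitution_rate = 0.15,
                                 flanks = c(50L, 30L), targeting = TRUE,
                                 seed = 1L, motif_pool = NULL) {
  stopifnot(n_repeats >= 2L, substitution_rate >= 0, substitution_rate < 1)
  W <- nchar(SOLENOID_CONSENSUS)
  templates <- motif_pool %||% SOLENOID_CONSENSUS
  motifs <- vapply(seq_len(n_repeats), function(k) {
    tpl <- templates[[(k - 1L) %% length(templates) + 1L]]
    mutate_sequence(tpl, substitution_rate, seed = seed * 1000L + k)
  }, character(1))
  n_fl <- flanks[1L]
  c_fl <- flanks[2L]
  flank_seq <- with_seed_(seed * 1000L + 999L, {
    c(random_globular_sequence(n_fl), random_globular_sequence(c_fl))
  })
  sequence <- paste0(flank_seq[1L], paste(motifs, collapse = ""),
                     flank_seq[2L])
  starts <- n_fl + (seq_len(n_repeats) - 1L) * W + 1L
  ends <- starts + W - 1L
  linker_pos <- ends[-n_repeats]  # junction residue between repeats
  helix_iv <- do.call(rbind, lapply(seq_len(n_repeats), function(k) {
    do.call(rbind, lapply(.MOTIF_HELICES, function(h) {
      c(starts[k] + h[1L] - 1L, starts[k] + h[2L] - 1L)
    }))
  }))
  ann <- dplyr::bind_rows(
    ann_row(id, "repeat", start = starts, end = ends),
    ann_row(id, "linker_score", position = linker_pos, score = 0.9),
    ann_row(id, "linker_score",
            position = c(n_fl, n_fl + n_repeats * W + 1L), score = 0.02),
    ann_row(id, "ss",
            position = unlist(lapply(seq_len(nrow(helix_iv)), function(r) {
              helix_iv[r, 1L]:helix_iv[r, 2L]
            })), label = "H"),
    ann_row(id, "disorder",
            position = c(seq_len(n_fl),
                         (n_fl + n_repeats * W + 1L):nchar(sequence)),
            score = 0.7))
  list(
    record = fasta_records(id, sequence),
    annotations = ann,
    votes = mock_votes(id, organelle_votes = if (targeting) 2L else 0L),
    truth = list(motif_intervals = tibble::tibble(start = starts, end = ends),
                 motif_sequences = motifs, linker_positions = linker_pos,
                 helix_segments = helix_iv))
}

#' Generate one synthetic non-solenoid protein
#'
#' Negatives carry no planted repeats, uniformly low linker propensity,
#' scattered short helices and low disorder.  `"globular"` draws a
#' random sequence with globular composition; `"shuffled-solenoid"`
#' permutes a paired positive's sequence, preserving its residue
#' multiset so composition features cannot separate the pair.
#'
#' @param id Protein id.
#' @param length Sequence length (>= 50; ignored for shuffles).
#' @param composition `"globular"` or `"shuffled-solenoid"`.
#' @param seed Integer seed.
#' @param paired_sequence Positive sequence to permute when
#'   `composition = "shuffled-solenoid"`.
#' @param organelle_votes Number of organelle votes (default 0).
#' @return A list `record`, `annotations`, `votes`.
#' @export
make_negative_record <- function(id, length = 300L,
                                 composition = c("globular",
                                                 "shuffled-solenoid"),
                                 seed = 1L, paired_sequence = NULL,
                                 organelle_votes = 0L) {
  composition <- match.arg(composition)
  sequence <- with_seed_(seed, {
    if (composition == "globular") {
      stopifnot(length >= 50L)
      random_globular_sequence(length)
    } else {
      stopifnot(!is.null(paired_sequence))
      paste(sample(strsplit(paired_sequence, "")[[1L]]), collapse = "")
    }
  })
  n <- nchar(sequence)
  helix_rows <- with_seed_(seed + 1L, {
    # a few short scattered helices, ~15% helix content
    k <- max(1L, n %/% 60L)
    st <- sort(sample.int(n - 9L, k))
    unlist(lapply(st, function(s) s:(s + 8L)))
  })
  ann <- dplyr::bind_rows(
    ann_row(id, "linker_score", position = c(5L, n %/% 2L, n - 4L),
            score = 0.05),
    ann_row(id, "ss", position = unique(helix_rows), label = "H"),
    ann_row(id, "disorder", position = seq_len(min(10L, n)), score = 0.2))
  list(record = fasta_records(id, sequence), annotations = ann,
       votes = mock_votes(id, organelle_votes = organelle_votes))
}

#' Generate the labeled descriptor benchmark
#'
#' Stands in for a curated solenoid / non-solenoid training set.
#' Positives vary in repeat count (2-8 copies at 15% divergence) and are
#' organelle-targeted with probability 0.8; negatives mix globular
#' random sequences (2/3) with composition-preserving shuffles of
#' positives (1/3) and carry organelle votes with probability 0.2.
#' Classes are separable primarily on repeat proportion and linker count
#' by construction.
#'
#' @param n_pos,n_neg Class sizes (each >= 10; defaults 200 / 150).
#' @param seed Integer seed.
#' @return A list: `proteins`, `annotations`, `votes`, `labels`
#'   (`protein_id`, `class`, `solenoid`), and `descriptors` (the labeled
#'   61-column descriptor tibble ready for [train_rf()]).
#' @export
make_benchmark <- function(n_pos = 200L, n_neg = 150L, seed = 1L) {
  stopifnot(n_pos >= 10L, n_neg >= 10L)
  pos <- purrr::map(seq_len(n_pos), function(i) {
    cfg <- with_seed_(seed * 100000L + i, list(
      n_repeats = sample(2:8, 1L),
      flanks = c(sample(40:80, 1L), sample(20:50, 1L)),
      targeting = stats::runif(1) < 0.8))
    make_solenoid_record(sprintf("pos%03d", i), n_repeats = cfg$n_repeats,
                         substitution_rate = 0.15, flanks = cfg$flanks,
                         targeting = cfg$targeting,
                         seed = seed * 100000L + i)
  })
  neg <- purrr::map(seq_len(n_neg), function(i) {
    s <- seed * 200000L + i
    votes <- with_seed_(s + 5000L, if (stats::runif(1) < 0.2) 2L else 0L)
    if (i %% 3L == 0L) {
      make_negative_record(sprintf("neg%03d", i),
                           composition = "shuffled-solenoid", seed = s,
                           paired_sequence = pos[[(i %% n_pos) + 1L]]$record$sequence,
                           organelle_votes = votes)
    } else {
      len <- with_seed_(s + 6000L, sample(150:600, 1L))
      make_negative_record(sprintf("neg%03d", i), length = len,
                           composition = "globular", seed = s,
                           organelle_votes = votes)
    }
  })
  all <- c(pos, neg)
  proteins <- dplyr::bind_rows(purrr::map(all, "record"))
  annotations <- dplyr::bind_rows(purrr::map(all, "annotations"))
  votes <- dplyr::bind_rows(purrr::map(all, "votes"))
  labels <- tibble::tibble(
    protein_id = proteins$id,
    class = rep(c("solenoid", "non-solenoid"), c(n_pos, n_neg)),
    solenoid = rep(c(TRUE, FALSE), c(n_pos, n_neg)))
  descriptors <- build_descriptor_matrix(proteins, annotations) |>
    dplyr::left_join(labels[c("protein_id", "class")], by = "protein_id")
  list(proteins = proteins, annotations = annotations, votes = votes,
       labels = labels, descriptors = descriptors)
}

#' Generate seed motifs for the iterative search testbed
#'
#' @param n Number of seed motifs (default 12).
#' @param family Motif family tag (default `"OPR"`).
#' @param divergence Per-position divergence of each seed from the
#'   consensus (default 0.10).
#' @param seed Integer seed.
#' @return A seed-motif tibble (see [motif_seeds()]).
#' @export
make_seed_motifs <- function(n = 12L, family = "OPR", divergence = 0.10,
                             seed = 1L) {
  seqs <- vapply(seq_len(n), function(i) {
    mutate_sequence(SOLENOID_CONSENSUS, divergence, seed = seed * 500L + i)
  }, character(1))
  motif_seeds(sprintf("seed%02d", seq_len(n)), seqs, family = family)
}

#' Generate a toy proteome with planted solenoids and decoys
#'
#' End-to-end testbed for the iterative search: organelle-targeted
#' planted solenoids at a stated divergence from the seed consensus,
#' optional non-targeted planted solenoids, globular decoys, and
#' optionally a staged-divergence pair — protein `stagedA` whose motifs
#' diverge `divergence_stages[1]` from the consensus, and `stagedB`
#' whose motifs are further mutations *of A's realized motifs* so that B
#' is near `divergence_stages[2]` from the consensus but much closer to
#' A, and is therefore reachable only after A's motifs have joined the
#' profile set.
#'
#' @param n_planted_pto Organelle-targeted planted solenoids (default 8).
#' @param n_planted_nonpto Non-targeted planted solenoids (default 0).
#' @param n_decoys Globular decoys (default 20).
#' @param divergence Per-position divergence of planted motifs from the
#'   consensus (default 0.15).
#' @param divergence_stages Length-2 vector of consensus divergences for
#'   the staged pair (use `c(0.5, 0.8)`: shallower far-stage values are
#'   still reachable directly from the seed profiles, defeating the
#'   purpose of the fixture), or `NULL` (default) for none.
#' @param n_seeds,seed_divergence Passed to [make_seed_motifs()].
#' @param seed Integer seed.
#' @return A list: `seeds`, `proteins`, `annotations`, `votes`, `truth`
#'   (tibble of planted protein ids, their kind and motif count).
#' @export
make_toy_proteome <- function(n_planted_pto = 8L, n_planted_nonpto = 0L,
                              n_decoys = 20L, divergence = 0.15,
                              divergence_stages = NULL, n_seeds = 12L,
                              seed_divergence = 0.10, seed = 1L) {
  seeds <- make_seed_motifs(n_seeds, divergence = seed_divergence,
                            seed = seed)
  recs <- list()
  truth <- list()
  add <- function(x, kind) {
    recs[[length(recs) + 1L]] <<- x
    truth[[length(truth) + 1L]] <<- tibble::tibble(
      protein_id = x$record$id, kind = kind,
      n_motifs = if (!is.null(x$truth)) nrow(x$truth$motif_intervals) else 0L)
  }
  for (i in seq_len(n_planted_pto)) {
    add(make_solenoid_record(sprintf("planted%02d", i),
                             substitution_rate = divergence,
                             targeting = TRUE, seed = seed * 300L + i),
        "planted_pto")
  }
  for (i in seq_len(n_planted_nonpto)) {
    add(make_solenoid_record(sprintf("nonpto%02d", i),
                             substitution_rate = divergence,
                             targeting = FALSE, seed = seed * 400L + i),
        "planted_nonpto")
  }
  if (!is.null(divergence_stages)) {
    stopifnot(length(divergence_stages) == 2L,
              divergence_stages[2L] > divergence_stages[1L])
    # Staged pair as two diverged subfamilies: protein A repeats noisy
    # copies of one variant V_A of the consensus, so its motifs form a
    # tight cluster of their own once found; protein B repeats copies of
    # V_B, a further drift of V_A.  The compound rate r solves
    # d2 ~ d1 + (1 - d1) r, putting B near divergence_stages[2] from the
    # consensus while staying close to A's subfamily profile.
    v_a <- mutate_sequence(SOLENOID_CONSENSUS, divergence_stages[1L],
                           seed = seed * 700L + 11L)
    r <- (divergence_stages[2L] - divergence_stages[1L]) /
      (1 - divergence_stages[1L])
    v_b <- mutate_sequence(v_a, r, seed = seed * 700L + 12L)
    a <- make_solenoid_record("stagedA", substitution_rate = 0.05,
                              targeting = TRUE, seed = seed * 700L + 1L,
                              motif_pool = v_a)
    b <- make_solenoid_record("stagedB", substitution_rate = 0.05,
                              targeting = TRUE, seed = seed * 700L + 2L,
                              motif_pool = v_b)
    add(a, "staged_intermediate")
    add(b, "staged_far")
  }
  for (i in seq_len(n_decoys)) {
    len <- with_seed_(seed * 600L + i, sample(200:500, 1L))
    votes <- with_seed_(seed * 600L + 5000L + i,
                        if (stats::runif(1) < 0.3) 2L else 0L)
    add(make_negative_record(sprintf("decoy%02d", i), length = len,
                             seed = seed * 600L + i,
                             organelle_votes = votes),
        "decoy")
  }
  list(seeds = seeds,
       proteins = dplyr::bind_rows(purrr::map(recs, "record")),
       annotations = dplyr::bind_rows(purrr::map(recs, "annotations")),
       votes = dplyr::bind_rows(purrr::map(recs, "votes")),
       truth = dplyr::bind_rows(truth))
}

#' Regenerate repeat annotations with the naive detector
#'
#' "Honest mode" for integration tests: replaces the mock repeat
#' intervals by [detect_repeats_naive()] calls on the sequences, keeping
#' the other mock tracks (no naive stand-in exists for the external
#' linker/secondary-structure/disorder predictors).
#'
#' @param proteins Protein tibble.
#' @param annotations Mock annotation tibble.
#' @param ... Passed to [detect_repeats_naive()].
#' @return The annotation tibble with recomputed `repeat` rows.
#' @export
naive_repeat_annotations <- function(proteins, annotations, ...) {
  keep <- annotations[annotations$annotation_type != "repeat", , drop = FALSE]
  rep_rows <- purrr::map(seq_len(nrow(proteins)), function(i) {
    iv <- detect_repeats_naive(proteins$sequence[i], ...)
    if (nrow(iv) == 0L) return(NULL)
    ann_row(proteins$id[i], "repeat", start = iv$start, end = iv$end)
  })
  dplyr::bind_rows(keep, dplyr::bind_rows(rep_rows))
}
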