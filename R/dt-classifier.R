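#' Decision-tree filter parameters
#'
#' All thresholds of the alpha-solenoid decision-tree filter chain, each
#' exposed as a parameter.  Defaults follow the method's stated values:
#' at least one sequence repeat of at least 29 aa; at least 4 linkers with
#' consecutive linkers between 32 and 400 aa apart (inclusive); at least
#' 65% helix between the two extreme linkers; no transmembrane helix
#' beyond residue 78; at least 2 of 4 organelle-targeting votes.
#'
#' @param min_repeat_len Minimum repeat length in aa (default 29).
#' @param min_repeat_count Minimum number of such repeats (default 1).
#' @param min_linkers Minimum linker count (default 4).
#' @param linker_spacing Inclusive `[min, max]` spacing between
#'   consecutive linkers in aa (default `c(32, 400)`).
#' @param linker_score_cutoff Linker-propensity cutoff (default 0.15).
#' @param min_helix_fraction Minimum helix fraction between the extreme
#'   linkers (default 0.65).
#' @param tm_boundary End of the N-terminal part for the TM rule
#'   (default 78).
#' @param min_targeting_votes Organelle-vote quorum (default 2).
#' @param preset `"methods"` (the defaults) or `"results-text"`, an
#'   alternative documented reading requiring 2 repeats of >= 26 aa.
#' @return A named list of class `dt_params`.
#' @export
dt_params <- function(min_repeat_len = 29L, min_repeat_count = 1L,
                      min_linkers = 4L, linker_spacing = c(32L, 400L),
                      linker_score_cutoff = 0.15,
                      min_helix_fraction = 0.65, tm_boundary = 78L,
                      min_targeting_votes = 2L,
                      preset = c("methods", "results-text")) {
  preset <- match.arg(preset)
  if (preset == "results-text") {
    min_repeat_len <- 26L
    min_repeat_count <- 2L
  }
  stopifnot(min_repeat_len > 0, min_repeat_count > 0, min_linkers > 0,
            length(linker_spacing) == 2L,
            linker_spacing[1] < linker_spacing[2])
  structure(list(
    min_repeat_len = min_repeat_len, min_repeat_count = min_repeat_count,
    min_linkers = min_linkers, linker_spacing = linker_spacing,
    linker_score_cutoff = linker_score_cutoff,
    min_helix_fraction = min_helix_fraction, tm_boundary = tm_boundary,
    min_targeting_votes = min_targeting_votes), class = "dt_params")
}

# one protein through the filter chain; returns verdict row
dt_classify_one <- function(length, tracks, n_organelle_votes, params) {
  measured <- list(n_repeats_long = NA_integer_, n_linkers = NA_integer_,
                   helix_fraction = NA_real_,
                   n_organelle_votes = NA_integer_)
  fail <- function(step) {
    c(list(pass = FALSE, failed_step = step), measured)
  }
  # (1) transmembrane exclusion
  if (exclude_tm_after_boundary(tracks$tm_helices, params$tm_boundary)) {
    return(fail("tm"))
  }
  # (2) sequence repeats (absence of repeat rows means none were found)
  rep_len <- tracks$repeats$end - tracks$repeats$start + 1
  measured$n_repeats_long <- sum(rep_len >= params$min_repeat_len)
  if (measured$n_repeats_long < params$min_repeat_count) {
    return(fail("repeats"))
  }
  # (3) linker count and spacing
  if (!tracks$has[["linker"]]) stop("missing annotation track: linker_score")
  linkers <- call_linkers(tracks$linker_scores, params$linker_score_cutoff)
  measured$n_linkers <- linkers$count
  spacing_ok <- length(linkers$distances) == 0L ||
    all(linkers$distances >= params$linker_spacing[1] &
        linkers$distances <= params$linker_spacing[2])
  if (linkers$count < params$min_linkers || !spacing_ok) {
    return(fail("linkers"))
  }
  # (4) helix content between the extreme linkers
  if (!tracks$has[["ss"]]) stop("missing annotation track: ss")
  hf <- helix_fraction_between_extreme_linkers(tracks$ss, linkers$positions)
  measured$helix_fraction <- hf
  if (is.na(hf) || hf < params$min_helix_fraction) {
    return(fail("helix_fraction"))
  }
  # (5) organelle-targeting consensus
  measured$n_organelle_votes <- n_organelle_votes
  if (n_organelle_votes < params$min_targeting_votes) {
    return(fail("targeting"))
  }
  c(list(pass = TRUE, failed_step = "none"), measured)
}

#' Run the decision-tree filter chain over annotated proteins
#'
#' Applies, in order and short-circuiting at the first failure:
#' transmembrane exclusion, sequence-repeat requirement, linker count and
#' spacing, helix fraction between the extreme linkers, and the
#' organelle-targeting consensus.  The first failing step is recorded per
#' protein together with the measured quantities.
#'
#' @param proteins Tibble with columns `id`, `sequence`, `length`.
#' @param annotations Long annotation tibble (see [read_annotations()]).
#' @param votes Targeting-vote tibble (see [consensus_pto()]).
#' @param params A [dt_params()] object.
#' @return A tibble of verdicts: `protein_id`, `pass`, `failed_step`
#'   (`tm`, `repeats`, `linkers`, `helix_fraction`, `targeting` or
#'   `none`), plus the measured values per step (NA for steps not
#'   reached).
#' @export
dt_classify <- function(proteins, annotations, votes, params = dt_params()) {
  stopifnot(inherits(params, "dt_params"))
  pto <- consensus_pto(votes, ids = proteins$id,
                       min_votes = params$min_targeting_votes)
  nv <- stats::setNames(pto$n_organelle_votes, pto$protein_id)
  rows <- purrr::map(seq_len(nrow(proteins)), function(i) {
    tr <- annotation_tracks(annotations, proteins$id[i], proteins$length[i])
    v <- dt_classify_one(proteins$length[i], tr,
                         nv[[proteins$id[i]]], params)
    tibble::as_tibble_row(c(list(protein_id = proteins$id[i]), v))
  })
  dplyr::bind_rows(rows)
}

#' Exhaustive grid evaluation of decision-tree thresholds
#'
#' Evaluates every combination of the supplied parameter grids on a
#' labeled training set and reports confusion counts and rates per
#' combination.  The best combination maximizes F1, with ties broken
#' toward higher precision (the stated selection intent, "maximizing
#' precision and recall", needs a combiner; F1 is ours).
#'
#' @param proteins,annotations,votes As in [dt_classify()].
#' @param labels Tibble with `protein_id` and logical `solenoid` (the
#'   training truth).
#' @param grid A named list of parameter vectors (names as in
#'   [dt_params()]); parameters not in the grid stay at their defaults.
#' @return A tibble with one row per combination: the varied parameters,
#'   `TP`, `FP`, `TN`, `FN`, `precision`, `recall`, `specificity`, `F1`,
#'   `accuracy`; the selected row index is in attribute `best`.
#' @export
dt_parameter_sweep <- function(proteins, annotations, votes, labels, grid) {
  if (length(grid) == 0L || any(lengths(grid) == 0L)) {
    stop("empty parameter grid")
  }
  combos <- expand.grid(grid, stringsAsFactors = FALSE)
  truth <- stats::setNames(labels$solenoid, labels$protein_id)[proteins$id]
  rows <- purrr::map(seq_len(nrow(combos)), function(i) {
    p <- do.call(dt_params, as.list(combos[i, , drop = FALSE]))
    verdict <- dt_classify(proteins, annotations, votes, p)
    m <- metrics_from_counts(
      TP = sum(verdict$pass & truth), FP = sum(verdict$pass & !truth),
      TN = sum(!verdict$pass & !truth), FN = sum(!verdict$pass & truth))
    dplyr::bind_cols(tibble::as_tibble(combos[i, , drop = FALSE]), m)
  })
  out <- dplyr::bind_rows(rows)
  f1 <- ifelse(is.na(out$F1), -Inf, out$F1)
  prec <- ifelse(is.na(out$precision), -Inf, out$precision)
  attr(out, "best") <- order(-f1, -prec)[1L]
  out
}
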