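#' Read a protein FASTA file into a tibble
#'
#' Reads amino-acid FASTA and returns one row per entry.  The header token
#' before the first whitespace becomes the protein id, sequences are
#' upper-cased and a trailing stop character (`*`) is stripped.
#'
#' @param path Path to a FASTA file of amino-acid sequences.
#' @return A tibble with columns `id`, `sequence` and `length`.  An empty
#'   file yields a zero-row tibble with a warning.
#' @details Only the 20 canonical residues plus `X` are accepted; any other
#'   character is an error reporting its position.  Duplicated ids are an
#'   error: ids must be unique within a proteome.
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) {
    warning("FASTA file '", path, "' contains no sequences")
    return(tibble::tibble(id = character(), sequence = character(),
                          length = integer()))
  }
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- unname(toupper(as.character(aa)))
  seqs <- sub("\\*+$", "", seqs)
  fasta_records(ids, seqs)
}

#' Assemble and validate protein records
#'
#' @param ids Character vector of unique protein ids.
#' @param sequences Character vector of amino-acid sequences (canonical
#'   residues plus `X`).
#' @return A tibble with columns `id`, `sequence`, `length`.
#' @export
fasta_records <- function(ids, sequences) {
  stopifnot(length(ids) == length(sequences))
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("duplicate protein id(s): ", paste(unique(dup), collapse = ", "))
  }
  bad <- stringr::str_locate(sequences, "[^ACDEFGHIKLMNPQRSTVWYX]")[, "start"]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1L]
    stop("invalid residue in sequence '", ids[i], "' at position ", bad[i])
  }
  if (any(nchar(sequences) < 1L)) {
    stop("zero-length sequence for id ",
         ids[which(nchar(sequences) < 1L)[1L]])
  }
  tibble::tibble(id = as.character(ids), sequence = sequences,
                 length = nchar(sequences))
}

#' Write protein records to FASTA
#'
#' @param records A tibble with columns `id` and `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  aa <- Biostrings::AAStringSet(records$sequence)
  names(aa) <- records$id
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Extract a 1-based inclusive subsequence
#'
#' Coordinates are 1-based and inclusive throughout the package, matching
#' residue numbering; the slice of `[start, end]` has length
#' `end - start + 1`.
#'
#' @param sequence An amino-acid string.
#' @param start,end Residue positions, `1 <= start <= end <= nchar(sequence)`.
#' @return The sub-sequence as a string.
#' @export
slice_sequence <- function(sequence, start, end) {
  n <- nchar(sequence)
  if (any(start < 1L) || any(end > n) || any(start > end)) {
    stop("interval [", start, ",", end, "] out of range for length ", n)
  }
  substr(rep(sequence, length.out = max(length(start), 1L)), start, end)
}

#' Organelle-targeting consensus over predictor votes
#'
#' A protein is flagged `pto` ("predicted targeted to organelles") when at
#' least `min_votes` of the four localization predictors call it
#' chloroplast- or mitochondrion-targeted.  Votes for the two organelles
#' pool: either label counts toward the quorum.  Tools absent from the
#' table implicitly vote "other".
#'
#' @param votes A tibble with columns `protein_id`, `tool` and `label`
#'   (`label` in `chloroplast`, `mitochondrion`, `other`).  At most one row
#'   per (protein, tool).
#' @param ids Optional character vector of protein ids the result must
#'   cover; proteins with no vote rows get `pto = FALSE`.
#' @param min_votes Vote quorum (default 2, "at least 2 over 4 predictors").
#' @return A tibble with columns `protein_id`, `n_organelle_votes`, `pto`.
#' @export
consensus_pto <- function(votes, ids = NULL, min_votes = 2L) {
  stopifnot(all(c("protein_id", "tool", "label") %in% names(votes)))
  if (anyDuplicated(votes[c("protein_id", "tool")])) {
    stop("more than one label for the same (protein, tool)")
  }
  tab <- votes |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(
      n_organelle_votes =
        sum(.data$label %in% c("chloroplast", "mitochondrion")),
      .groups = "drop")
  if (!is.null(ids)) {
    tab <- tibble::tibble(protein_id = as.character(ids)) |>
      dplyr::left_join(tab, by = "protein_id") |>
      dplyr::mutate(n_organelle_votes =
                      dplyr::coalesce(.data$n_organelle_votes, 0L))
  }
  dplyr::mutate(tab, pto = .data$n_organelle_votes >= min_votes)
}

#' Read a structural-annotation table
#'
#' The annotation dialect is a tab-separated file with one header line and
#' columns `protein_id`, `annotation_type`, `start`, `end`, `position`,
#' `score`, `label`, `tool`.  Each `annotation_type` uses a subset:
#' `repeat`/`tm` use `start`,`end`; `linker_score`/`disorder` use
#' `position`,`score`; `ss` uses `position`,`label`; `targeting` uses
#' `tool`,`label`.  Unused cells are empty.
#'
#' @param path Path to the annotation TSV.
#' @return A tibble in the same long layout.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                           na.strings = c("NA", ""))
  need <- c("protein_id", "annotation_type")
  if (!all(need %in% names(ann))) {
    stop("annotation table must have columns ", paste(need, collapse = ", "))
  }
  for (col in c("start", "end", "position", "score", "label", "tool")) {
    if (!col %in% names(ann)) ann[[col]] <- NA
  }
  tibble::as_tibble(ann)
}

#' Write a structural-annotation table
#' @param annotations Long annotation tibble (see [read_annotations()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "")
  invisible(path)
}

#' Read a taxonomy table (protein id, species, phylum)
#' @param path Tab-separated file with columns `protein_id`, `species`,
#'   `phylum`.
#' @return A tibble.
#' @export
read_taxonomy <- function(path) {
  tax <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  stopifnot(all(c("protein_id", "species", "phylum") %in% names(tax)))
  tibble::as_tibble(tax)
}

# Per-protein annotation tracks, expanded to dense vectors.  Internal
# accessor shared by the decision-tree and descriptor stages.
annotation_tracks <- function(annotations, protein_id, length) {
  ann <- annotations[annotations$protein_id == protein_id, , drop = FALSE]
  sub <- function(type) ann[ann$annotation_type == type, , drop = FALSE]
  dense <- function(rows, default) {
    v <- rep(default, length)
    if (nrow(rows) > 0L) v[rows$position] <- rows$score
    v
  }
  rep_rows <- sub("repeat")
  tm_rows <- sub("tm")
  ss_rows <- sub("ss")
  ss <- rep("other", length)
  if (nrow(ss_rows) > 0L) ss[ss_rows$position] <- ss_rows$label
  list(
    repeats = tibble::tibble(start = as.integer(rep_rows$start),
                             end = as.integer(rep_rows$end)),
    tm_helices = tibble::tibble(start = as.integer(tm_rows$start),
                                end = as.integer(tm_rows$end)),
    linker_scores = dense(sub("linker_score"), 0),
    disorder_scores = dense(sub("disorder"), 0),
    ss = ss,
    has = c(repeats = any(ann$annotation_type == "repeat"),
            linker = any(ann$annotation_type == "linker_score"),
            ss = any(ann$annotation_type == "ss"),
            tm = TRUE,
            disorder = any(ann$annotation_type == "disorder"))
  )
}
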