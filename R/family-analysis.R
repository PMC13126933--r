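#' Cluster candidate proteins into families
#'
#' Builds a similarity graph over candidates from all-against-all hit
#' statistics, keeping edges with `E-value < max_evalue` whose aligned
#' region covers at least `min_mutual_coverage` of *both* proteins, and
#' partitions it with Markov clustering.  Candidates without any kept
#' edge become singleton families.
#'
#' @param candidate_ids Character vector of candidate protein ids.
#' @param hits Tibble of pairwise hits with columns `node_a`, `node_b`,
#'   `evalue`, `q_cov`, `s_cov` (coverage of each partner by the aligned
#'   region).  [pairwise_protein_hits()] produces this from sequences.
#' @param max_evalue Edge E-value cutoff (default 1e-6).
#' @param min_mutual_coverage Mutual coverage cutoff (default 0.7).
#' @param inflation MCL inflation; integer values above 10 are read as
#'   tenths (50 means 5.0), the default.
#' @return A tibble `protein_id`, `family_id` (contiguous from 1).
#' @export
cluster_families <- function(candidate_ids, hits, max_evalue = 1e-6,
                             min_mutual_coverage = 0.7, inflation = 50) {
  if (length(candidate_ids) == 0L) {
    return(tibble::tibble(protein_id = character(), family_id = integer()))
  }
  keep <- hits$evalue < max_evalue &
    hits$q_cov >= min_mutual_coverage & hits$s_cov >= min_mutual_coverage
  edges <- tibble::tibble(node_a = hits$node_a[keep],
                          node_b = hits$node_b[keep],
                          weight = -log10(pmax(hits$evalue[keep], 1e-200)))
  cl <- suppressWarnings(
    markov_cluster(edges, inflation = inflation, nodes = candidate_ids))
  out <- cl$partition
  names(out) <- c("protein_id", "family_id")
  out[out$protein_id %in% candidate_ids, , drop = FALSE]
}

#' All-against-all protein similarity hits with coverage
#'
#' Local alignment (BLOSUM62, gap 11/1) of every protein pair, reporting
#' the E-value and the fraction of each partner covered by the aligned
#' region; input for [cluster_families()].
#'
#' @param proteins Protein tibble (`id`, `sequence`).
#' @return A tibble `node_a`, `node_b`, `evalue`, `q_cov`, `s_cov`.
#' @export
pairwise_protein_hits <- function(proteins) {
  m <- nrow(proteins)
  if (m < 2L) {
    return(tibble::tibble(node_a = character(), node_b = character(),
                          evalue = numeric(), q_cov = numeric(),
                          s_cov = numeric()))
  }
  space <- sum(nchar(proteins$sequence))
  rows <- purrr::map(seq_len(m - 1L), function(i) {
    idx <- (i + 1L):m
    st <- sw_align(proteins$sequence[i], proteins$sequence[idx],
                   search_space = nchar(proteins$sequence[i]) * space)
    tibble::tibble(node_a = proteins$id[i], node_b = proteins$id[idx],
                   evalue = st$evalue, q_cov = st$q_cov, s_cov = st$s_cov)
  })
  dplyr::bind_rows(rows)
}

#' Phylostratigraphic class of each family
#'
#' A singleton family has one member; a species-specific family has
#' several members from one species; a phylum-specific family spans
#' several species of one phylum; an inter-phyla family spans phyla.
#'
#' @param families Tibble `protein_id`, `family_id` from
#'   [cluster_families()].
#' @param taxonomy Tibble `protein_id`, `species`, `phylum`; every family
#'   member must be present.
#' @return A tibble with one row per family: `family_id`, `n_members`,
#'   `n_species`, `n_phyla`, `class`.
#' @export
classify_families <- function(families, taxonomy) {
  missing <- setdiff(families$protein_id, taxonomy$protein_id)
  if (length(missing) > 0L) {
    stop("protein(s) missing from taxonomy: ",
         paste(missing, collapse = ", "))
  }
  families |>
    dplyr::left_join(taxonomy, by = "protein_id") |>
    dplyr::group_by(.data$family_id) |>
    dplyr::summarise(
      n_members = dplyr::n(),
      n_species = dplyr::n_distinct(.data$species),
      n_phyla = dplyr::n_distinct(.data$phylum), .groups = "drop") |>
    dplyr::mutate(class = dplyr::case_when(
      .data$n_members == 1L ~ "singleton",
      .data$n_phyla > 1L ~ "inter-phyla",
      .data$n_species > 1L ~ "phylum-specific",
      TRUE ~ "species-specific"))
}

#' Positional bias of motif clusters along proteins
#'
#' For each motif cluster with more than `min_cluster_size - 1` member
#' motifs, computes the frequency with which the cluster occurs at each
#' relative repeat position (the 1-based ordinal rank of the motif among
#' its protein's motifs, in coordinate order).  A cluster is biased when
#' at least `bias_threshold` of its motifs sit at one position.
#'
#' @param assignments Tibble with columns `protein_id`, `start`,
#'   `cluster` — one row per retained motif, `cluster` being its motif
#'   cluster; one representative per paralog family is expected upstream.
#' @param bias_threshold Bias cutoff on the maximum positional frequency
#'   (default 0.8, `>=`).
#' @param min_cluster_size Minimum motif count for a cluster to enter the
#'   table (default 5, i.e. clusters with more than 4 motifs).
#' @return A tibble `cluster`, `size`, `position`, `frequency`, `biased`,
#'   `biased_position`; per-cluster frequencies sum to 1.
#' @export
motif_positional_bias <- function(assignments, bias_threshold = 0.8,
                                  min_cluster_size = 5L) {
  ranked <- assignments |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(position = dplyr::row_number()) |>
    dplyr::ungroup()
  tab <- ranked |>
    dplyr::count(.data$cluster, .data$position, name = "n") |>
    dplyr::group_by(.data$cluster) |>
    dplyr::mutate(size = sum(.data$n), frequency = .data$n / .data$size) |>
    dplyr::filter(.data$size >= min_cluster_size) |>
    dplyr::mutate(
      biased = max(.data$frequency) >= bias_threshold,
      biased_position = dplyr::if_else(
        .data$biased, .data$position[which.max(.data$frequency)],
        NA_integer_)) |>
    dplyr::ungroup() |>
    dplyr::select("cluster", "size", "position", "frequency",
                  "biased", "biased_position")
  tab
}

#' Longest member per family (paralog deduplication)
#'
#' @param families Tibble `protein_id`, `family_id`.
#' @param proteins Protein tibble (`id`, `length`).
#' @return Character vector of one representative id per family.
#' @export
family_representatives <- function(families, proteins) {
  families |>
    dplyr::left_join(proteins[c("id", "length")],
                     by = c(protein_id = "id")) |>
    dplyr::group_by(.data$family_id) |>
    dplyr::slice_max(.data$length, n = 1L, with_ties = FALSE) |>
    dplyr::ungroup() |>
    dplyr::pull(.data$protein_id)
}
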