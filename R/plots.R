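#' Plot cluster-size distribution of a Markov clustering
#'
#' @param object An `mcl_clustering` object.
#' @param ... Unused.
#' @return A ggplot: clusters ordered by size, bar height = member count.
#' @export
autoplot.mcl_clustering <- function(object, ...) {
  sizes <- object$partition |>
    dplyr::count(.data$cluster, name = "size") |>
    dplyr::arrange(dplyr::desc(.data$size)) |>
    dplyr::mutate(rank = dplyr::row_number())
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$rank, y = .data$size)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::labs(
      x = "cluster (by decreasing size)", y = "motifs",
      title = sprintf("Markov clustering at inflation %.1f: %d clusters",
                      object$inflation, object$n_clusters)) +
    ggplot2::theme_minimal()
}

#' Plot feature importances of a random-forest model
#'
#' @param object An `rf_model`.
#' @param top_n Number of top features to show (default 20).
#' @param ... Unused.
#' @return A ggplot of mean-decrease-in-impurity importances.
#' @export
autoplot.rf_model <- function(object, top_n = 20L, ...) {
  imp <- rank_feature_importance(object) |>
    dplyr::slice_head(n = top_n) |>
    dplyr::mutate(feature = factor(.data$feature, levels = rev(.data$feature)))
  ggplot2::ggplot(imp, ggplot2::aes(x = .data$importance, y = .data$feature)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "mean decrease in impurity", y = NULL,
                  title = "Random-forest feature importance") +
    ggplot2::theme_minimal()
}

#' Plot motif accumulation across iterative-search iterations
#'
#' @param object An `ipb_result`.
#' @param ... Unused.
#' @return A ggplot of the motif count and new-candidate count per
#'   iteration.
#' @export
autoplot.ipb_result <- function(object, ...) {
  h <- tidyr::pivot_longer(
    object$history[c("iteration", "n_motifs", "n_new_candidates")],
    cols = c("n_motifs", "n_new_candidates"),
    names_to = "quantity", values_to = "count")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$iteration, y = .data$count,
                                  colour = .data$quantity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = object$history$iteration) +
    ggplot2::labs(x = "iteration", y = "count", colour = NULL,
                  title = "Iterative profile-based search") +
    ggplot2::theme_minimal()
}

#' Heatmap of motif-cluster positional bias
#'
#' @param bias_table Output of [motif_positional_bias()].
#' @return A ggplot heatmap: motif clusters by relative repeat position,
#'   fill = frequency; biased clusters are marked.
#' @export
plot_positional_bias <- function(bias_table) {
  lab <- bias_table |>
    dplyr::distinct(.data$cluster, .data$biased) |>
    dplyr::mutate(cluster_label = paste0(.data$cluster,
                                         ifelse(.data$biased, " *", "")))
  d <- dplyr::left_join(bias_table, lab, by = c("cluster", "biased"))
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$position),
                                  y = .data$cluster_label,
                                  fill = .data$frequency)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = "relative repeat position", y = "motif cluster",
                  fill = "frequency",
                  title = "Positional bias of motif clusters (* biased)") +
    ggplot2::theme_minimal()
}

#' Bar chart of decision-tree failure provenance
#'
#' @param verdicts Output of [dt_classify()].
#' @return A ggplot of protein counts per first failing step.
#' @export
plot_dt_verdicts <- function(verdicts) {
  d <- dplyr::count(verdicts, .data$failed_step, name = "n")
  steps <- c("tm", "repeats", "linkers", "helix_fraction", "targeting",
             "none")
  d$failed_step <- factor(d$failed_step, levels = steps)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$failed_step, y = .data$n)) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = "first failing step (none = passed)", y = "proteins",
                  title = "Decision-tree filter provenance") +
    ggplot2::theme_minimal()
}
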