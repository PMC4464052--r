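#' Plot a cumulative RMSD histogram
#'
#' @param object A [cumulative_histogram()] tibble.
#' @param ... Unused.
#' @return A ggplot: cumulative proportion of ligands against the RMSD
#'   threshold.
#' @export
autoplot.cumulative_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$edge,
                                       y = .data$proportion)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "RMSD threshold (Å)",
                  y = "cumulative proportion") +
    ggplot2::theme_minimal()
}

#' Plot pose-family probabilities
#'
#' @param object A [build_pose_families()] tibble.
#' @param ... Unused.
#' @return A ggplot of family probabilities by rank.
#' @export
autoplot.pose_families <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$family),
                                       y = .data$probability)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "pose family (rank)", y = "probability") +
    ggplot2::theme_minimal()
}

#' Plot a rescoring: docking score versus adjusted score
#'
#' @param object A [rescore()] result.
#' @param ... Unused.
#' @return A ggplot showing the applied pKd bonus per pose.
#' @export
autoplot.pose_rescoring <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$score,
                                       y = .data$adjusted_score,
                                       colour = .data$w)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "docking score (pKd)",
                  y = "adjusted score (pKd)", colour = "bonus w") +
    ggplot2::theme_minimal()
}

#' Plot an ensemble selection over its similarity matrix
#'
#' @param object An `ensemble_selection`.
#' @param ... Unused.
#' @return A ggplot heat map of the pocket similarity matrix with
#'   exemplar rows marked.
#' @export
autoplot.ensemble_selection <- function(object, ...) {
  v <- object$matrix$values
  df <- tidyr::pivot_longer(
    tibble::as_tibble(v, rownames = "a"),
    -"a", names_to = "b", values_to = "similarity")
  df$a <- factor(df$a, levels = object$matrix$ids)
  df$b <- factor(df$b, levels = object$matrix$ids)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$b, y = .data$a,
                                   fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 1)) +
    ggplot2::annotate(
      "point",
      x = match(object$exemplar_ids, object$matrix$ids),
      y = match(object$exemplar_ids, object$matrix$ids),
      shape = 4, size = 3) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90))
}
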