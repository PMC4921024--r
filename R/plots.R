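#' Plot per-genome stage counts of a call set
#'
#' @param object a `fusion_calls` tibble.
#' @param ... unused.
#' @return A ggplot: genes surviving each workflow stage, per genome.
#' @export
autoplot.fusion_calls <- function(object, ...) {
  s <- stage_summary(object) |>
    tidyr::pivot_longer(c("n_naive", "n_candidate", "n_final"),
                        names_to = "stage", values_to = "n") |>
    mutate(stage = factor(.data$stage,
                          levels = c("n_naive", "n_candidate", "n_final"),
                          labels = c("naive multi-domain",
                                     "full-gene candidate",
                                     "final fusion")))
  ggplot2::ggplot(s, ggplot2::aes(x = .data$genome_id, y = .data$n,
                                  fill = .data$stage)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "genes",
                  title = "Fusion-detection stage attrition") +
    ggplot2::theme_minimal()
}

#' Plot the cohort distribution of per-role fused proportions
#'
#' @param object a `role_fusion_stats` tibble (ideally after
#'   [frequently_fused()], so the implied flagging threshold is drawn).
#' @param ... unused.
#' @return A ggplot histogram with the flagging threshold, when available.
#' @export
autoplot.role_fusion_stats <- function(object, ...) {
  p <- ggplot2::ggplot(as_tibble(object),
                       ggplot2::aes(x = .data$proportion)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey55") +
    ggplot2::labs(x = "fused proportion of role's genes", y = "roles",
                  title = "Per-role fusion frequency") +
    ggplot2::theme_minimal()
  thr <- attr(object, "threshold")
  if (!is.null(thr) && is.finite(thr)) {
    p <- p + ggplot2::geom_vline(xintercept = thr, linetype = "dashed",
                                 colour = "firebrick")
  }
  p
}

#' Plot fusion counts against genome size
#'
#' @param genome_counts tibble from [genome_fusion_counts()].
#' @return A ggplot scatter with the through-origin least-squares line.
#' @export
plot_genome_proportionality <- function(genome_counts) {
  prop <- genome_proportionality(genome_counts)
  ggplot2::ggplot(genome_counts,
                  ggplot2::aes(x = .data$n_genes, y = .data$n_fused)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = prop$slope, intercept = 0,
                         linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "genes in genome", y = "predicted fusions",
                  title = sprintf("Fusions vs genome size (slope %.3f)",
                                  prop$slope)) +
    ggplot2::theme_minimal()
}
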