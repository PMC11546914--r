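# ggplot2 autoplot methods for the main result objects.

#' Plot inclusion frequencies from a GA search
#'
#' Horizontal bar chart of per-metabolite inclusion frequency over retained
#' combinations, the primary-marker ranking statistic.
#'
#' @param object A `ga_markers` from [ga_search()].
#' @param top_n How many metabolites to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ga_markers
#' @export
autoplot.ga_markers <- function(object, top_n = 20, ...) {
  df <- head(object$inclusion, top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$frequency,
    y = stats::reorder(.data$metabolite, .data$frequency)
  )) +
    ggplot2::geom_col(fill = "#2c7fb8") +
    ggplot2::scale_x_continuous(limits = c(0, 1), expand = c(0, 0.01)) +
    ggplot2::labs(
      x = "inclusion frequency", y = NULL,
      title = "Primary markers: inclusion frequency over GA combinations"
    ) +
    ggplot2::theme_minimal()
}

#' Plot consensus counts from a DAE ensemble
#'
#' Per-metabolite count of autoencoder models flagging it as anomalous, with
#' the selection threshold drawn as a dashed line.
#'
#' @param object A `dae_ensemble` from [run_dae_ensemble()].
#' @param top_n How many metabolites to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dae_ensemble
#' @export
autoplot.dae_ensemble <- function(object, top_n = 30, ...) {
  df <- head(object$consensus, top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$consensus_count,
    y = stats::reorder(.data$metabolite, .data$consensus_count),
    fill = .data$selected
  )) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(
      xintercept = object$config$consensus_min, linetype = "dashed"
    ) +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#d7301f", `FALSE` = "grey60"), guide = "none"
    ) +
    ggplot2::labs(
      x = sprintf("models flagging (of %d)", nrow(object$models)), y = NULL,
      title = "Secondary markers: ensemble consensus"
    ) +
    ggplot2::theme_minimal()
}

#' Plot an over-representation analysis
#'
#' Pathways ordered by significance, bar length `-log10(p)`, filled by FDR
#' significance.
#'
#' @param object An `ora_result` from [ora()].
#' @param fdr_max Highlight threshold (default 0.05).
#' @param top_n How many pathways to show.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ora_result
#' @export
autoplot.ora_result <- function(object, fdr_max = 0.05, top_n = 15, ...) {
  df <- head(object, top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = -log10(.data$p_value),
    y = stats::reorder(.data$pathway_name, -.data$p_value),
    fill = .data$fdr < fdr_max
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(
      values = c(`TRUE` = "#31a354", `FALSE` = "grey60"),
      name = sprintf("FDR < %.2g", fdr_max)
    ) +
    ggplot2::labs(
      x = expression(-log[10](p)), y = NULL,
      title = "Pathway over-representation"
    ) +
    ggplot2::theme_minimal()
}
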