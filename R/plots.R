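# ggplot2 helpers for the main result types.

#' Plot per-block contributions to the outcome
#'
#' Bar chart of squared superweights per latent variable, optionally with
#' bootstrap error bars from [bootstrap_block_importance()].
#'
#' @param importance Tibble from [block_importance()] or
#'   [bootstrap_block_importance()].
#' @return A ggplot object.
#' @export
plot_block_importance <- function(importance) {
  has_sem <- "sem" %in% names(importance)
  val <- if (has_sem) "mean" else "importance"
  df <- importance[!is.na(importance$lv), , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data$lv), y = .data[[val]], fill = .data$block)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.9)) +
    ggplot2::labs(x = "Latent variable", y = "Block importance",
                  fill = "Omics view") +
    ggplot2::theme_minimal()
  if (has_sem) {
    p <- p + ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sem,
                   ymax = .data$mean + .data$sem),
      position = ggplot2::position_dodge(width = 0.9), width = 0.2)
  }
  p
}

#' Plot top pathway importances
#'
#' Horizontal bar chart of the highest-ranked pathways from [mb_vip()],
#' [vip()] or [pathway_importance()].
#'
#' @param importance Importance tibble with a `vip` or `importance` column.
#' @param n_top Number of pathways to show (default 15).
#' @return A ggplot object.
#' @export
plot_importance <- function(importance, n_top = 15) {
  val <- if ("vip" %in% names(importance)) "vip" else "importance"
  idcol <- if ("feature" %in% names(importance)) "feature" else "pathway_id"
  df <- utils::head(importance[order(-importance[[val]]), ], n_top)
  df[[idcol]] <- stats::reorder(df[[idcol]], df[[val]])
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[val]], y = .data[[idcol]])) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = toupper(val), y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a cross-validation curve
#'
#' Mean score with one-standard-error ribbon against the tuned quantity
#' (latent variables from [nested_lv_selection()], or feature count from
#' [rfe_select()]).
#'
#' @param curve Tibble with an x column (`ncomp` or `n_features`) and
#'   `mean_auc` plus `se_auc`/`sd_auc`.
#' @return A ggplot object.
#' @export
plot_cv_curve <- function(curve) {
  xcol <- intersect(c("ncomp", "n_features"), names(curve))[1]
  ecol <- intersect(c("se_auc", "sd_auc"), names(curve))[1]
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data[[xcol]],
                                           y = .data$mean_auc)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = xcol, y = "Mean AUC") +
    ggplot2::theme_minimal()
  if (!is.na(ecol)) {
    p <- p + ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_auc - .data[[ecol]],
                   ymax = .data$mean_auc + .data[[ecol]]),
      alpha = 0.2)
  }
  p
}

#' Heatmap of clustered top-pathway scores
#'
#' Tile heatmap of the restricted score matrix with rows and columns in
#' dendrogram order from [cluster_top_pathways()].
#'
#' @param clustering Output of [cluster_top_pathways()].
#' @return A ggplot object.
#' @export
plot_pathway_heatmap <- function(clustering) {
  m <- clustering$matrix
  df <- tidyr::expand_grid(sample_id = rownames(m),
                           pathway_id = colnames(m))
  df$score <- m[cbind(df$sample_id, df$pathway_id)]
  df$sample_id <- factor(df$sample_id, levels = clustering$sample_order)
  df$pathway_id <- factor(df$pathway_id, levels = clustering$pathway_order)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sample_id,
                                   y = .data$pathway_id,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Activity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
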