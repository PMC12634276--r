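#' Heatmap of a trial similarity matrix
#'
#' @param object A `similarity_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.similarity_matrix <- function(object, ...) {
  n <- nrow(object)
  df <- tidyr::expand_grid(i = seq_len(n), j = seq_len(n))
  df$r <- object[cbind(df$i, df$j)]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "trial", y = "trial", fill = "r",
                  title = attr(object, "condition") %||% "trial similarity") +
    ggplot2::coord_fixed()
}

#' Axial mosaic of a searchlight map
#'
#' @param object A `searchlight_map`.
#' @param slices Which z slices to show (0-based; default every defined
#'   slice).
#' @param ... Unused.
#' @return A ggplot facetted by slice.
#' @exportS3Method ggplot2::autoplot
autoplot.searchlight_map <- function(object, slices = NULL, ...) {
  arr <- unclass(object)
  lin <- which(!is.na(arr))
  co <- arrayInd(lin, dim(arr)) - 1L
  df <- tibble::tibble(x = co[, 1], y = co[, 2], z = co[, 3], r = arr[lin])
  if (is.null(slices)) slices <- sort(unique(df$z))
  df <- df[df$z %in% slices, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~z, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "searchlight trial-pair correlation", fill = "mean r")
}

#' RS distributions by group and condition
#'
#' @param rs_table Tibble with `subject_id`, `condition`, `mean_z` (as the
#'   pipeline's `rs_table`).
#' @param participants Tibble with `subject_id`, `group`.
#' @return A ggplot.
#' @export
plot_rs_by_group <- function(rs_table, participants) {
  df <- dplyr::left_join(rs_table, participants, by = "subject_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$mean_z,
                                   fill = .data$group)) +
    ggplot2::geom_boxplot(outlier.shape = NA, alpha = 0.6,
                          position = ggplot2::position_dodge(width = 0.8)) +
    ggplot2::geom_point(position = ggplot2::position_jitterdodge(
      jitter.width = 0.1, dodge.width = 0.8), size = 1) +
    ggplot2::labs(y = "mean Fisher-z RS", x = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
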