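## Dendrogram segment extraction from an hclust object (x positions follow
## the leaf order, heights are the linkage heights — here mean inter-cluster
## edit distances).
hclust_segments <- function(hc) {
  n <- length(hc$order)
  leaf_x <- stats::setNames(seq_len(n), hc$order)
  node_x <- numeric(nrow(hc$merge))
  node_h <- hc$height
  seg <- vector("list", nrow(hc$merge))
  pos <- function(id) {
    if (id < 0) c(x = unname(leaf_x[as.character(-id)]), h = 0) else
      c(x = node_x[id], h = node_h[id])
  }
  for (i in seq_len(nrow(hc$merge))) {
    a <- pos(hc$merge[i, 1])
    b <- pos(hc$merge[i, 2])
    node_x[i] <- mean(c(a["x"], b["x"]))
    seg[[i]] <- tibble::tibble(
      x = c(a["x"], b["x"], a["x"]),
      xend = c(a["x"], b["x"], b["x"]),
      y = c(a["h"], b["h"], node_h[i]),
      yend = c(node_h[i], node_h[i], node_h[i])
    )
  }
  dplyr::bind_rows(seg)
}

#' Plot a variant grouping dendrogram
#'
#' Dendrogram of the Levenshtein-distance clustering with leaves coloured by
#' sequence group; the y axis is the linkage height (edit distance).
#'
#' @param object A [cluster_variants()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @importFrom ggplot2 autoplot
#' @method autoplot hyb_grouping
#' @export
autoplot.hyb_grouping <- function(object, ...) {
  hc <- object$hclust
  seg <- hclust_segments(hc)
  leaves <- tibble::tibble(
    x = seq_along(hc$order),
    name = hc$labels[hc$order]
  ) |>
    dplyr::left_join(object$groups, by = "name")
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y,
                   yend = .data$yend),
      linewidth = 0.4
    ) +
    ggplot2::geom_text(
      data = leaves,
      ggplot2::aes(x = .data$x, y = -0.5, label = .data$name,
                   colour = .data$group),
      angle = 90, hjust = 1, size = 3
    ) +
    ggplot2::scale_y_continuous("edit distance (linkage height)") +
    ggplot2::expand_limits(y = -max(hc$height) * 0.35) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   axis.title.x = ggplot2::element_blank(),
                   panel.grid.major.x = ggplot2::element_blank())
}

#' Plot screen stage counts
#'
#' Bar chart of the pipeline stage counts (log scale), from windows through
#' the core-domain filter.
#'
#' @param object A [run_screen()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot hyb_screen
#' @export
autoplot.hyb_screen <- function(object, ...) {
  df <- dplyr::mutate(object$summary,
                      stage = factor(.data$stage, levels = .data$stage))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stage, y = pmax(.data$count, 0.5))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = format(.data$count,
                                                   big.mark = ",")),
                       vjust = -0.4, size = 3) +
    ggplot2::scale_y_log10("count (log scale)") +
    ggplot2::labs(x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot genome category fractions or peak proportions
#'
#' @param fractions Tibble from [genome_category_fractions()] or
#'   [classify_peak_regions()].
#' @return A ggplot object.
#' @export
plot_category_fractions <- function(fractions) {
  value <- if ("fraction" %in% names(fractions)) "fraction" else "proportion"
  ggplot2::ggplot(fractions,
                  ggplot2::aes(x = .data$category, y = .data[[value]])) +
    ggplot2::geom_col(fill = "grey40") +
    ggplot2::labs(x = NULL, y = paste0(value, " (%)")) +
    ggplot2::theme_minimal()
}
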