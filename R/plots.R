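#' Plot group decoding accuracies by ROI and scheme
#'
#' Bars of group-mean accuracy per ROI, faceted by scheme, with the chance
#' level drawn as a dashed line. Input is the tidy table from
#' [decode_cohort()].
#'
#' @param accuracy A tibble with columns `roi`, `network`, `scheme`,
#'   `accuracy`, `chance`.
#' @return A ggplot object.
#' @export
plot_accuracy <- function(accuracy) {
  summ <- dplyr::summarise(
    dplyr::group_by(accuracy, .data$roi, .data$network, .data$scheme, .data$chance),
    mean_accuracy = mean(.data$accuracy),
    se = stats::sd(.data$accuracy) / sqrt(dplyr::n()),
    .groups = "drop"
  )
  ggplot2::ggplot(
    summ,
    ggplot2::aes(x = .data$roi, y = .data$mean_accuracy, fill = .data$network)
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(
      ggplot2::aes(
        ymin = .data$mean_accuracy - .data$se,
        ymax = .data$mean_accuracy + .data$se
      ),
      width = 0.3
    ) +
    ggplot2::geom_hline(
      ggplot2::aes(yintercept = .data$chance),
      linetype = "dashed"
    ) +
    ggplot2::facet_wrap(~scheme) +
    ggplot2::labs(x = NULL, y = "decoding accuracy", fill = "network") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @method autoplot similarity_matrix
#' @export
autoplot.similarity_matrix <- function(object, ...) {
  m <- unclass(object)
  d <- tidyr::expand_grid(
    row = factor(rownames(m), levels = rownames(m)),
    col = factor(colnames(m), levels = colnames(m))
  )
  d$value <- as.vector(t(m))
  ggplot2::ggplot(d, ggplot2::aes(.data$col, .data$row, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "darkblue", mid = "white", high = "darkred", midpoint = 0
    ) +
    ggplot2::labs(x = NULL, y = NULL, fill = "r") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @method autoplot joint_delta
#' @export
autoplot.joint_delta <- function(object, ...) {
  d <- tidy.joint_delta(object)
  ggplot2::ggplot(
    d,
    ggplot2::aes(x = .data$added, y = .data$original, fill = .data$delta)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(
      low = "#3b0a63", mid = "white", high = "red", midpoint = 0
    ) +
    ggplot2::labs(
      x = "added ROI", y = "original ROI",
      fill = expression(Delta ~ "accuracy")
    ) +
    ggplot2::theme_minimal()
}

#' @method autoplot mvpa_dendrogram
#' @export
autoplot.mvpa_dendrogram <- function(object, ...) {
  hc <- object$hclust
  n <- length(hc$labels)
  # leaf x-positions in plotting order; internal-node coordinates by merge
  leaf_x <- numeric(n)
  leaf_x[hc$order] <- seq_len(n)
  node_x <- numeric(nrow(hc$merge))
  node_h <- hc$height
  seg <- list()
  get_x <- function(id) if (id < 0) leaf_x[-id] else node_x[id]
  get_h <- function(id) if (id < 0) 0 else node_h[id]
  for (i in seq_len(nrow(hc$merge))) {
    a <- hc$merge[i, 1]
    b <- hc$merge[i, 2]
    xa <- get_x(a)
    xb <- get_x(b)
    node_x[i] <- (xa + xb) / 2
    seg[[length(seg) + 1]] <- data.frame(
      x = c(xa, xa, xb), xend = c(xa, xb, xb),
      y = c(get_h(a), node_h[i], node_h[i]),
      yend = c(node_h[i], node_h[i], get_h(b))
    )
  }
  seg <- dplyr::bind_rows(seg)
  labs <- data.frame(x = seq_len(n), label = hc$labels[hc$order])
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, xend = .data$xend, y = .data$y, yend = .data$yend)
    ) +
    ggplot2::geom_text(
      data = labs,
      ggplot2::aes(x = .data$x, y = 0, label = .data$label),
      angle = 90, hjust = 1.1, size = 3
    ) +
    ggplot2::scale_y_continuous(expand = ggplot2::expansion(mult = c(0.35, 0.05))) +
    ggplot2::labs(x = NULL, y = "merge height (distance)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(
      axis.text.x = ggplot2::element_blank(),
      panel.grid.major.x = ggplot2::element_blank()
    )
}

#' @method autoplot mvpa_accuracy_map
#' @export
autoplot.mvpa_accuracy_map <- function(object, ...) {
  dim3 <- dim(object$values)
  d <- tidyr::expand_grid(x = seq_len(dim3[1]), y = seq_len(dim3[2]), z = seq_len(dim3[3]))
  d$accuracy <- as.vector(object$values[cbind(d$x, d$y, d$z)])
  d <- d[!is.na(d$accuracy), ]
  ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~z, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "accuracy") +
    ggplot2::theme_minimal()
}
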