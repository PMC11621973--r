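#' Bar chart of a ranked dominance hierarchy
#'
#' One bar per individual, ordered by rank, bar height = normalised
#' David's score; fill encodes sex when a roster is supplied.
#'
#' @param object a [davids_scores()] (optionally [rank_hierarchy()]-ed)
#'   table.
#' @param roster optional roster tibble with `id` and `sex`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot davids_score_table
#' @export
autoplot.davids_score_table <- function(object, roster = NULL, ...) {
  df <- tibble::as_tibble(object)
  df <- df[order(-df$norm_ds), ]
  df$id <- factor(df$id, levels = df$id)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$id, y = .data$norm_ds))
  if (!is.null(roster)) {
    df <- dplyr::left_join(df, dplyr::select(roster, "id", "sex"), by = "id")
    p <- ggplot2::ggplot(
      df,
      ggplot2::aes(x = .data$id, y = .data$norm_ds, fill = .data$sex)
    ) +
      ggplot2::scale_fill_manual(
        values = c(female = "white", male = "black", unknown = "grey60")
      )
  }
  p +
    ggplot2::geom_col(colour = "black") +
    ggplot2::labs(
      x = "individual", y = "normalised David's score",
      title = "Dominance hierarchy"
    ) +
    ggplot2::theme_minimal()
}

#' Stem plot of an autocorrelation result
#'
#' Lags on the x-axis, autocorrelation on the y-axis, with the approximate
#' white-noise band at +/- 2/sqrt(n).
#'
#' @param object an [autocorrelation()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot acf_result
#' @export
autoplot.acf_result <- function(object, ...) {
  band <- 2 / sqrt(attr(object, "n"))
  ggplot2::ggplot(object, ggplot2::aes(x = .data$lag, y = .data$r)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey40") +
    ggplot2::geom_hline(
      yintercept = c(-band, band),
      linetype = "dashed", colour = "steelblue"
    ) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$lag, yend = 0)) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "lag", y = "autocorrelation",
      title = "Temporal independence of recordings"
    ) +
    ggplot2::theme_minimal()
}

#' Sociogram of a weighted association network
#'
#' Nodes are placed on a circle (or by classical multidimensional scaling
#' of association dissimilarities when `layout = "mds"`); edge width is
#' proportional to association weight, node colour encodes community when
#' a partition is supplied.
#'
#' @param object a [social_network()].
#' @param partition optional [fast_greedy_partition()] result.
#' @param scores optional [eigenvector_centrality()] tibble (node size).
#' @param layout `"circle"` or `"mds"`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot social_network
#' @export
autoplot.social_network <- function(object, partition = NULL, scores = NULL,
                                    layout = c("circle", "mds"), ...) {
  layout <- match.arg(layout)
  ids <- object$ids
  k <- length(ids)
  if (layout == "circle" || k < 3) {
    theta <- 2 * pi * (seq_len(k) - 1) / k
    pos <- tibble::tibble(id = ids, x = cos(theta), y = sin(theta))
  } else {
    w <- object$weights
    d <- max(w) - w
    diag(d) <- 0
    xy <- stats::cmdscale(stats::as.dist(d), k = 2)
    pos <- tibble::tibble(id = ids, x = xy[, 1], y = xy[, 2])
  }
  edges <- tidy.social_network(object) |>
    dplyr::left_join(dplyr::rename(pos, x0 = "x", y0 = "y"),
      by = c(from = "id")
    ) |>
    dplyr::left_join(dplyr::rename(pos, x1 = "x", y1 = "y"),
      by = c(to = "id")
    )
  nodes <- pos
  if (!is.null(partition)) {
    nodes <- dplyr::left_join(nodes, tidy.community_partition(partition),
      by = "id"
    )
  }
  if (!is.null(scores)) {
    nodes <- dplyr::left_join(nodes, scores, by = "id")
  }
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(
        x = .data$x0, y = .data$y0, xend = .data$x1, yend = .data$y1,
        linewidth = .data$weight
      ),
      colour = "grey55"
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 2.5))
  p <- p + if (!is.null(partition) && !is.null(scores)) {
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(
        x = .data$x, y = .data$y,
        colour = .data$community, size = .data$centrality
      )
    )
  } else if (!is.null(partition)) {
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$community),
      size = 4
    )
  } else {
    ggplot2::geom_point(
      data = nodes, ggplot2::aes(x = .data$x, y = .data$y), size = 4
    )
  }
  p +
    ggplot2::geom_text(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$id),
      vjust = -1.2
    ) +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Association sociogram")
}

#' Bar chart of eigenvector centrality scores
#'
#' @param object an [eigenvector_centrality()] tibble.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot centrality_scores
#' @export
autoplot.centrality_scores <- function(object, ...) {
  df <- object[order(-object$centrality), ]
  df$id <- factor(df$id, levels = df$id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$id, y = .data$centrality)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(
      x = "individual", y = "eigenvector centrality",
      title = "Network centrality"
    ) +
    ggplot2::theme_minimal()
}
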