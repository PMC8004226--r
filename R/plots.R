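# ggplot2 graphics for the main result types: descriptor distributions,
# elbow curves, silhouette profiles, PCA chemical-space maps, and the
# compound-target network.

#' Side-by-side descriptor distributions of two libraries
#'
#' Faceted histograms (free scales) of the shared numeric descriptors,
#' the graphical counterpart of [distribution_report()].
#'
#' @param a,b Descriptor tibbles.
#' @param labels Names for the two libraries.
#' @param bins Histogram bins.
#' @return A ggplot object.
#' @export
plot_descriptor_distributions <- function(a, b,
                                          labels = c("library A",
                                                     "library B"),
                                          bins = 20) {
  num <- function(d) names(d)[vapply(d, is.numeric, logical(1))]
  shared <- intersect(num(tibble::as_tibble(a)), num(tibble::as_tibble(b)))
  if (length(shared) == 0) stop("no shared numeric columns", call. = FALSE)
  long <- dplyr::bind_rows(
    tidyr::pivot_longer(dplyr::mutate(tibble::as_tibble(a)[shared],
                                      library = labels[1]),
                        -"library", names_to = "descriptor"),
    tidyr::pivot_longer(dplyr::mutate(tibble::as_tibble(b)[shared],
                                      library = labels[2]),
                        -"library", names_to = "descriptor")
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$value,
                                     fill = .data$library)) +
    ggplot2::geom_histogram(bins = bins, position = "identity",
                            alpha = 0.55) +
    ggplot2::facet_wrap(~descriptor, scales = "free") +
    ggplot2::labs(x = NULL, y = "count", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Elbow plot of a WSS curve
#'
#' @param curve Tibble `k`, `wss` (from [wss_curve()]).
#' @param chosen Optional k to mark (e.g. the [elbow_k()] choice).
#' @return A ggplot object.
#' @export
plot_wss_curve <- function(curve, chosen = NULL) {
  p <- ggplot2::ggplot(curve, ggplot2::aes(x = .data$k, y = .data$wss)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "number of clusters k",
                  y = "within-cluster sum of squares") +
    ggplot2::theme_minimal()
  if (!is.null(chosen)) {
    p <- p + ggplot2::geom_vline(xintercept = chosen, linetype = "dashed")
  }
  p
}

#' Silhouette profile of a partition
#'
#' @param sil Output of [silhouette_scores()].
#' @return A ggplot object.
#' @export
plot_silhouette <- function(sil) {
  sil <- dplyr::arrange(sil, .data$cluster, dplyr::desc(.data$silhouette))
  sil$pos <- seq_len(nrow(sil))
  ggplot2::ggplot(sil, ggplot2::aes(x = .data$pos, y = .data$silhouette,
                                    fill = factor(.data$cluster))) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = attr(sil, "silhouette_mean") %||%
                          mean(sil$silhouette), linetype = "dashed") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "silhouette width", fill = "cluster") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Chemical-space map from a PCA
#'
#' @param object A `seno_pca`.
#' @param labels Optional cluster labels to colour by (tibble or vector).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.seno_pca <- function(object, labels = NULL, ...) {
  sc <- object$scores
  pcs <- setdiff(names(sc), "compound_id")[1:2]
  if (!is.null(labels)) {
    if (inherits(labels, "seno_clustering")) labels <- labels$labels
    if (is.data.frame(labels)) {
      sc <- dplyr::left_join(sc, labels, by = "compound_id")
    } else {
      sc$cluster <- labels[sc$compound_id]
    }
    aes <- ggplot2::aes(x = .data[[pcs[1]]], y = .data[[pcs[2]]],
                        colour = factor(.data$cluster))
  } else {
    aes <- ggplot2::aes(x = .data[[pcs[1]]], y = .data[[pcs[2]]])
  }
  ev <- 100 * object$explained_variance[1:2]
  ggplot2::ggplot(sc, aes) +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("%s (%.1f%%)", pcs[1], ev[1]),
      y = sprintf("%s (%.1f%%)", pcs[2], ev[2]),
      colour = "cluster"
    ) +
    ggplot2::theme_minimal()
}

#' Plot a compound-target network
#'
#' Simple force-directed layout with compound and target nodes
#' distinguished; pathway-annotated targets are highlighted.
#'
#' @param object A `seno_network`.
#' @param seed Layout seed.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.seno_network <- function(object, seed = 1, ...) {
  xy <- withr::with_seed(seed,
                         igraph::layout_with_fr(object$graph))
  nodes <- object$nodes
  nodes$x <- xy[, 1]; nodes$y <- xy[, 2]
  nodes$class <- ifelse(nodes$kind == "compound", "compound",
                        ifelse(nodes$pathways != "", "senescence target",
                               "target"))
  idx <- stats::setNames(seq_len(nrow(nodes)), nodes$id)
  seg <- tibble::tibble(
    x = nodes$x[idx[object$edges$compound_id]],
    y = nodes$y[idx[object$edges$compound_id]],
    xend = nodes$x[idx[object$edges$target_symbol]],
    yend = nodes$y[idx[object$edges$target_symbol]]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = seg,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend,
                                       yend = .data$yend),
                          colour = "grey70") +
    ggplot2::geom_point(data = nodes,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$class,
                                     shape = .data$class), size = 3) +
    ggplot2::theme_void() +
    ggplot2::labs(colour = NULL, shape = NULL)
}
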