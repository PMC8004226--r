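# broom-style tidiers for the package's fitted/derived objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a clustering result
#'
#' @param x A `seno_clustering`.
#' @param ... Unused.
#' @return Tibble `compound_id`, `cluster`.
#' @export
tidy.seno_clustering <- function(x, ...) {
  x$labels
}

#' One-row summary of a clustering result
#'
#' @param x A `seno_clustering`.
#' @param d Optional distance matrix; when given, mean silhouette and Dunn
#'   index are included.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.seno_clustering <- function(x, d = NULL, ...) {
  out <- tibble::tibble(method = x$method, k = x$k, n = nrow(x$labels),
                        wss = if (!is.null(x$wss)) x$wss else NA_real_)
  if (!is.null(d) && x$k >= 2) {
    out$silhouette_mean <- silhouette_mean(d, x)
    out$dunn <- dunn_index(d, x)
  }
  out
}

#' Tidy a PCA of descriptor space
#'
#' @param x A `seno_pca`.
#' @param matrix `"scores"` (per-compound coordinates) or `"loadings"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.seno_pca <- function(x, matrix = c("scores", "loadings"), ...) {
  matrix <- match.arg(matrix)
  if (matrix == "scores") return(x$scores)
  tibble::as_tibble(x$loadings, rownames = "descriptor")
}

#' One-row summary of a PCA
#'
#' @param x A `seno_pca`.
#' @param ... Unused.
#' @return A one-row tibble with per-component explained-variance fractions.
#' @export
glance.seno_pca <- function(x, ...) {
  ev <- x$explained_variance
  out <- tibble::as_tibble(as.list(stats::setNames(
    ev, paste0("var_pc", seq_along(ev)))))
  out$n_components <- length(ev)
  out
}

#' Tidy a compound-target network
#'
#' @param x A `seno_network`.
#' @param what `"edges"` or `"nodes"`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.seno_network <- function(x, what = c("edges", "nodes"), ...) {
  what <- match.arg(what)
  if (what == "edges") x$edges else x$nodes
}

#' One-row summary of a compound-target network
#'
#' @param x A `seno_network`.
#' @param ... Unused.
#' @return Tibble with node/edge counts.
#' @export
glance.seno_network <- function(x, ...) {
  tibble::tibble(
    n_nodes = nrow(x$nodes),
    n_compounds = sum(x$nodes$kind == "compound"),
    n_targets = sum(x$nodes$kind == "target"),
    n_edges = nrow(x$edges),
    n_annotated_targets = sum(x$nodes$kind == "target" &
                                x$nodes$pathways != "")
  )
}
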