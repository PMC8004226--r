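# Phase 1: cluster the senolytic descriptor matrix, visualize chemical space
# by PCA, and extract the lead cluster containing the anchor compounds.

#' Principal component analysis of a descriptor table
#'
#' PCA of the (already standardized) descriptor table: components are
#' eigenvectors of the covariance matrix ordered by decreasing variance.
#' Sign convention: within each component the largest-magnitude loading is
#' made positive, so scores are reproducible across platforms.
#'
#' @param descriptors Standardized descriptor tibble
#'   (see [standardize_descriptors()]).
#' @param n_components Number of components to keep; truncated with a
#'   warning if it exceeds the rank `min(n_rows - 1, n_cols)`.
#' @return A `seno_pca` object: `loadings` (columns = components),
#'   `explained_variance` (fractions), `scores` tibble.
#' @export
pca_descriptors <- function(descriptors, n_components = 2) {
  x <- .descriptor_matrix(descriptors)
  rank_max <- min(nrow(x) - 1L, ncol(x))
  if (n_components > rank_max) {
    warning("n_components truncated to the rank bound ", rank_max,
            call. = FALSE)
    n_components <- rank_max
  }
  p <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  var_frac <- p$sdev^2 / sum(p$sdev^2)
  keep <- seq_len(n_components)
  load <- p$rotation[, keep, drop = FALSE]
  scores <- p$x[, keep, drop = FALSE]
  for (j in seq_len(ncol(load))) {
    if (load[which.max(abs(load[, j])), j] < 0) {
      load[, j] <- -load[, j]
      scores[, j] <- -scores[, j]
    }
  }
  structure(
    list(
      loadings = load,
      explained_variance = var_frac[keep],
      all_variances = p$sdev^2,
      scores = tibble::as_tibble(scores) |>
        dplyr::mutate(compound_id = rownames(x), .before = 1),
      center = p$center
    ),
    class = "seno_pca"
  )
}

#' @export
print.seno_pca <- function(x, ...) {
  cat("<seno_pca> ", ncol(x$loadings), " components, explained variance: ",
      paste(sprintf("%.1f%%", 100 * x$explained_variance), collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Select the lead cluster from a descriptor table
#'
#' Clusters the standardized descriptors with both K-means and Ward (same k,
#' Euclidean distances) and returns the members of the K-means cluster
#' holding the majority of the anchor compounds, together with the agreement
#' fraction between the two methods. Errors if the anchors split evenly
#' across clusters, which demands an explicit choice.
#'
#' @param descriptors Descriptor tibble (standardized internally if not
#'   already).
#' @param k Number of clusters (default 2: separates the two broad families
#'   of senolytic chemotypes).
#' @param anchor_ids Compound ids known to sit in the lead cluster.
#' @param seed Seed for the K-means restarts.
#' @param standardize Standardize the table first (default TRUE).
#' @return A tibble of lead compound ids (`compound_id`), with attributes
#'   `cluster` (index), `agreement` (K-means vs Ward label agreement),
#'   `kmeans`, `ward` (the two `seno_clustering` objects).
#' @export
select_lead_cluster <- function(descriptors, k = 2, anchor_ids, seed = 1,
                                standardize = TRUE) {
  d <- tibble::as_tibble(descriptors)
  if (standardize) d <- suppressWarnings(standardize_descriptors(d))
  x <- .descriptor_matrix(d)
  if (k == 1) {
    warning("k = 1: every compound is in the lead set", call. = FALSE)
    return(structure(tibble::tibble(compound_id = rownames(x)),
                     cluster = 1L, agreement = 1))
  }
  km <- kmeans_cluster(x, k, seed = seed)
  wd <- ward_cluster(as.matrix(stats::dist(x)), k)
  agreement <- partition_agreement(km, wd)

  missing <- setdiff(anchor_ids, rownames(x))
  if (length(missing) > 0) {
    stop("anchor ids absent from the descriptor table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  lv <- stats::setNames(km$labels$cluster, km$labels$compound_id)
  votes <- table(lv[anchor_ids])
  top <- votes[votes == max(votes)]
  if (length(top) > 1) {
    stop("anchors split evenly across clusters (",
         paste(names(top), collapse = " vs "),
         "); choose the lead cluster explicitly", call. = FALSE)
  }
  lead_cluster <- as.integer(names(top)[1])
  out <- tibble::tibble(
    compound_id = km$labels$compound_id[km$labels$cluster == lead_cluster]
  )
  attr(out, "cluster") <- lead_cluster
  attr(out, "agreement") <- agreement
  attr(out, "kmeans") <- km
  attr(out, "ward") <- wd
  out
}

#' Per-compound cluster affinity
#'
#' How well each compound sits in its assigned cluster, reported as the
#' per-point silhouette width under the given partition (Euclidean distances
#' on the standardized descriptors). Values near 1 mean the compound is
#' central to its cluster; near 0, equidistant between clusters.
#'
#' @param descriptors Descriptor tibble.
#' @param labels Cluster labels (tibble, named vector, or `seno_clustering`).
#' @param standardize Standardize the table first (default TRUE).
#' @return Tibble `compound_id`, `cluster`, `affinity` in `[-1, 1]`.
#' @export
cluster_affinity <- function(descriptors, labels, standardize = TRUE) {
  d <- tibble::as_tibble(descriptors)
  if (standardize) d <- suppressWarnings(standardize_descriptors(d))
  x <- .descriptor_matrix(d)
  sil <- silhouette_scores(as.matrix(stats::dist(x)), labels)
  dplyr::rename(sil, affinity = "silhouette")
}
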