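# Clustering and cluster-validity machinery shared by the descriptor-space
# lead selection and the fingerprint-space similarity screen.
#
# Conventions pinned here:
#  * Ward on a precomputed distance matrix squares the input distances
#    internally (stats::hclust "ward.D2"), so plain Euclidean or Jaccard
#    distances are passed in unsquared.
#  * K-means = Lloyd iterations from k-means++ initialization, best of
#    `restarts` by within-cluster sum of squares, reproducible via `seed`.
#  * Silhouette of a singleton cluster is 0.

# accept labels as a named vector or a tibble(compound_id, cluster); return a
# named integer vector aligned with the distance matrix ids
.labels_vec <- function(labels, ids) {
  if (is.data.frame(labels)) {
    labels <- stats::setNames(labels$cluster, labels$compound_id)
  }
  if (is.null(names(labels))) {
    stopifnot(length(labels) == length(ids))
    names(labels) <- ids
  }
  out <- labels[ids]
  if (anyNA(out)) stop("labels missing for some ids", call. = FALSE)
  stats::setNames(as.integer(out), ids)
}

.check_dist <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 2)
  if (max(abs(d - t(d))) > 1e-12) stop("distance matrix not symmetric",
                                       call. = FALSE)
  if (any(diag(d) != 0)) stop("distance matrix diagonal must be zero",
                              call. = FALSE)
  if (is.null(rownames(d))) {
    rownames(d) <- colnames(d) <- as.character(seq_len(nrow(d)))
  }
  d
}

#' Ward hierarchical clustering of a distance matrix
#'
#' Agglomerative minimum-variance (Ward) clustering; labels come from
#' cutting the merge tree at `k` clusters. Deterministic for a fixed
#' distance matrix.
#'
#' @param d Symmetric distance matrix with id dimnames.
#' @param k Number of clusters, `1 <= k <= n`.
#' @return A `seno_clustering` object: labels tibble, `k`, merge tree and
#'   non-decreasing merge heights.
#' @export
ward_cluster <- function(d, k) {
  d <- .check_dist(d)
  n <- nrow(d)
  if (k < 1 || k > n) stop("k must be between 1 and n = ", n, call. = FALSE)
  hc <- stats::hclust(stats::as.dist(d), method = "ward.D2")
  labs <- stats::cutree(hc, k = k)
  structure(
    list(
      labels = tibble::tibble(compound_id = rownames(d),
                              cluster = as.integer(labs[rownames(d)])),
      k = as.integer(k), method = "ward",
      merge = hc$merge, height = hc$height, order = hc$order,
      hclust = hc
    ),
    class = "seno_clustering"
  )
}

# k-means++ center selection (Arthur & Vassilvitskii 2007)
.kmeanspp_centers <- function(x, k) {
  n <- nrow(x)
  centers <- integer(k)
  centers[1] <- sample.int(n, 1)
  if (k > 1) {
    d2 <- rowSums((x - matrix(x[centers[1], ], n, ncol(x),
                              byrow = TRUE))^2)
    for (j in 2:k) {
      prob <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
      centers[j] <- sample.int(n, 1, prob = prob)
      d2 <- pmin(d2, rowSums((x - matrix(x[centers[j], ], n, ncol(x),
                                         byrow = TRUE))^2))
    }
  }
  x[centers, , drop = FALSE]
}

#' K-means clustering of a descriptor table
#'
#' Lloyd iterations from k-means++ starts; the best of `restarts` runs by
#' total within-cluster sum of squares is returned. Reproducible given
#' `seed`.
#'
#' @param x Descriptor tibble (numeric columns + optional `compound_id`) or
#'   numeric matrix with row names.
#' @param k Number of clusters.
#' @param seed Integer seed.
#' @param restarts Number of independent starts (default 10).
#' @return A `seno_clustering` object with a `wss` component.
#' @export
kmeans_cluster <- function(x, k, seed = 1, restarts = 10) {
  if (is.data.frame(x)) x <- .descriptor_matrix(x)
  stopifnot(is.matrix(x))
  n <- nrow(x)
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (k > n) stop("k cannot exceed the number of rows", call. = FALSE)
  if (is.null(rownames(x))) rownames(x) <- as.character(seq_len(n))

  fit <- withr::with_seed(seed, {
    best <- NULL
    for (r in seq_len(restarts)) {
      init <- .kmeanspp_centers(x, k)
      # duplicate initial centers would abort kmeans(); jitterless fallback
      if (anyDuplicated(init)) {
        init <- init + stats::rnorm(length(init), sd = 1e-8)
      }
      km <- suppressWarnings(
        stats::kmeans(x, centers = init, iter.max = 300,
                      algorithm = "Lloyd")
      )
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
    best
  })
  structure(
    list(
      labels = tibble::tibble(compound_id = rownames(x),
                              cluster = as.integer(fit$cluster)),
      k = as.integer(k), method = "kmeans",
      wss = fit$tot.withinss, centers = fit$centers
    ),
    class = "seno_clustering"
  )
}

#' @export
print.seno_clustering <- function(x, ...) {
  sizes <- table(x$labels$cluster)
  cat("<seno_clustering> ", x$method, ", k = ", x$k, ", n = ",
      nrow(x$labels), "\n", sep = "")
  cat("  cluster sizes:", paste(sizes, collapse = ", "), "\n")
  if (!is.null(x$wss)) cat("  total within-cluster SS:",
                           format(x$wss, digits = 6), "\n")
  invisible(x)
}

#' Per-point silhouette widths
#'
#' `s_i = (b_i - a_i) / max(a_i, b_i)` with `a_i` the mean distance of point
#' i to its own cluster (excluding itself) and `b_i` the smallest mean
#' distance to any other cluster. Points in singleton clusters get 0.
#'
#' @param d Distance matrix.
#' @param labels Cluster labels (named vector, tibble, or `seno_clustering`).
#' @return A tibble `compound_id`, `cluster`, `silhouette`; attribute
#'   `silhouette_mean` is the arithmetic mean over points.
#' @export
silhouette_scores <- function(d, labels) {
  d <- .check_dist(d)
  if (inherits(labels, "seno_clustering")) labels <- labels$labels
  lv <- .labels_vec(labels, rownames(d))
  ks <- sort(unique(lv))
  if (length(ks) < 2) stop("silhouette needs at least 2 clusters",
                           call. = FALSE)
  n <- nrow(d)
  sizes <- table(lv)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- lv[i]
    if (sizes[[as.character(own)]] == 1L) { s[i] <- 0; next }
    a_i <- sum(d[i, lv == own]) / (sizes[[as.character(own)]] - 1L)
    b_i <- min(vapply(setdiff(ks, own), function(kk) {
      mean(d[i, lv == kk])
    }, numeric(1)))
    s[i] <- (b_i - a_i) / max(a_i, b_i)
  }
  out <- tibble::tibble(compound_id = rownames(d),
                        cluster = unname(lv), silhouette = s)
  attr(out, "silhouette_mean") <- mean(s)
  out
}

#' Mean silhouette of a partition
#'
#' @inheritParams silhouette_scores
#' @return The arithmetic mean of the per-point silhouette widths.
#' @export
silhouette_mean <- function(d, labels) {
  attr(silhouette_scores(d, labels), "silhouette_mean")
}

#' Dunn index of a partition
#'
#' Minimum between-cluster point-pair distance divided by the maximum
#' within-cluster diameter. If every cluster has zero diameter the index is
#' `+Inf`.
#'
#' @inheritParams silhouette_scores
#' @return A non-negative scalar (possibly `Inf`).
#' @export
dunn_index <- function(d, labels) {
  d <- .check_dist(d)
  if (inherits(labels, "seno_clustering")) labels <- labels$labels
  lv <- .labels_vec(labels, rownames(d))
  ks <- sort(unique(lv))
  if (length(ks) < 2) stop("Dunn index needs at least 2 clusters",
                           call. = FALSE)
  same <- outer(lv, lv, "==")
  off <- upper.tri(d)
  between <- d[off][!same[off]]
  within <- d[off][same[off]]
  min_between <- if (length(between)) min(between) else Inf
  max_within <- if (length(within)) max(within) else 0
  if (max_within == 0) return(Inf)
  min_between / max_within
}

#' Distance-based within-cluster sum of squares
#'
#' For each cluster, the sum of squared pairwise distances divided by twice
#' the cluster size; for Euclidean distances this equals the centroid-based
#' within-cluster sum of squares, and it generalizes the elbow curve to
#' fingerprint (Jaccard) distance matrices.
#'
#' @inheritParams silhouette_scores
#' @return Total WSS (scalar).
#' @export
partition_wss <- function(d, labels) {
  d <- .check_dist(d)
  if (inherits(labels, "seno_clustering")) labels <- labels$labels
  lv <- .labels_vec(labels, rownames(d))
  sum(vapply(unique(lv), function(kk) {
    idx <- which(lv == kk)
    if (length(idx) < 2) return(0)
    sum(d[idx, idx]^2) / (2 * length(idx))
  }, numeric(1)))
}

#' Elbow curve over k for Ward partitions of a distance matrix
#'
#' @param d Distance matrix.
#' @param k_range Contiguous integer range of cluster counts.
#' @return A tibble `k`, `wss`.
#' @export
wss_curve <- function(d, k_range = 1:8) {
  d <- .check_dist(d)
  k_range <- k_range[k_range <= nrow(d)]
  tibble::tibble(
    k = as.integer(k_range),
    wss = vapply(k_range, function(k) {
      if (k == 1) {
        partition_wss(d, stats::setNames(rep(1L, nrow(d)), rownames(d)))
      } else {
        partition_wss(d, ward_cluster(d, k))
      }
    }, numeric(1))
  )
}

#' Elbow method: pick k at maximum curvature of the WSS curve
#'
#' Returns the interior k maximizing the second difference
#' `(wss[k-1] - wss[k]) - (wss[k] - wss[k+1])`; ties break toward smaller k.
#' A non-monotone curve triggers a warning but still yields an answer.
#'
#' @param curve A tibble/data.frame with columns `k` and `wss`, covering a
#'   contiguous range of at least 3 values of k.
#' @return The chosen integer k.
#' @export
elbow_k <- function(curve) {
  curve <- curve[order(curve$k), ]
  k <- curve$k; w <- curve$wss
  if (length(k) < 3) stop("elbow needs wss for at least 3 contiguous k",
                          call. = FALSE)
  if (any(diff(k) != 1)) stop("k range must be contiguous", call. = FALSE)
  if (any(diff(w) > 0)) {
    warning("WSS curve is not monotone non-increasing", call. = FALSE)
  }
  interior <- 2:(length(k) - 1)
  second_diff <- (w[interior - 1] - w[interior]) -
    (w[interior] - w[interior + 1])
  as.integer(k[interior[which.max(second_diff)]])
}

#' Agreement between two partitions
#'
#' Fraction of points on which two labelings agree under the best one-to-one
#' matching of cluster indices (maximum-overlap greedy matching; exact for
#' two clusters).
#'
#' @param labels_a,labels_b Labels (vectors, tibbles, or `seno_clustering`).
#' @return Agreement fraction in `[0, 1]`.
#' @export
partition_agreement <- function(labels_a, labels_b) {
  if (inherits(labels_a, "seno_clustering")) labels_a <- labels_a$labels
  if (inherits(labels_b, "seno_clustering")) labels_b <- labels_b$labels
  a <- stats::setNames(labels_a$cluster, labels_a$compound_id)
  b <- stats::setNames(labels_b$cluster, labels_b$compound_id)
  ids <- intersect(names(a), names(b))
  a <- a[ids]; b <- b[ids]
  tab <- table(a, b)
  agree <- 0
  while (length(tab) > 0 && nrow(tab) > 0 && ncol(tab) > 0) {
    best <- which(tab == max(tab), arr.ind = TRUE)[1, ]
    agree <- agree + tab[best[1], best[2]]
    tab <- tab[-best[1], -best[2], drop = FALSE]
  }
  as.numeric(agree) / length(ids)
}
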