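# Independent oracle implementations used to check the package's numerics.
# Each is a direct, naive transcription of the defining formula, kept
# deliberately separate from the implementation under test.

# silhouette widths by the raw formula, double loop
oracle_silhouette <- function(d, labels) {
  ids <- rownames(d)
  lv <- labels[ids]
  vapply(seq_along(ids), function(i) {
    own <- lv[i]
    mine <- which(lv == own)
    if (length(mine) == 1) return(0)
    a_i <- mean(d[i, setdiff(mine, i)])
    b_i <- min(vapply(setdiff(unique(lv), own), function(k) {
      mean(d[i, which(lv == k)])
    }, numeric(1)))
    (b_i - a_i) / max(a_i, b_i)
  }, numeric(1))
}

# Dunn index by brute-force double loop over point pairs
oracle_dunn <- function(d, labels) {
  ids <- rownames(d)
  lv <- labels[ids]
  n <- length(ids)
  min_between <- Inf; max_within <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (lv[i] == lv[j]) max_within <- max(max_within, d[i, j])
      else min_between <- min(min_between, d[i, j])
    }
  }
  if (max_within == 0) return(Inf)
  min_between / max_within
}

# total within-cluster sum of squared deviations from the centroid
oracle_wss <- function(x, labels) {
  sum(vapply(unique(labels), function(k) {
    xs <- x[labels == k, , drop = FALSE]
    sum(sweep(xs, 2, colMeans(xs))^2)
  }, numeric(1)))
}

# exhaustive minimum-variance bipartition of <= 8 points
oracle_best_bipartition <- function(x) {
  n <- nrow(x)
  best <- NULL; best_obj <- Inf
  for (mask in 1:(2^(n - 1) - 1)) {
    lab <- as.integer(intToBits(mask)[1:n]) + 1L
    if (length(unique(lab)) < 2) next
    obj <- oracle_wss(x, lab)
    if (obj < best_obj) { best_obj <- obj; best <- lab }
  }
  list(labels = best, objective = best_obj)
}

# naive re-implementation of the QED desirability + weighted geometric mean
oracle_qed <- function(vec, params, weights) {
  ds <- vapply(names(params), function(nm) {
    p <- params[[nm]]
    x <- vec[[nm]]
    ads <- p[["a"]] + p[["b"]] /
      (1 + exp(-(x - p[["c"]] + p[["d"]] / 2) / p[["e"]])) *
      (1 - 1 / (1 + exp(-(x - p[["c"]] - p[["d"]] / 2) / p[["f"]])))
    min(max(ads / p[["dmax"]], 1e-6), 1)
  }, numeric(1))
  exp(sum(weights[names(params)] * log(ds)) / sum(weights[names(params)]))
}

# random descriptor vectors spanning (and overshooting) drug-like ranges
random_descriptor_tbl <- function(n, seed) {
  withr::with_seed(seed, tibble::tibble(
    compound_id = sprintf("R%03d", seq_len(n)),
    mw = stats::runif(n, 50, 1200),
    alogp = stats::runif(n, -4, 10),
    hba = sample(0:15, n, replace = TRUE),
    hbd = sample(0:10, n, replace = TRUE),
    psa = stats::runif(n, 0, 300),
    rotb = sample(0:20, n, replace = TRUE),
    arom = sample(0:6, n, replace = TRUE),
    alerts = sample(0:4, n, replace = TRUE)
  ))
}

# two well-separated gaussian blobs with row-named matrix output
make_blobs <- function(n_per, dim = 2, sep = 10, seed = 1) {
  withr::with_seed(seed, {
    a <- matrix(stats::rnorm(n_per * dim), ncol = dim)
    b <- matrix(stats::rnorm(n_per * dim), ncol = dim) + sep
    x <- rbind(a, b)
    dimnames(x) <- list(sprintf("p%02d", seq_len(2 * n_per)),
                        sprintf("d%d", seq_len(dim)))
    list(x = x, truth = rep(1:2, each = n_per))
  })
}

fixture_path <- function(file) {
  system.file("extdata", file, package = "senoscreen", mustWork = TRUE)
}
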