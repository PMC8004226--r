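# Quantitative Estimate of Drug-likeness (QED).
#
# Each of the eight descriptors is mapped through an asymmetric double
# sigmoid (ADS) desirability function peaked at the drug-like optimum, and
# the weighted QED is the weighted geometric mean of the eight
# desirabilities. Constants below are the published ADS fits and weights of
# Bickerton et al. (2012), "Quantifying the chemical beauty of drugs",
# Nature Chemistry 4:90-98 (parameter sets A-F and the normalizing maximum
# DMAX per descriptor; weights = the published descriptor weights).

.qed_ads_params <- list(
  mw     = c(a = 2.817065973, b = 392.5754953,  c = 290.7489764,
             d = 2.419764353, e = 49.22325677,  f = 65.37051707,
             dmax = 104.9805561),
  alogp  = c(a = 3.172690585, b = 137.8624751,  c = 2.534937431,
             d = 4.581497897, e = 0.822739154,  f = 0.576295591,
             dmax = 131.3186604),
  hba    = c(a = 2.948620388, b = 160.4605972,  c = 3.615294657,
             d = 4.435986202, e = 0.290141953,  f = 1.300669958,
             dmax = 148.7763046),
  hbd    = c(a = 1.618662227, b = 1010.051101,  c = 0.985094388,
             d = 1e-09,       e = 0.713820843,  f = 0.920922555,
             dmax = 258.1632616),
  psa    = c(a = 1.876861559, b = 125.2232657,  c = 62.90773554,
             d = 87.83366614, e = 12.01999824,  f = 28.51324732,
             dmax = 104.5686167),
  rotb   = c(a = 0.01,        b = 272.4121427,  c = 2.55837997,
             d = 1.565547684, e = 1.271567166,  f = 2.758063707,
             dmax = 105.4420403),
  arom   = c(a = 3.21778897,  b = 957.7374108,  c = 2.274627939,
             d = 1e-09,       e = 1.317690384,  f = 0.375760881,
             dmax = 312.337261),
  alerts = c(a = 0.01,        b = 1199.094025,  c = -0.09002883,
             d = 1e-09,       e = 0.185904477,  f = 0.875193782,
             dmax = 417.725314)
)

.qed_weights_published <- c(mw = 0.66, alogp = 0.46, hba = 0.05, hbd = 0.61,
                            psa = 0.06, rotb = 0.65, arom = 0.48,
                            alerts = 0.95)

# desirabilities are floored here so the log in the geometric mean stays
# finite for extreme descriptor values
.qed_floor <- 1e-6

#' QED desirability parameters
#'
#' @return The list of vendored ADS parameter vectors (one per descriptor,
#'   components `a`-`f` and `dmax`).
#' @export
qed_parameters <- function() .qed_ads_params

#' QED descriptor weights
#'
#' @param scheme `"published"` (the optimized weights of the original QED
#'   formulation; this is the weighted QED, wQED) or `"equal"` (plain
#'   geometric mean).
#' @return A named numeric vector of eight non-negative weights.
#' @export
qed_weights <- function(scheme = c("published", "equal")) {
  scheme <- match.arg(scheme)
  if (scheme == "published") .qed_weights_published
  else stats::setNames(rep(1, 8), names(.qed_weights_published))
}

#' Asymmetric double sigmoid desirability
#'
#' Evaluates the ADS desirability `d(x) = ADS(x) / dmax`, floored at `1e-6`,
#' where `ADS(x) = a + b / (1 + exp(-(x - c + d/2)/e)) *
#' (1 - 1 / (1 + exp(-(x - c - d/2)/f)))` and `dmax` normalizes the maximum
#' of the function to 1. Any real `x` is accepted; the sigmoid tails decay
#' to the floor.
#'
#' @param x Numeric vector of descriptor values.
#' @param params A parameter vector with components `a`-`f` and `dmax`
#'   (one element of [qed_parameters()]).
#' @return Desirability values in `(0, 1]`.
#' @export
ads_desirability <- function(x, params) {
  p <- as.list(params)
  ads <- p$a + p$b / (1 + exp(-(x - p$c + p$d / 2) / p$e)) *
    (1 - 1 / (1 + exp(-(x - p$c - p$d / 2) / p$f)))
  pmin(pmax(ads / p$dmax, .qed_floor), 1)
}

#' Weighted QED score
#'
#' Maps the eight QED descriptors of each compound through their desirability
#' functions and combines them as the weighted geometric mean
#' `exp(sum(w_i * log d_i) / sum(w_i))`. With equal weights this is the plain
#' geometric mean. The score is scale-free in the weights.
#'
#' @param descriptors Descriptor tibble with columns `mw`, `alogp`, `hba`,
#'   `hbd`, `psa`, `rotb`, `alerts` and (depending on `arom_source`) `arom`
#'   or `n_aromatic_rings`.
#' @param weights Either a scheme name accepted by [qed_weights()] or a named
#'   numeric vector of eight non-negative weights, not all zero.
#' @param arom_source `"rings"` applies the aromatic-descriptor desirability
#'   to the aromatic ring count (the quantity the published ADS constants
#'   were fit to; default) or `"bonds"` to the aromatic bond count.
#' @return A tibble with `compound_id`, the eight desirabilities (`d_mw`,
#'   ..., `d_alerts`) and `qed`.
#' @export
qed_score <- function(descriptors, weights = "published",
                      arom_source = c("rings", "bonds")) {
  arom_source <- match.arg(arom_source)
  d <- tibble::as_tibble(descriptors)
  if (is.character(weights)) weights <- qed_weights(weights)
  weights <- weights[names(.qed_ads_params)]
  if (anyNA(weights) || any(weights < 0) || sum(weights) == 0) {
    stop("weights must be eight non-negative values (named mw, alogp, hba, ",
         "hbd, psa, rotb, arom, alerts), not all zero", call. = FALSE)
  }
  arom_col <- if (arom_source == "rings" && "n_aromatic_rings" %in% names(d)) {
    d$n_aromatic_rings
  } else {
    d$arom
  }
  vals <- list(mw = d$mw, alogp = d$alogp, hba = d$hba, hbd = d$hbd,
               psa = d$psa, rotb = d$rotb, arom = arom_col,
               alerts = d$alerts)
  missing <- names(vals)[vapply(vals, is.null, logical(1))]
  if (length(missing) > 0) {
    stop("descriptor table lacks columns required for QED: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  des <- purrr::imap(vals, function(x, nm) {
    ads_desirability(x, .qed_ads_params[[nm]])
  })
  lg <- purrr::imap(des, function(dd, nm) weights[[nm]] * log(dd))
  qed <- exp(Reduce(`+`, lg) / sum(weights))
  out <- tibble::tibble(
    compound_id = if ("compound_id" %in% names(d)) d$compound_id
                  else as.character(seq_len(nrow(d)))
  )
  for (nm in names(des)) out[[paste0("d_", nm)]] <- des[[nm]]
  out$qed <- qed
  out
}

#' Apply the strict drug-likeness threshold
#'
#' Partitions scored compounds into drug-like (`qed > threshold`, strict
#' inequality: a score exactly at the threshold fails) and the rest, and
#' reports the pass rate as a percentage rounded to two decimals.
#'
#' @param scores A tibble with a `qed` column (from [qed_score()]).
#' @param threshold Drug-likeness cutoff, default 0.5.
#' @return The input tibble with a logical `passed` column; attributes
#'   `pass_rate` (percent, 2 decimals; `NA` for empty input), `n_passed`,
#'   `n_failed`.
#' @export
filter_druglike <- function(scores, threshold = 0.5) {
  s <- tibble::as_tibble(scores)
  if (!"qed" %in% names(s)) stop("scores must contain a qed column",
                                 call. = FALSE)
  s$passed <- s$qed > threshold
  n_pass <- sum(s$passed)
  n_all <- nrow(s)
  attr(s, "n_passed") <- n_pass
  attr(s, "n_failed") <- n_all - n_pass
  attr(s, "pass_rate") <- if (n_all == 0) NA_real_
                          else round(100 * n_pass / n_all, 2)
  s
}

#' Pass rate of a drug-likeness filter result
#'
#' @param filtered Result of [filter_druglike()].
#' @return Percentage of compounds passing, rounded to 2 decimals.
#' @export
pass_rate <- function(filtered) {
  attr(filtered, "pass_rate")
}

#' Compare descriptor distributions between two tables
#'
#' Per shared numeric descriptor column, summary statistics (min, quartiles
#' by the type-7 linear-interpolation convention, max), histogram bin counts
#' on the pooled range, and a flag for whether the two tables' ranges
#' overlap. This is the numeric surface behind side-by-side histogram/boxplot
#' figures comparing a candidate library against reference compounds.
#'
#' @param a,b Descriptor tibbles.
#' @param labels Length-2 character vector naming the two tables.
#' @param bins Number of histogram bins.
#' @return A tibble with one row per (descriptor, table): `descriptor`,
#'   `table`, `min`, `q1`, `median`, `q3`, `max`, `overlap`, and a
#'   list-column `hist` of bin counts.
#' @export
distribution_report <- function(a, b, labels = c("a", "b"), bins = 10) {
  a <- tibble::as_tibble(a); b <- tibble::as_tibble(b)
  num <- function(d) names(d)[vapply(d, is.numeric, logical(1))]
  shared <- intersect(num(a), num(b))
  if (length(shared) == 0L) {
    stop("no shared numeric descriptor columns", call. = FALSE)
  }
  purrr::map_dfr(shared, function(col) {
    xa <- a[[col]]; xb <- b[[col]]
    rng <- range(c(xa, xb))
    brk <- seq(rng[1], rng[2], length.out = bins + 1)
    if (rng[1] == rng[2]) brk <- rng[1] + seq(-0.5, 0.5, length.out = bins + 1)
    overlap <- max(min(xa), min(xb)) <= min(max(xa), max(xb))
    one <- function(x, tag) {
      q <- stats::quantile(x, c(0, 0.25, 0.5, 0.75, 1), type = 7,
                           names = FALSE)
      tibble::tibble(descriptor = col, table = tag,
                     min = q[1], q1 = q[2], median = q[3], q3 = q[4],
                     max = q[5], overlap = overlap,
                     hist = list(graphics::hist(x, breaks = brk,
                                                plot = FALSE)$counts))
    }
    dplyr::bind_rows(one(xa, labels[1]), one(xb, labels[2]))
  })
}
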