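# Phase 3: for each senolytic lead, cluster {lead} + drug-like candidates in
# fingerprint (Tanimoto) space, validate the partition, extract the
# candidates co-clustered with the lead, and take the deduplicated union
# across leads.

#' Screen candidates against one lead
#'
#' Fingerprints the lead and the candidates, builds the Tanimoto distance
#' matrix, picks k by the elbow method over Ward partitions (k = 2 ..
#' min(8, n-1)) unless `k` is given, cuts the Ward tree, and records the
#' candidates sharing the lead's cluster together with the partition's mean
#' silhouette and Dunn index.
#'
#' @param lead One-row compound tibble (or a compound table plus `lead_id`).
#' @param candidates Compound tibble of drug-like candidates (>= 3 rows).
#' @param k Number of clusters; `NULL` (default) = elbow choice.
#' @param n_bits,max_path_length Fingerprint parameters.
#' @param fps Optional precomputed fingerprint tibble covering lead and
#'   candidates (saves re-fingerprinting in multi-lead loops).
#' @return One-row tibble: `lead_id`, `k_used`, `n_candidates`,
#'   `n_co_clustered`, `silhouette_mean`, `dunn`, list-column
#'   `co_clustered_ids`.
#' @export
screen_against_lead <- function(lead, candidates, k = NULL, n_bits = 1024,
                                max_path_length = 6, fps = NULL) {
  lead <- .as_compound_tbl(lead)
  stopifnot(nrow(lead) == 1)
  candidates <- .as_compound_tbl(candidates)
  candidates <- candidates[candidates$compound_id != lead$compound_id, ,
                           drop = FALSE]
  if (nrow(candidates) < 3) {
    stop("need at least 3 candidates to screen", call. = FALSE)
  }
  all_cmp <- dplyr::bind_rows(lead, candidates)
  if (is.null(fps)) {
    fps <- fingerprint_compounds(all_cmp, n_bits = n_bits,
                                 max_path_length = max_path_length)
  } else {
    fps <- fps[match(all_cmp$compound_id, fps$compound_id), , drop = FALSE]
    if (anyNA(fps$compound_id)) {
      stop("precomputed fingerprints missing for some compounds",
           call. = FALSE)
    }
  }
  dm <- tanimoto_distance_matrix(fps)
  if (max(dm) == 0) {
    stop("all fingerprints identical; clustering geometry is degenerate",
         call. = FALSE)
  }
  n <- nrow(dm)
  if (is.null(k)) {
    ks <- 1:min(8, n - 1)
    k <- if (length(ks) >= 3) elbow_k(wss_curve(dm, ks)) else 2L
    k <- max(k, 2L)
  }
  cl <- ward_cluster(dm, k)
  lv <- stats::setNames(cl$labels$cluster, cl$labels$compound_id)
  lead_cluster <- lv[[lead$compound_id]]
  co <- setdiff(names(lv)[lv == lead_cluster], lead$compound_id)
  tibble::tibble(
    lead_id = lead$compound_id,
    k_used = as.integer(k),
    n_candidates = nrow(candidates),
    n_co_clustered = length(co),
    silhouette_mean = attr(silhouette_scores(dm, cl), "silhouette_mean"),
    dunn = dunn_index(dm, cl),
    co_clustered_ids = list(co)
  )
}

#' Screen candidates against every lead
#'
#' Runs [screen_against_lead()] once per lead over a shared candidate set,
#' fingerprinting each structure once. Candidates without any record in an
#' optional binding table are dropped before screening (compounds with no
#' known protein targets cannot enter the network phase), with counts
#' recorded in the `pre_screen` attribute.
#'
#' @param leads Compound tibble of leads.
#' @param candidates Compound tibble of candidates.
#' @param bindings Optional binding tibble (`compound_id`, `target_symbol`);
#'   when given, candidates lacking binding records are excluded.
#' @param k Cluster count per lead (`NULL` = per-lead elbow choice).
#' @inheritParams screen_against_lead
#' @return A tibble with one row per lead (the per-lead screen records).
#' @export
screen_leads <- function(leads, candidates, bindings = NULL, k = NULL,
                         n_bits = 1024, max_path_length = 6) {
  leads <- .as_compound_tbl(leads)
  candidates <- .as_compound_tbl(candidates)
  n_before <- nrow(candidates)
  if (!is.null(bindings)) {
    with_targets <- unique(as.character(bindings$compound_id))
    candidates <- candidates[candidates$compound_id %in% with_targets, ,
                             drop = FALSE]
    message(n_before - nrow(candidates), " of ", n_before,
            " candidates dropped (no binding records); ", nrow(candidates),
            " screened")
  }
  fps <- fingerprint_compounds(dplyr::bind_rows(leads, candidates),
                               n_bits = n_bits,
                               max_path_length = max_path_length)
  out <- purrr::map_dfr(seq_len(nrow(leads)), function(i) {
    screen_against_lead(leads[i, , drop = FALSE], candidates, k = k,
                        n_bits = n_bits, max_path_length = max_path_length,
                        fps = fps)
  })
  attr(out, "pre_screen") <- c(candidates_in = n_before,
                               candidates_screened = nrow(candidates))
  out
}

#' Deduplicated union of per-lead screen hits
#'
#' Takes the union of `co_clustered_ids` across leads, de-duplicates through
#' canonical structure keys, and records for every surviving candidate the
#' leads that co-clustered it.
#'
#' @param records Screen records from [screen_leads()].
#' @param compounds Compound tibble covering the candidates (used for
#'   canonical keys; canonicalized on the fly if needed).
#' @return A tibble `compound_id`, `n_support`, list-column `support`
#'   (supporting lead ids).
#' @export
union_screen_hits <- function(records, compounds) {
  if (nrow(records) == 0) {
    return(tibble::tibble(compound_id = character(0),
                          n_support = integer(0), support = list()))
  }
  pairs <- purrr::map_dfr(seq_len(nrow(records)), function(i) {
    ids <- records$co_clustered_ids[[i]]
    if (length(ids) == 0) return(NULL)
    tibble::tibble(lead_id = records$lead_id[i], compound_id = ids)
  })
  if (nrow(pairs) == 0) {
    return(tibble::tibble(compound_id = character(0),
                          n_support = integer(0), support = list()))
  }
  compounds <- .as_compound_tbl(compounds)
  if (!"structure_key" %in% names(compounds)) {
    compounds <- canonicalize_compounds(compounds)
  }
  key <- stats::setNames(compounds$structure_key, compounds$compound_id)
  keep <- dedup_compounds(compounds[compounds$compound_id %in%
                                      pairs$compound_id, , drop = FALSE])
  kept_of <- stats::setNames(attr(keep, "dedup_map")$kept_id,
                             attr(keep, "dedup_map")$compound_id)
  pairs$compound_id <- unname(kept_of[pairs$compound_id])
  pairs <- dplyr::distinct(pairs)
  pairs |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(n_support = dplyr::n(),
                     support = list(sort(unique(.data$lead_id))),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$compound_id, keep$compound_id))
}

#' Tabular summary of a similarity screen
#'
#' One row per lead (candidate counts, mean silhouette, Dunn index) plus the
#' overall mean silhouette across leads, rounded to two decimals in the
#' `sc_mean` attribute.
#'
#' @param records Screen records from [screen_leads()].
#' @param hits Deduplicated union from [union_screen_hits()] (optional; adds
#'   totals).
#' @return A tibble; attributes `sc_mean` (2 decimals) and `n_unique_hits`.
#' @export
screen_report <- function(records, hits = NULL) {
  stopifnot(nrow(records) >= 1)
  out <- records |>
    dplyr::select("lead_id", "k_used", "n_candidates", "n_co_clustered",
                  "silhouette_mean", "dunn")
  attr(out, "sc_mean") <- round(mean(records$silhouette_mean), 2)
  if (!is.null(hits)) attr(out, "n_unique_hits") <- nrow(hits)
  out
}
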