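# Orchestration of the four screening phases: lead selection -> QED
# drug-likeness filter -> per-lead fingerprint similarity screen -> compound-
# target network ranking, with a JSON run manifest recording the attrition
# counts at every stage.

#' Assemble and validate a pipeline configuration
#'
#' Inputs may be file paths (read with the package readers) or in-memory
#' tibbles. Exactly one of `leads` / (`descriptors` + `anchor_ids`) selects
#' the lead set: an explicit lead table, or descriptor-space lead-cluster
#' selection. With `library = NULL` the pipeline runs in network-only mode:
#' `candidates` + `bindings` + `pathways` feed the network phase directly.
#'
#' @param library Compound library (path or tibble) of screening candidates.
#' @param leads Lead compounds (path, tibble, or character ids into
#'   `library`).
#' @param descriptors Descriptor table (path or tibble) for lead selection.
#' @param anchor_ids Anchor compound ids for [select_lead_cluster()].
#' @param candidates Compound table for network-only mode.
#' @param bindings Binding table (path or tibble).
#' @param pathways Pathway gene sets (path or tibble).
#' @param qed_threshold Drug-likeness cutoff in (0, 1); default 0.5.
#' @param qed_weights Weight scheme for [qed_score()].
#' @param n_bits Fingerprint length (512/1024/2048).
#' @param k_screen Cluster count per lead (`NULL` = elbow).
#' @param k_leads Cluster count for lead selection.
#' @param seed Integer seed (required; no wall-clock seeding).
#' @param out_dir Output directory (`NULL` = nothing written).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(library = NULL, leads = NULL, descriptors = NULL,
                            anchor_ids = NULL, candidates = NULL,
                            bindings = NULL, pathways = NULL,
                            qed_threshold = 0.5,
                            qed_weights = "published", n_bits = 1024,
                            k_screen = NULL, k_leads = 2, seed = 1,
                            out_dir = NULL) {
  if (!is.numeric(qed_threshold) || qed_threshold <= 0 || qed_threshold >= 1)
    stop("qed_threshold must lie in (0, 1)", call. = FALSE)
  if (!n_bits %in% c(512, 1024, 2048))
    stop("n_bits must be 512, 1024 or 2048", call. = FALSE)
  if (is.null(seed) || !is.numeric(seed))
    stop("an explicit integer seed is required", call. = FALSE)
  structure(as.list(environment()), class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Config file; keys are the arguments of [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  ext <- tolower(tools::file_ext(path))
  vals <- if (ext %in% c("yml", "yaml")) yaml::read_yaml(path)
          else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, vals)
}

.load_tbl <- function(x, reader) {
  if (is.null(x) || is.data.frame(x)) return(x)
  if (is.character(x) && length(x) == 1 && file.exists(x)) return(reader(x))
  x
}

#' Run the screening pipeline
#'
#' Executes the configured phases in order and returns a result bundle with
#' a manifest of counts at every attrition point (loaded, valid, drug-like,
#' with binding records, co-clustered, deduplicated, ranked). Any phase
#' failure aborts with the phase name. With `out_dir` set, per-phase CSVs,
#' the GraphML network and `manifest.json` are written.
#'
#' @param cfg A [pipeline_config()].
#' @return A `seno_pipeline_result` list: `leads`, `qed`, `screen_records`,
#'   `hits`, `network`, `ranking`, `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  phase <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline phase '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  manifest <- list(seed = cfg$seed,
                   params = list(qed_threshold = cfg$qed_threshold,
                                 n_bits = cfg$n_bits,
                                 k_screen = cfg$k_screen,
                                 k_leads = cfg$k_leads),
                   counts = list())
  bindings <- phase("inputs", .load_tbl(cfg$bindings, read_bindings))
  pathways <- phase("inputs", .load_tbl(cfg$pathways, read_pathways))

  network_only <- is.null(cfg$library)
  if (network_only) {
    candidates <- phase("inputs", .load_tbl(cfg$candidates, read_compounds))
    if (is.null(candidates)) {
      stop("pipeline phase 'inputs' failed: network-only mode needs ",
           "candidates", call. = FALSE)
    }
    candidates <- phase("dedup", dedup_compounds(candidates))
    manifest$counts$loaded <- nrow(candidates)
    manifest$counts$deduped <- nrow(candidates)
    leads <- qed <- records <- hits <- NULL
    hit_ids <- candidates$compound_id
  } else {
    library_tbl <- phase("load_library",
                         .load_tbl(cfg$library, read_compounds))
    library_tbl <- phase("load_library", canonicalize_compounds(library_tbl))
    manifest$counts$loaded <- nrow(library_tbl)
    manifest$counts$valid <- sum(library_tbl$valid)

    leads <- phase("lead_selection", {
      if (!is.null(cfg$leads)) {
        if (is.character(cfg$leads) && !any(file.exists(cfg$leads))) {
          library_tbl[library_tbl$compound_id %in% cfg$leads, , drop = FALSE]
        } else {
          .as_compound_tbl(.load_tbl(cfg$leads, read_compounds))
        }
      } else {
        desc <- .load_tbl(cfg$descriptors, read_descriptor_table)
        if (is.null(desc) || is.null(cfg$anchor_ids)) {
          stop("either leads or descriptors + anchor_ids must be supplied")
        }
        sel <- select_lead_cluster(desc, k = cfg$k_leads,
                                   anchor_ids = cfg$anchor_ids,
                                   seed = cfg$seed)
        library_tbl[library_tbl$compound_id %in% sel$compound_id, ,
                    drop = FALSE]
      }
    })
    manifest$counts$leads <- nrow(leads)

    candidates <- library_tbl[library_tbl$valid &
                                !library_tbl$compound_id %in%
                                  leads$compound_id, , drop = FALSE]

    qed <- phase("qed_filter", {
      desc <- compute_descriptors(candidates)
      filter_druglike(qed_score(desc, weights = cfg$qed_weights),
                      threshold = cfg$qed_threshold)
    })
    druglike <- candidates[candidates$compound_id %in%
                             qed$compound_id[qed$passed], , drop = FALSE]
    manifest$counts$druglike <- nrow(druglike)
    manifest$qed_pass_rate <- pass_rate(qed)

    records <- phase("similarity_screen", {
      screen_leads(leads, druglike, bindings = bindings, k = cfg$k_screen,
                   n_bits = cfg$n_bits)
    })
    manifest$counts$with_binding <-
      unname(attr(records, "pre_screen")["candidates_screened"])
    hits <- phase("similarity_screen",
                  union_screen_hits(records, candidates))
    manifest$counts$co_clustered <-
      length(unique(unlist(records$co_clustered_ids)))
    manifest$counts$deduped <- nrow(hits)
    manifest$sc_mean <- round(mean(records$silhouette_mean), 2)
    hit_ids <- hits$compound_id
  }

  network <- ranking <- NULL
  if (!is.null(bindings) && !is.null(pathways) && length(hit_ids) > 0) {
    network <- phase("target_network",
                     build_target_network(bindings, pathways, hit_ids))
    ranking <- phase("target_network", rank_multitarget(network))
    manifest$counts$ranked <- nrow(ranking)
  }

  result <- structure(
    list(leads = leads, qed = qed,
         screen_records = if (!network_only) records else NULL,
         hits = if (!network_only) hits else NULL,
         network = network, ranking = ranking, manifest = manifest),
    class = "seno_pipeline_result"
  )
  if (!is.null(cfg$out_dir)) .write_pipeline_outputs(result, cfg$out_dir)
  result
}

.write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(x, f) {
    if (!is.null(x)) utils::write.csv(as.data.frame(x),
                                      file.path(out_dir, f),
                                      row.names = FALSE)
  }
  w(result$leads, "leads.csv")
  w(result$qed, "qed_scores.csv")
  if (!is.null(result$screen_records)) {
    flat <- result$screen_records |>
      dplyr::mutate(co_clustered_ids = vapply(.data$co_clustered_ids,
                                              paste, character(1),
                                              collapse = ";"))
    w(flat, "screen_records.csv")
  }
  if (!is.null(result$hits)) {
    flat <- result$hits |>
      dplyr::mutate(support = vapply(.data$support, paste, character(1),
                                     collapse = ";"))
    w(flat, "hits.csv")
  }
  if (!is.null(result$ranking)) {
    flat <- result$ranking |>
      dplyr::mutate(
        senescence_targets = vapply(.data$senescence_targets, paste,
                                    character(1), collapse = ";"),
        pathways_hit = vapply(.data$pathways_hit, paste, character(1),
                              collapse = ";")
      )
    w(flat, "ranking.csv")
  }
  if (!is.null(result$network)) {
    export_network(result$network, file.path(out_dir, "network.graphml"),
                   "graphml")
  }
  jsonlite::write_json(result$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.seno_pipeline_result <- function(x, ...) {
  cat("<seno_pipeline_result>\n")
  cnt <- x$manifest$counts
  for (nm in names(cnt)) cat("  ", nm, ": ", cnt[[nm]], "\n", sep = "")
  if (!is.null(x$ranking) && nrow(x$ranking) > 0) {
    cat("  top candidate:", x$ranking$compound_id[1], "\n")
  }
  invisible(x)
}
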