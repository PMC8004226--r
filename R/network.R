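# Phase 4: compound-target network joined to senescence pathway gene sets,
# and multitarget ranking of the candidates.

# symbol typos seen in the wild (network sources mix hand-typed symbols);
# applied after uppercasing
.symbol_aliases <- c(HDCA4 = "HDAC4", HDCA5 = "HDAC5", HDCA1 = "HDAC1",
                     HDCA2 = "HDAC2", HDCA6 = "HDAC6", HDCA8 = "HDAC8")

#' Normalize gene/protein symbols
#'
#' Uppercases, strips whitespace, and applies a small alias map correcting
#' common typos (e.g. `HDCA4` -> `HDAC4`).
#'
#' @param symbols Character vector.
#' @param aliases Named character vector of corrections.
#' @return Normalized character vector.
#' @export
normalize_symbols <- function(symbols, aliases = .symbol_aliases) {
  s <- toupper(gsub("\\s+", "", as.character(symbols)))
  hit <- s %in% names(aliases)
  s[hit] <- unname(aliases[s[hit]])
  s
}

#' Read a compound-target binding table
#'
#' CSV with columns `compound_id`, `target_symbol` and optional free-text
#' `interaction` (inhibitor/modulator/...). Symbols are normalized.
#'
#' @param path CSV path.
#' @return A binding tibble.
#' @export
read_bindings <- function(path) {
  if (!file.exists(path)) stop("binding table not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("compound_id", "target_symbol")
  if (!all(need %in% names(df))) {
    stop("binding table needs columns compound_id, target_symbol",
         call. = FALSE)
  }
  tibble::tibble(
    compound_id = as.character(df$compound_id),
    target_symbol = normalize_symbols(df$target_symbol),
    interaction = if ("interaction" %in% names(df))
      as.character(df$interaction) else NA_character_
  ) |>
    dplyr::filter(nzchar(.data$compound_id), nzchar(.data$target_symbol))
}

#' Read pathway gene sets
#'
#' Two-column CSV (`pathway_code`, `gene`) or GMT (set name, description,
#' member genes per line; chosen by the `.gmt` extension). Symbols are
#' normalized.
#'
#' @param path File path.
#' @return A tibble `pathway_code`, `gene`.
#' @export
read_pathways <- function(path) {
  if (!file.exists(path)) stop("pathway file not found: ", path,
                               call. = FALSE)
  if (tolower(tools::file_ext(path)) == "gmt") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    out <- purrr::map_dfr(strsplit(lines, "\t", fixed = TRUE), function(p) {
      if (length(p) < 3) return(NULL)
      tibble::tibble(pathway_code = p[1], gene = p[-(1:2)])
    })
  } else {
    df <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("pathway_code", "gene") %in% names(df))) {
      stop("pathway csv needs columns pathway_code, gene", call. = FALSE)
    }
    out <- tibble::tibble(pathway_code = as.character(df$pathway_code),
                          gene = as.character(df$gene))
  }
  out$gene <- normalize_symbols(out$gene)
  out <- dplyr::distinct(out[nzchar(out$gene), , drop = FALSE])
  if (nrow(out) == 0) stop("no pathway genes read", call. = FALSE)
  out
}

#' Build the compound-target network
#'
#' A bipartite graph whose compound nodes are the supplied candidates and
#' whose target nodes are annotated with the pathway codes containing their
#' symbol. Duplicate binding rows collapse onto one edge; binding records
#' for compounds outside `compounds` are dropped with a count.
#'
#' @param bindings Binding tibble (`compound_id`, `target_symbol`).
#' @param pathways Pathway tibble (`pathway_code`, `gene`).
#' @param compounds Character vector of compound ids to include (default:
#'   every compound in `bindings`).
#' @return A `seno_network` object: an igraph graph plus node and edge
#'   tibbles; attribute `n_dropped` counts discarded binding rows.
#' @export
build_target_network <- function(bindings, pathways, compounds = NULL) {
  bindings <- tibble::as_tibble(bindings)
  if (nrow(bindings) == 0) stop("empty binding table", call. = FALSE)
  bindings$compound_id <- as.character(bindings$compound_id)
  bindings$target_symbol <- normalize_symbols(bindings$target_symbol)
  if (is.null(compounds)) compounds <- unique(bindings$compound_id)
  n_in <- nrow(bindings)
  bindings <- bindings[bindings$compound_id %in% compounds, , drop = FALSE]
  n_dropped <- n_in - nrow(bindings)
  if (nrow(bindings) == 0) {
    stop("no binding records left for the supplied compounds", call. = FALSE)
  }
  edges <- dplyr::distinct(bindings[, c("compound_id", "target_symbol")])

  pathways <- tibble::as_tibble(pathways)
  annot <- pathways |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      pathways = paste(sort(unique(.data$pathway_code)), collapse = ";"),
      .groups = "drop"
    )
  targets <- tibble::tibble(id = sort(unique(edges$target_symbol))) |>
    dplyr::left_join(annot, by = c(id = "gene")) |>
    dplyr::mutate(pathways = dplyr::coalesce(.data$pathways, ""),
                  kind = "target")
  cmp_nodes <- tibble::tibble(id = unique(edges$compound_id),
                              pathways = "", kind = "compound")
  nodes <- dplyr::bind_rows(cmp_nodes, targets)

  g <- igraph::graph_from_data_frame(
    edges, directed = FALSE,
    vertices = data.frame(name = nodes$id, kind = nodes$kind,
                          pathways = nodes$pathways,
                          type = nodes$kind == "target")
  )
  structure(
    list(graph = g, nodes = nodes,
         edges = tibble::as_tibble(edges)),
    class = "seno_network", n_dropped = n_dropped
  )
}

#' @export
print.seno_network <- function(x, ...) {
  cat("<seno_network> ", sum(x$nodes$kind == "compound"), " compounds, ",
      sum(x$nodes$kind == "target"), " targets, ", nrow(x$edges),
      " edges\n", sep = "")
  invisible(x)
}

#' Rank compounds by multitarget capacity
#'
#' For each compound node: the number of distinct targets (`n_targets`), the
#' number of those annotated to at least one senescence pathway
#' (`n_senescence_targets`), and the pathway codes hit. Sorted by
#' senescence-target count (descending), then total targets (descending),
#' then compound id (alphabetical tie-break).
#'
#' @param net A `seno_network`.
#' @return A ranked tibble with list-columns `senescence_targets`,
#'   `pathways_hit`.
#' @export
rank_multitarget <- function(net) {
  stopifnot(inherits(net, "seno_network"))
  annot <- stats::setNames(net$nodes$pathways, net$nodes$id)
  out <- net$edges |>
    dplyr::group_by(.data$compound_id) |>
    dplyr::summarise(
      n_targets = dplyr::n_distinct(.data$target_symbol),
      senescence_targets = list(sort(unique(
        .data$target_symbol[annot[.data$target_symbol] != ""]
      ))),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      n_senescence_targets = lengths(.data$senescence_targets),
      pathways_hit = purrr::map(.data$senescence_targets, function(ts) {
        sort(unique(unlist(strsplit(annot[ts], ";", fixed = TRUE))))
      })
    ) |>
    dplyr::arrange(dplyr::desc(.data$n_senescence_targets),
                   dplyr::desc(.data$n_targets), .data$compound_id) |>
    dplyr::select("compound_id", "n_targets", "n_senescence_targets",
                  "senescence_targets", "pathways_hit")
  out
}

#' Export a network to standard graph formats
#'
#' Writes GraphML (node attributes `kind` and `pathways` preserved; a
#' GraphML re-import reproduces the network exactly), SIF triples
#' (`compound binds target`), or node/edge CSV tables.
#'
#' @param net A `seno_network`.
#' @param path Output file path (for `csv`, the prefix: `<path>_nodes.csv`
#'   and `<path>_edges.csv` are written).
#' @param format `"graphml"`, `"sif"` or `"csv"`.
#' @return The paths written, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "sif", "csv")) {
  stopifnot(inherits(net, "seno_network"))
  format <- match.arg(format)
  paths <- switch(format,
    graphml = {
      igraph::write_graph(net$graph, path, format = "graphml")
      path
    },
    sif = {
      writeLines(paste(net$edges$compound_id, "binds",
                       net$edges$target_symbol), path)
      path
    },
    csv = {
      np <- paste0(path, "_nodes.csv"); ep <- paste0(path, "_edges.csv")
      utils::write.csv(as.data.frame(net$nodes), np, row.names = FALSE)
      utils::write.csv(as.data.frame(net$edges), ep, row.names = FALSE)
      c(np, ep)
    }
  )
  invisible(paths)
}

#' Re-import a GraphML network export
#'
#' @param path GraphML file written by [export_network()].
#' @return A `seno_network`.
#' @export
read_network_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  nodes <- tibble::tibble(
    id = igraph::V(g)$name,
    pathways = igraph::V(g)$pathways,
    kind = igraph::V(g)$kind
  )
  el <- igraph::as_edgelist(g)
  # orient edges compound -> target regardless of stored order
  kind <- stats::setNames(nodes$kind, nodes$id)
  swap <- kind[el[, 1]] == "target"
  el[swap, ] <- el[swap, c(2, 1)]
  structure(
    list(graph = g, nodes = nodes,
         edges = tibble::tibble(compound_id = el[, 1],
                                target_symbol = el[, 2])),
    class = "seno_network", n_dropped = 0L
  )
}
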