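fig6_network <- function() {
  build_target_network(read_bindings(fixture_path("figure6_bindings.csv")),
                       read_pathways(fixture_path("senescence_pathways.csv")))
}

test_that("duplicate binding rows collapse onto single edges", {
  b <- tibble::tibble(compound_id = c("c1", "c1", "c1"),
                      target_symbol = c("T1", "T1", "T2"))
  p <- tibble::tibble(pathway_code = "CC", gene = "T1")
  net <- build_target_network(b, p)
  expect_equal(nrow(net$nodes), 3)
  expect_equal(nrow(net$edges), 2)
  net_dup <- build_target_network(dplyr::bind_rows(b, b[1, ]), p)
  expect_equal(net_dup$edges, net$edges)
  expect_error(build_target_network(b[0, ], p), "empty")
})

test_that("symbol normalization fixes case, whitespace, and known typos", {
  expect_equal(normalize_symbols(c(" hdac4", "HDCA4", "jun ")),
               c("HDAC4", "HDAC4", "JUN"))
})

test_that("the published interaction fixture yields the reported connections", {
  net <- fig6_network()
  hin <- net$edges$target_symbol[net$edges$compound_id == "ZINC95911093"]
  expect_setequal(hin, c("HDAC1", "HDAC2", "HDAC4", "HDAC5", "HDAC6",
                         "HDAC8", "TYR"))
  annotated <- net$nodes$pathways[match(c("HDAC4", "HDAC5", "HDAC1"),
                                        net$nodes$id)]
  expect_equal(annotated, c("CC", "CC", ""))
})

test_that("multitarget ranking counts distinct targets and orders by the stated keys", {
  net <- fig6_network()
  r <- rank_multitarget(net)
  deg <- setNames(r$n_targets, r$compound_id)
  expect_equal(deg[["ZINC95911093"]], 7)   # hinokitiol
  expect_equal(deg[["ZINC34383300"]], 10)  # preussomerin C
  expect_equal(deg[["ZINC2558154"]], 6)    # tanshinone I

  # degrees equal a brute-force edge scan
  brute <- table(net$edges$compound_id)
  expect_equal(unname(deg[names(brute)]), as.integer(brute))

  # duplicate rows to one target count once
  b <- tibble::tibble(compound_id = "c", target_symbol = c("T1", "T1"))
  net1 <- build_target_network(b, tibble::tibble(pathway_code = "CC",
                                                 gene = "T9"))
  expect_equal(rank_multitarget(net1)$n_targets, 1)

  # full tie broken alphabetically
  b2 <- tibble::tibble(compound_id = c("zeta", "alpha"),
                       target_symbol = c("T1", "T2"))
  r2 <- rank_multitarget(build_target_network(
    b2, tibble::tibble(pathway_code = "CC", gene = "none")))
  expect_equal(r2$compound_id, c("alpha", "zeta"))
})

test_that("pathway annotation is monotone under gene-set growth", {
  b <- read_bindings(fixture_path("figure6_bindings.csv"))
  p_small <- tibble::tibble(pathway_code = "CC", gene = "HDAC4")
  p_big <- dplyr::bind_rows(p_small,
                            tibble::tibble(pathway_code = "CC",
                                           gene = c("HDAC5", "TYR")))
  ann <- function(net) net$nodes$id[net$nodes$pathways != ""]
  expect_true(all(ann(build_target_network(b, p_small)) %in%
                    ann(build_target_network(b, p_big))))
})

test_that("network exports round-trip (graphml) and match counts (sif, csv)", {
  net <- fig6_network()
  gml <- withr::local_tempfile(fileext = ".graphml")
  export_network(net, gml, "graphml")
  back <- read_network_graphml(gml)
  expect_setequal(back$nodes$id, net$nodes$id)
  expect_equal(
    dplyr::arrange(back$edges, .data$compound_id, .data$target_symbol),
    dplyr::arrange(net$edges, .data$compound_id, .data$target_symbol)
  )
  expect_equal(back$nodes$pathways[match(net$nodes$id, back$nodes$id)],
               net$nodes$pathways)

  sif <- withr::local_tempfile(fileext = ".sif")
  export_network(net, sif, "sif")
  expect_length(readLines(sif), nrow(net$edges))

  prefix <- withr::local_tempfile()
  paths <- export_network(net, prefix, "csv")
  nodes_csv <- utils::read.csv(paste0(prefix, "_nodes.csv"))
  expect_equal(nrow(nodes_csv), nrow(net$nodes))

  expect_error(export_network(net, gml, "dot"), "arg")
})

test_that("gmt pathway files parse to the same sets as two-column csv", {
  gmt <- withr::local_tempfile(fileext = ".gmt")
  writeLines(c("CC\tdesc\tHDAC4\tHDAC5", "OSIS\tdesc\tJUN"), gmt)
  p <- read_pathways(gmt)
  expect_equal(nrow(p), 3)
  expect_setequal(p$gene[p$pathway_code == "CC"], c("HDAC4", "HDAC5"))
})
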