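test_that("screening a lead against planted analogs recovers the family", {
  lib <- generate_library(synth_spec(seed = 19, n_decoys = 30,
                                     n_analog_families = 1,
                                     analogs_per_family = 5))
  truth <- attr(lib, "truth")
  lead <- lib[truth$role == "parent", ][1, ]
  cands <- lib[truth$role != "parent", ]
  rec <- screen_against_lead(lead, cands)
  analogs <- truth$compound_id[truth$role == "analog"]
  expect_gte(sum(analogs %in% rec$co_clustered_ids[[1]]), 4)
  expect_gte(rec$k_used, 2)
  expect_false(lead$compound_id %in% rec$co_clustered_ids[[1]])
})

test_that("forcing k=3 on a three-family library returns the lead's own family", {
  lib <- generate_library(synth_spec(seed = 23, n_decoys = 0,
                                     n_analog_families = 3,
                                     analogs_per_family = 6))
  truth <- attr(lib, "truth")
  lead <- lib[truth$role == "parent" & truth$family == 1, ]
  cands <- lib[lib$compound_id != lead$compound_id, ]
  rec <- screen_against_lead(lead, cands, k = 3)
  fam1 <- truth$compound_id[truth$family == 1 & truth$role == "analog"]
  expect_setequal(rec$co_clustered_ids[[1]], fam1)
})

test_that("degenerate inputs are rejected", {
  same <- tibble::tibble(compound_id = c("c1", "c2", "c3"),
                         smiles = c("CCO", "OCC", "C(C)O"))
  lead <- tibble::tibble(compound_id = "lead", smiles = "CCO")
  expect_error(screen_against_lead(lead, same), "degenerate")
  few <- tibble::tibble(compound_id = c("c1", "c2"),
                        smiles = c("CCO", "CCN"))
  expect_error(screen_against_lead(lead, few), "at least 3")
})

test_that("candidate recovery across 10 seeds averages at least 90 percent", {
  rates <- vapply(1:10, function(s) {
    lib <- generate_library(synth_spec(seed = s, n_decoys = 50,
                                       n_analog_families = 1,
                                       analogs_per_family = 5))
    truth <- attr(lib, "truth")
    lead <- lib[truth$role == "parent", ][1, ]
    cands <- lib[truth$role != "parent", ]
    rec <- screen_against_lead(lead, cands)
    analogs <- truth$compound_id[truth$role == "analog"]
    mean(analogs %in% rec$co_clustered_ids[[1]])
  }, numeric(1))
  expect_gte(mean(rates), 0.9)
})

test_that("union of per-lead hits dedups through structures and books support", {
  records <- tibble::tibble(
    lead_id = c("L1", "L2"),
    k_used = c(2L, 2L), n_candidates = c(3L, 3L), n_co_clustered = c(2L, 2L),
    silhouette_mean = c(0.3, 0.4), dunn = c(1, 1),
    co_clustered_ids = list(c("A", "B"), c("Bdup", "C"))
  )
  cmp <- tibble::tibble(compound_id = c("A", "B", "Bdup", "C"),
                        smiles = c("CCO", "c1ccccc1", "C1=CC=CC=C1", "CCN"))
  hits <- union_screen_hits(records, cmp)
  expect_setequal(hits$compound_id, c("A", "B", "C"))
  expect_setequal(hits$support[hits$compound_id == "B"][[1]], c("L1", "L2"))
  # support bookkeeping conserves counts once duplicates collapse
  expect_equal(sum(hits$n_support),
               nrow(dplyr::distinct(tibble::tibble(
                 lead = rep(records$lead_id, lengths(records$co_clustered_ids)),
                 id = sub("dup", "", unlist(records$co_clustered_ids))))))

  empty <- union_screen_hits(records[0, ], cmp)
  expect_equal(nrow(empty), 0)
})

test_that("the reconstructed per-lead hit lists collapse to 17 unique candidates", {
  cand <- read_compounds(fixture_path("table2_candidates_synthetic_smiles.csv"))
  half <- nrow(cand) %/% 2
  records <- tibble::tibble(
    lead_id = c("navitoclax", "rapamycin"),
    k_used = 3L, n_candidates = nrow(cand),
    n_co_clustered = c(half + 2L, nrow(cand) - half),
    silhouette_mean = c(0.23, 0.38), dunn = c(1, 1),
    co_clustered_ids = list(cand$compound_id[1:(half + 2)],
                            cand$compound_id[(half + 1):nrow(cand)])
  )
  hits <- union_screen_hits(records, cand)
  expect_equal(nrow(hits), 17)
})

test_that("screen reports average the per-lead silhouettes to 2 decimals", {
  records <- tibble::tibble(
    lead_id = c("L1", "L2"), k_used = 2L, n_candidates = 10L,
    n_co_clustered = c(3L, 4L), silhouette_mean = c(0.2, 0.4),
    dunn = c(0.5, 0.7), co_clustered_ids = list("A", "B")
  )
  rep2 <- screen_report(records)
  expect_equal(attr(rep2, "sc_mean"), 0.3)
  one <- screen_report(records[1, ])
  expect_equal(attr(one, "sc_mean"), 0.2)

  # rendered csv re-parses to the same numbers
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(as.data.frame(rep2), path, row.names = FALSE)
  back <- utils::read.csv(path)
  expect_equal(back$silhouette_mean, rep2$silhouette_mean)
})

test_that("screening is invariant to candidate order and respects binding pre-filter", {
  lib <- generate_library(synth_spec(seed = 29, n_decoys = 20,
                                     n_analog_families = 1,
                                     analogs_per_family = 4))
  truth <- attr(lib, "truth")
  lead <- lib[truth$role == "parent", ][1, ]
  cands <- lib[truth$role != "parent", ]
  r1 <- screen_against_lead(lead, cands)
  r2 <- screen_against_lead(lead, cands[rev(seq_len(nrow(cands))), ])
  expect_setequal(r1$co_clustered_ids[[1]], r2$co_clustered_ids[[1]])
  expect_equal(r1$silhouette_mean, r2$silhouette_mean)

  bindings <- tibble::tibble(compound_id = cands$compound_id[1:10],
                             target_symbol = "T001")
  expect_message(
    recs <- screen_leads(lead, cands, bindings = bindings, k = 2),
    "dropped"
  )
  expect_equal(recs$n_candidates, 10)
})
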