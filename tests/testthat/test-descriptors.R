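test_that("descriptor counts match chemical definitions on reference molecules", {
  cmp <- tibble::tibble(
    compound_id = c("benzene", "ethanol", "pyridine", "pyrrole", "butane"),
    smiles = c("c1ccccc1", "CCO", "c1ccncc1", "c1cc[nH]c1", "CCCC")
  )
  d <- compute_descriptors(cmp)
  # benzene: six aromatic bonds, no donors, nothing rotates
  expect_equal(d$arom[1], 6)
  expect_equal(d$hbd[1], 0)
  expect_equal(d$rotb[1], 0)
  # ethanol: one O-H donor, one O acceptor, mass from standard atomic weights
  expect_equal(d$hbd[2], 1)
  expect_equal(d$hba[2], 1)
  expect_equal(d$mw[2], 46.07, tolerance = 0.01 / 46.07)
  # pyridine N accepts; pyrrole N donates its lone pair to the ring
  expect_equal(d$hba[3], 1)
  expect_equal(d$hba[4], 0)
  expect_equal(d$hbd[4], 1)
  # butane: one rotatable central bond
  expect_equal(d$rotb[5], 1)
})

test_that("descriptors are invariant to input atom ordering", {
  a <- compute_descriptors(tibble::tibble(compound_id = "m",
                                          smiles = "CC(=O)Oc1ccccc1C(=O)O"))
  b <- compute_descriptors(tibble::tibble(compound_id = "m",
                                          smiles = "OC(=O)c1ccccc1OC(C)=O"))
  expect_equal(a[, -1], b[, -1])
})

test_that("descriptor computation errors name the offending compound", {
  cmp <- tibble::tibble(compound_id = c("ok", "broken"),
                        smiles = c("CCO", "xx##"))
  expect_error(compute_descriptors(cmp), "broken")
})

test_that("structural alerts fire on known alerting groups and can be disabled", {
  cmp <- tibble::tibble(
    compound_id = c("nitrobenzene", "thiophenol", "anisole"),
    smiles = c("O=[N+]([O-])c1ccccc1", "Sc1ccccc1", "COc1ccccc1")
  )
  d <- compute_descriptors(cmp)
  expect_gte(d$alerts[1], 1)
  expect_gte(d$alerts[2], 1)
  expect_equal(d$alerts[3], 0)
  d0 <- compute_descriptors(cmp, alerts = FALSE)
  expect_equal(d0$alerts, c(0L, 0L, 0L))
})

test_that("rule violation counts follow the published conditions", {
  d <- tibble::tibble(compound_id = c("ethanol", "heavy", "floppy"),
                      mw = c(46.07, 600, 300), alogp = c(-0.1, 6, 1),
                      hba = c(1, 11, 4), hbd = c(1, 6, 1),
                      psa = c(20.2, 120, 150), rotb = c(0, 5, 11))
  v <- rule_violations(d)
  expect_equal(v$lipinski, c(0, 4, 0))
  expect_equal(v$veber, c(0, 0, 2))
  expect_equal(v$egan, c(0, 1, 1))
  # counts bounded by the number of conditions in each rule
  expect_true(all(v$lipinski <= 4) && all(v$ghose <= 4) &&
                all(v$veber <= 2) && all(v$egan <= 2) && all(v$muegge <= 9))
})

test_that("rule violations agree with direct evaluation on computed descriptors", {
  cmp <- tibble::tibble(compound_id = "aspirin",
                        smiles = "CC(=O)Oc1ccccc1C(=O)O")
  d <- compute_descriptors(cmp)
  v <- rule_violations(d)
  expect_equal(v$lipinski,
               sum(d$mw > 500, d$alogp > 5, d$hbd > 5, d$hba > 10))
  expect_equal(v$ghose,
               sum(d$mw < 160 | d$mw > 480, d$alogp < -0.4 | d$alogp > 5.6,
                   d$mr < 40 | d$mr > 130, d$natoms < 20 | d$natoms > 70))
})

test_that("descriptor tables read with alias renaming and quarantine bad rows", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("compound_id,molweight,cLogP,H.acceptors",
               "a,100,1.5,2", "b,200,NA,3", "c,300,2.5,4"), path)
  expect_message(tbl <- read_descriptor_table(path), "quarantined")
  expect_named(tbl, c("compound_id", "mw", "alogp", "hba"))
  expect_equal(nrow(tbl), 2)
  expect_equal(attr(tbl, "quarantine")$compound_id, "b")
  expect_match(attr(tbl, "quarantine")$reason, "alogp")

  # round trip
  out <- withr::local_tempfile(fileext = ".csv")
  write_descriptor_table(tbl, out)
  again <- read_descriptor_table(out)
  expect_equal(as.data.frame(again), as.data.frame(tbl),
               ignore_attr = TRUE)
})

test_that("standardization hits exact z-scores, drops constants, is idempotent", {
  tbl <- tibble::tibble(compound_id = c("a", "b", "c"),
                        x = c(1, 2, 3), flat = c(5, 5, 5))
  expect_warning(z <- standardize_descriptors(tbl), "flat")
  expect_equal(z$x, c(-1.224744871, 0, 1.224744871), tolerance = 1e-9)
  expect_false("flat" %in% names(z))
  z2 <- suppressWarnings(standardize_descriptors(z))
  expect_equal(z2$x, z$x, tolerance = 1e-9)
  expect_error(standardize_descriptors(tibble::tibble(a = c(1, 1))),
               "zero variance")
})

test_that("hba/hbd/psa/alogp stay near the backend oracle on random synthetic molecules", {
  lib <- generate_library(synth_spec(seed = 42, n_decoys = 50,
                                     n_analog_families = 0,
                                     analogs_per_family = 0))
  d <- compute_descriptors(lib)
  props <- ChemmineR::propOB(
    suppressWarnings(ChemmineR::smiles2sdf(
      stats::setNames(lib$smiles, lib$compound_id))))
  # counts agree exactly with an independent perception of the same graph
  expect_equal(d$hbd, props$HBD)
  expect_true(all(abs(d$psa - props$TPSA) <= 2))
  expect_true(all(abs(d$alogp - props$logP) <= 0.5))
  # HBA definitions differ across toolkits; demand close agreement
  expect_true(mean(abs(d$hba - props$HBA2) <= 1) >= 0.9)
})
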