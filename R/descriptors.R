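# Molecular descriptors: the eight QED inputs plus the auxiliary counts needed
# by the published drug-likeness rules, and ingestion of precomputed
# descriptor tables (DataWarrior-style column names accepted as aliases).
#
# Pinned conventions (the backend's and ours):
#  * HBA = N and O atoms that are not positively charged and not pyrrole-type
#    (aromatic N contributing its lone pair to the ring, i.e. three
#    substituents counting H).
#  * HBD = N or O atoms bearing at least one hydrogen, counted per heteroatom.
#  * ROTB = acyclic single bonds between two non-terminal heavy atoms (no
#    amide exclusion).
#  * AROM = aromatic bond count (the wording used by the screening protocol
#    this package implements); the aromatic ring count is also returned.
#  * PSA is the topological (fragment-contribution) polar surface area;
#    ALOGP is the backend's Crippen-type octanol-water partition estimate.

#' Default structural-alert patterns
#'
#' The curated structural-alert set shipped with the package: SMARTS patterns
#' covering the standard unwanted-functionality classes used in screening-
#' library triage (reactive groups, toxicophores, instability flags). The
#' ALERTS descriptor counts how many of these patterns match a molecule at
#' least once.
#'
#' @return A named character vector of SMARTS patterns.
#' @export
default_alert_patterns <- function() {
  path <- system.file("extdata", "structural_alerts.tsv",
                      package = "senoscreen", mustWork = TRUE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(df$smarts, df$alert)
}

#' Compute the QED descriptor vector for each compound
#'
#' Returns, per valid compound, the eight QED inputs (`mw`, `alogp`, `hba`,
#' `hbd`, `psa`, `rotb`, `arom`, `alerts`) plus auxiliary counts used by the
#' rule filters (`n_aromatic_rings`, `natoms`, `n_rings`, `n_carbon`,
#' `n_heteroatoms`, `mr`). Deterministic for a fixed canonical structure.
#'
#' @param compounds A compound tibble (see [read_compounds()]).
#' @param alerts If `FALSE`, skip SMARTS matching and set `alerts = 0` for
#'   every compound (strict emulation of protocols that ignore structural
#'   alerts).
#' @param alert_patterns Named character vector of SMARTS patterns; defaults
#'   to [default_alert_patterns()].
#' @return A tibble with one row per valid compound.
#' @export
compute_descriptors <- function(compounds, alerts = TRUE,
                                alert_patterns = default_alert_patterns()) {
  compounds <- .as_compound_tbl(compounds)
  bad <- compounds$compound_id[!compounds$valid]
  if (length(bad) > 0) {
    stop("cannot compute descriptors for unparseable compounds: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (nrow(compounds) == 0L) {
    stop("empty compound table", call. = FALSE)
  }

  graphs <- lapply(compounds$smiles, mol_graph)
  counts <- purrr::map_dfr(graphs, function(g) {
    a <- g$atoms
    pyrrole_n <- a$aromatic & a$element == "N" & (a$degree + a$n_h) == 3L
    hba <- sum(a$element %in% c("N", "O") & a$charge <= 0 & !pyrrole_n)
    hbd <- sum(a$element %in% c("N", "O") & a$n_h > 0)
    b <- g$bonds
    rotb <- sum(b$order == 1L & !b$in_ring &
                  a$degree[b$a1] >= 2L & a$degree[b$a2] >= 2L)
    tibble::tibble(
      hba = hba, hbd = hbd, rotb = rotb,
      arom = sum(b$aromatic),
      n_aromatic_rings = g$n_aromatic_rings,
      n_rings = g$n_rings,
      natoms = nrow(a) + sum(a$n_h),
      n_carbon = sum(a$element == "C"),
      n_heteroatoms = sum(!a$element %in% c("C", "H"))
    )
  })

  props <- .ob_properties(compounds$smiles, compounds$compound_id)

  alert_counts <- if (isTRUE(alerts)) {
    m <- .smarts_counts(compounds$smiles, compounds$compound_id,
                        as.list(alert_patterns))
    as.integer(rowSums(m > 0)[compounds$compound_id])
  } else {
    rep(0L, nrow(compounds))
  }

  tibble::tibble(
    compound_id = compounds$compound_id,
    mw = props$mw, alogp = props$alogp,
    hba = counts$hba, hbd = counts$hbd,
    psa = props$psa, rotb = counts$rotb, arom = counts$arom,
    alerts = alert_counts,
    n_aromatic_rings = counts$n_aromatic_rings,
    natoms = counts$natoms, n_rings = counts$n_rings,
    n_carbon = counts$n_carbon, n_heteroatoms = counts$n_heteroatoms,
    mr = props$mr
  )
}

#' Count violations of the published drug-likeness rules
#'
#' For each row of a descriptor table, counts the failed conditions of
#' Lipinski's rule of five (MW > 500, ALOGP > 5, HBD > 5, HBA > 10), the
#' Ghose filter (MW outside 160-480, ALOGP outside -0.4-5.6, molar
#' refractivity outside 40-130, atom count outside 20-70), the Veber rule
#' (ROTB > 10, PSA > 140), the Egan rule (ALOGP > 5.88, PSA > 131.6) and the
#' Muegge pharmacophore-point filter (MW outside 200-600, ALOGP outside
#' -2-5, PSA > 150, rings > 7, carbons < 5, heteroatoms < 2, ROTB > 15,
#' HBA > 10, HBD > 5). Conditions whose inputs are absent from the table are
#' counted as not violated (`NA`-safe), so the counts are lower bounds when
#' auxiliary columns are missing.
#'
#' @param descriptors A descriptor tibble (from [compute_descriptors()] or
#'   [read_descriptor_table()]).
#' @return A tibble with `compound_id` and counts `lipinski`, `ghose`,
#'   `veber`, `egan`, `muegge`.
#' @export
rule_violations <- function(descriptors) {
  d <- tibble::as_tibble(descriptors)
  n <- nrow(d)
  col <- function(nm) if (nm %in% names(d)) d[[nm]] else rep(NA_real_, n)
  viol <- function(...) {
    conds <- list(...)
    m <- matrix(vapply(conds, function(x) {
      x[is.na(x)] <- FALSE
      as.numeric(x)
    }, numeric(n)), nrow = n)
    rowSums(m)
  }
  mw <- col("mw"); alogp <- col("alogp"); hba <- col("hba"); hbd <- col("hbd")
  psa <- col("psa"); rotb <- col("rotb"); mr <- col("mr")
  natoms <- col("natoms"); n_rings <- col("n_rings")
  n_c <- col("n_carbon"); n_het <- col("n_heteroatoms")
  tibble::tibble(
    compound_id = if ("compound_id" %in% names(d)) d$compound_id
                  else as.character(seq_len(n)),
    lipinski = viol(mw > 500, alogp > 5, hbd > 5, hba > 10),
    ghose = viol(mw < 160 | mw > 480, alogp < -0.4 | alogp > 5.6,
                 mr < 40 | mr > 130, natoms < 20 | natoms > 70),
    veber = viol(rotb > 10, psa > 140),
    egan = viol(alogp > 5.88, psa > 131.6),
    muegge = viol(mw < 200 | mw > 600, alogp < -2 | alogp > 5, psa > 150,
                  n_rings > 7, n_c < 5, n_het < 2, rotb > 15,
                  hba > 10, hbd > 5)
  )
}

#' Column aliases accepted when reading descriptor tables
#'
#' Maps DataWarrior/SwissADME-style export column names onto the package's
#' descriptor names.
#'
#' @return A named character vector: `c(external_name = internal_name)`.
#' @export
descriptor_aliases <- function() {
  c(molweight = "mw", cLogP = "alogp", AlogP = "alogp",
    H.acceptors = "hba", H.Acceptors = "hba",
    H.donors = "hbd", H.Donors = "hbd",
    polar.surface.area = "psa", TPSA = "psa",
    rotatable.bonds = "rotb",
    aromatic.rings = "n_aromatic_rings",
    aromatic.atoms = "n_aromatic_atoms",
    natoms = "natoms", sp3.atoms = "n_sp3_atoms",
    total.surface.area = "tsa",
    electronegative.atoms = "n_heteroatoms",
    Lipinski..violations = "lipinski", Ghose..violations = "ghose",
    Veber..violations = "veber", Egan..violations = "egan",
    Muegge..violations = "muegge", nviolations = "nviolations")
}

#' Read a precomputed descriptor table
#'
#' Reads a CSV with one identifier column and numeric descriptor columns.
#' External column names are renamed through [descriptor_aliases()];
#' unrecognized columns are kept as-is (pass-through for proprietary scores).
#' Rows with any non-numeric (or missing) descriptor cell are quarantined:
#' removed from the returned table and attached, with reasons, as attribute
#' `quarantine`.
#'
#' @param path CSV path.
#' @param id_col Name of the identifier column. Default: `compound_id`, or
#'   the first column if no column is named `compound_id`.
#' @return A tibble whose first column is `compound_id`, all other columns
#'   numeric.
#' @export
read_descriptor_table <- function(path, id_col = NULL) {
  if (!file.exists(path)) stop("descriptor table not found: ", path,
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("descriptor table needs an ID column and at least ",
                          "one descriptor column", call. = FALSE)
  if (is.null(id_col)) {
    id_col <- if ("compound_id" %in% names(df)) "compound_id" else names(df)[1]
  }
  if (!id_col %in% names(df)) {
    stop("no ID column '", id_col, "' in descriptor table", call. = FALSE)
  }
  aliases <- descriptor_aliases()
  hit <- names(df) %in% names(aliases)
  names(df)[hit] <- unname(aliases[names(df)[hit]])

  ids <- as.character(df[[id_col]])
  vals <- df[, setdiff(names(df), id_col), drop = FALSE]
  num <- as.data.frame(suppressWarnings(lapply(vals, as.numeric)))
  bad_row <- rowSums(is.na(num)) > 0
  quarantine <- tibble::tibble(
    compound_id = ids[bad_row],
    reason = vapply(which(bad_row), function(i) {
      cols <- names(num)[is.na(num[i, ])]
      paste0("non-numeric value in: ", paste(cols, collapse = ", "))
    }, character(1))
  )
  out <- tibble::as_tibble(cbind(compound_id = ids[!bad_row],
                                 num[!bad_row, , drop = FALSE]))
  out$compound_id <- as.character(out$compound_id)
  if (nrow(quarantine) > 0) {
    message(nrow(quarantine), " descriptor rows quarantined (non-numeric cells)")
  }
  attr(out, "quarantine") <- quarantine
  out
}

#' Write a descriptor table to CSV
#'
#' @param descriptors Descriptor tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_descriptor_table <- function(descriptors, path) {
  utils::write.csv(as.data.frame(descriptors), path, row.names = FALSE)
  invisible(path)
}

#' Standardize a descriptor table (z-scores)
#'
#' Centers each numeric column to mean 0 and scales to unit standard
#' deviation. The population convention (divisor n, not n-1) is used, so a
#' column `c(1, 2, 3)` maps to `c(-1.2247, 0, 1.2247)`. Zero-variance columns
#' carry no clustering information and are dropped with a warning.
#' Idempotent up to numerical tolerance.
#'
#' @param descriptors A tibble with a `compound_id` column and numeric
#'   descriptor columns.
#' @return The standardized tibble. Attribute `dropped` names any
#'   zero-variance columns removed.
#' @export
standardize_descriptors <- function(descriptors) {
  d <- tibble::as_tibble(descriptors)
  if (nrow(d) < 2L) stop("need at least 2 rows to standardize", call. = FALSE)
  num_cols <- names(d)[vapply(d, is.numeric, logical(1))]
  if (length(num_cols) == 0L) stop("no numeric columns", call. = FALSE)
  pop_sd <- vapply(d[num_cols], function(x) {
    sqrt(mean((x - mean(x))^2))
  }, numeric(1))
  dead <- num_cols[pop_sd == 0]
  if (length(dead) == length(num_cols)) {
    stop("all descriptor columns have zero variance", call. = FALSE)
  }
  if (length(dead) > 0) {
    warning("dropping zero-variance columns: ", paste(dead, collapse = ", "),
            call. = FALSE)
    d <- d[, setdiff(names(d), dead), drop = FALSE]
    num_cols <- setdiff(num_cols, dead)
    pop_sd <- pop_sd[num_cols]
  }
  for (nm in num_cols) {
    d[[nm]] <- (d[[nm]] - mean(d[[nm]])) / pop_sd[[nm]]
  }
  attr(d, "dropped") <- dead
  d
}

# numeric matrix (rows named by compound_id) from a descriptor tibble
.descriptor_matrix <- function(descriptors) {
  d <- tibble::as_tibble(descriptors)
  num_cols <- names(d)[vapply(d, is.numeric, logical(1))]
  m <- as.matrix(d[, num_cols, drop = FALSE])
  rownames(m) <- if ("compound_id" %in% names(d)) d$compound_id
                 else as.character(seq_len(nrow(d)))
  m
}
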