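# Synthetic inputs for offline testing of every pipeline stage: molecule
# libraries with planted analog families, descriptor tables with realistic
# drug-like ranges, and binding/pathway tables with one planted multitarget
# winner.
#
# Molecules come from a fragment grammar (aryl/heteroaryl/cycloalkyl
# scaffold templates with substituents drawn from a drug-like fragment set),
# so every generated SMILES is chemically valid by construction - random
# character strings rarely parse. Analog families share a large
# (>= 13 heavy atoms) two-ring scaffold and differ from their parent by a
# single substituent edit, which keeps parent-analog Tanimoto similarity
# high while decoys, built on other scaffolds, stay dissimilar.

# two-slot scaffold templates reserved for analog families; three-ring
# scaffolds (~20 heavy atoms) keep the shared-path fraction high enough that
# a single substituent edit leaves parent-analog Tanimoto well above 0.6
.family_scaffolds <- c(
  "Cc1cc(%s)ccc1Cc1ccc(C(=O)Nc2cc(F)ccc2%s)cc1",
  "c1cc(%s)ccc1CCc1ccc(Oc2ncc(%s)cc2C)cc1",
  "c1cc(%s)ccc1C(=O)Nc1ccc(Cc2cc(C)ccc2%s)cc1",
  "Cc1cc(%s)ccc1Oc1ccc(C(=O)Nc2cc(C)ccc2%s)cc1"
)

# decoy scaffolds (distinct chemotypes)
.decoy_scaffolds <- c(
  "c1cc(%s)ccc1%s",                  # disubstituted benzene
  "c1cc(%s)oc1%s",                   # furan
  "c1cc(%s)sc1%s",                   # thiophene
  "C1CC(%s)CCC1%s",                  # cyclohexane
  "c1ccc2cc(%s)ccc2c1%s",            # naphthalene
  "C1CCN(%s)CC1%s"                   # piperidine
)

# drug-like substituents, valid as SMILES branch content
.substituents <- c("C", "CC", "O", "OC", "N", "NC", "F", "Cl", "C(=O)C",
                   "C(=O)OC", "C(=O)N", "C#N", "CO", "CCO", "N(C)C", "CN")

# single-heavy-atom substituents used for the analog edits, so a family
# differs from its parent by one small group on a large shared scaffold
.small_substituents <- c("C", "O", "N", "F", "Cl")

#' Specification for synthetic pipeline inputs
#'
#' Collects the knobs of the synthetic generator. Defaults describe the
#' screening conditions the package is tested under: a small natural-product-
#' sized decoy library, one planted family of close analogs of a lead, a
#' sparse binding table with one clear multitarget compound, and descriptor
#' ranges spanning the wide drug-like windows seen in natural-product
#' libraries.
#'
#' @param seed Integer seed; all generation is deterministic given it.
#' @param n_decoys Number of decoy molecules.
#' @param n_analog_families Number of planted analog families.
#' @param analogs_per_family Analogs derived from each family parent.
#' @param n_targets Number of protein targets in the binding universe.
#' @param planted_winner_targets Distinct targets given to the planted
#'   multitarget winner.
#' @param descriptor_ranges Named list of `c(low, high)` ranges for the
#'   eight QED descriptors.
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(seed = 1, n_decoys = 50, n_analog_families = 1,
                       analogs_per_family = 5, n_targets = 20,
                       planted_winner_targets = 6,
                       descriptor_ranges = NULL) {
  if (is.null(descriptor_ranges)) {
    descriptor_ranges <- list(
      mw = c(150, 800), alogp = c(-2, 8), hba = c(0, 12), hbd = c(0, 8),
      psa = c(10, 220), rotb = c(0, 15), arom = c(0, 15), alerts = c(0, 3)
    )
  }
  counts <- c(n_decoys, n_analog_families, analogs_per_family, n_targets,
              planted_winner_targets)
  if (any(counts < 0)) stop("all counts must be >= 0", call. = FALSE)
  if (analogs_per_family > 0 && n_analog_families == 0) {
    stop("analogs requested without any analog family", call. = FALSE)
  }
  if (planted_winner_targets > n_targets) {
    stop("planted_winner_targets cannot exceed n_targets", call. = FALSE)
  }
  bad <- names(descriptor_ranges)[vapply(descriptor_ranges, function(r) {
    r[1] >= r[2]
  }, logical(1))]
  if (length(bad)) stop("descriptor ranges need low < high: ",
                        paste(bad, collapse = ", "), call. = FALSE)
  structure(list(seed = seed, n_decoys = n_decoys,
                 n_analog_families = n_analog_families,
                 analogs_per_family = analogs_per_family,
                 n_targets = n_targets,
                 planted_winner_targets = planted_winner_targets,
                 descriptor_ranges = descriptor_ranges),
            class = "synth_spec")
}

#' Generate a synthetic molecule library with planted analog families
#'
#' @param spec A [synth_spec()].
#' @return A compound tibble with attribute `truth`: a tibble mapping each
#'   `compound_id` to its `role` (`decoy`, `parent`, `analog`) and `family`.
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  withr::with_seed(spec$seed, {
    rows <- list()
    for (f in seq_len(spec$n_analog_families)) {
      scaffold <- .family_scaffolds[((f - 1) %% length(.family_scaffolds)) + 1]
      subs <- c(sample(.substituents, 1), sample(.small_substituents, 1))
      parent <- sprintf(scaffold, subs[1], subs[2])
      rows[[length(rows) + 1]] <- tibble::tibble(
        compound_id = sprintf("FAM%d_PARENT", f), smiles = parent,
        role = "parent", family = f
      )
      alts <- sample(setdiff(.small_substituents, subs[2]),
                     spec$analogs_per_family,
                     replace = spec$analogs_per_family >
                       length(.small_substituents) - 1)
      for (a in seq_len(spec$analogs_per_family)) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          compound_id = sprintf("FAM%d_A%02d", f, a),
          smiles = sprintf(scaffold, subs[1], alts[a]),
          role = "analog", family = f
        )
      }
    }
    for (i in seq_len(spec$n_decoys)) {
      scaffold <- sample(.decoy_scaffolds, 1)
      subs <- sample(.substituents, 2)
      rows[[length(rows) + 1]] <- tibble::tibble(
        compound_id = sprintf("DECOY%03d", i),
        smiles = sprintf(scaffold, subs[1], subs[2]),
        role = "decoy", family = NA_integer_
      )
    }
    all <- dplyr::bind_rows(rows)
    out <- tibble::tibble(
      compound_id = all$compound_id, name = all$compound_id,
      smiles = all$smiles, source = "synthetic",
      valid = TRUE, parse_error = NA_character_
    )
    attr(out, "truth") <- all[, c("compound_id", "role", "family")]
    out
  })
}

#' Generate a synthetic descriptor table
#'
#' Uniform draws within the spec's per-descriptor ranges; count-valued
#' columns (`hba`, `hbd`, `rotb`, `arom`, `alerts`) are rounded to integers.
#'
#' @param spec A [synth_spec()].
#' @param n Number of rows.
#' @param ids Optional compound ids (default `SYN0001` ...).
#' @return A descriptor tibble.
#' @export
generate_descriptor_table <- function(spec, n, ids = NULL) {
  stopifnot(inherits(spec, "synth_spec"))
  if (is.null(ids)) ids <- sprintf("SYN%04d", seq_len(n))
  stopifnot(length(ids) == n)
  withr::with_seed(spec$seed + 1L, {
    out <- tibble::tibble(compound_id = ids)
    ints <- c("hba", "hbd", "rotb", "arom", "alerts")
    for (nm in names(spec$descriptor_ranges)) {
      r <- spec$descriptor_ranges[[nm]]
      x <- stats::runif(n, r[1], r[2])
      out[[nm]] <- if (nm %in% ints) round(x) else x
    }
    out
  })
}

#' Generate synthetic binding records and pathway gene sets
#'
#' Background compounds receive 0-2 random targets; the planted winner
#' receives `planted_winner_targets` distinct targets of which at least two
#' (three when available) belong to senescence pathway gene sets, so
#' [rank_multitarget()] must place it first.
#'
#' @param spec A [synth_spec()].
#' @param compound_ids Compound ids in the binding universe.
#' @param winner_id The planted winner (must be in `compound_ids`).
#' @return A list: `bindings`, `pathways`, `truth` (list with `winner_id`,
#'   `winner_targets`, `winner_senescence_targets`).
#' @export
generate_binding_and_pathways <- function(spec, compound_ids, winner_id) {
  stopifnot(inherits(spec, "synth_spec"), length(compound_ids) >= 1,
            winner_id %in% compound_ids)
  withr::with_seed(spec$seed + 2L, {
    targets <- sprintf("T%03d", seq_len(spec$n_targets))
    codes <- c("CC", "OSIS", "DDR")
    n_pw <- min(6L, spec$n_targets)
    pw_targets <- targets[seq_len(n_pw)]
    pathways <- tibble::tibble(
      pathway_code = codes[((seq_len(n_pw)) - 1L) %% length(codes) + 1L],
      gene = pw_targets
    )
    n_sen <- min(3L, spec$planted_winner_targets, n_pw)
    winner_sen <- sample(pw_targets, n_sen)
    pool <- setdiff(targets, winner_sen)
    winner_rest <- sample(pool, spec$planted_winner_targets - n_sen)
    winner_targets <- c(winner_sen, winner_rest)

    rows <- list(tibble::tibble(compound_id = winner_id,
                                target_symbol = winner_targets,
                                interaction = "inhibitor"))
    for (id in setdiff(compound_ids, winner_id)) {
      k <- sample(0:2, 1)
      if (k > 0) {
        rows[[length(rows) + 1]] <- tibble::tibble(
          compound_id = id, target_symbol = sample(targets, k),
          interaction = "modulator"
        )
      }
    }
    list(
      bindings = dplyr::bind_rows(rows),
      pathways = pathways,
      truth = list(winner_id = winner_id,
                   winner_targets = sort(winner_targets),
                   winner_senescence_targets = sort(winner_sen))
    )
  })
}

#' Write a full set of synthetic pipeline inputs to a directory
#'
#' Generates a library (first family parent = the lead), a binding table in
#' which one analog of the lead is the planted multitarget winner, pathway
#' gene sets, and the ground truth, and writes them as plain-text files:
#' `library.csv`, `bindings.csv`, `pathways.csv`, `truth.json`.
#'
#' @param spec A [synth_spec()] with at least one analog family.
#' @param dir Output directory (created if needed).
#' @return Invisibly, a list with the generated objects and file paths.
#' @export
generate_pipeline_inputs <- function(spec, dir) {
  stopifnot(inherits(spec, "synth_spec"), spec$n_analog_families >= 1,
            spec$analogs_per_family >= 1)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lib <- generate_library(spec)
  truth <- attr(lib, "truth")
  winner <- truth$compound_id[truth$role == "analog"][1]
  candidates <- lib$compound_id[lib$compound_id != "FAM1_PARENT"]
  bp <- generate_binding_and_pathways(spec, candidates, winner)

  paths <- list(
    library = file.path(dir, "library.csv"),
    bindings = file.path(dir, "bindings.csv"),
    pathways = file.path(dir, "pathways.csv"),
    truth = file.path(dir, "truth.json")
  )
  write_compounds(lib, paths$library)
  utils::write.csv(as.data.frame(bp$bindings), paths$bindings,
                   row.names = FALSE)
  utils::write.csv(as.data.frame(bp$pathways), paths$pathways,
                   row.names = FALSE)
  jsonlite::write_json(
    list(lead_id = "FAM1_PARENT",
         winner = bp$truth,
         roles = truth),
    paths$truth, auto_unbox = TRUE
  )
  invisible(list(library = lib, truth = truth, bindings = bp$bindings,
                 pathways = bp$pathways, winner = bp$truth, paths = paths))
}
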