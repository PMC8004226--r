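# Low-level molecule perception over the ChemmineR/OpenBabel backend.
# Everything downstream (descriptors, fingerprints) consumes the graph
# representation built here, so perception conventions are pinned in one place:
# kekulized bond orders from the SDF block, aromaticity from smallest-set ring
# perception, implicit hydrogens from a standard-valence model.

# per-session cache: SMILES string -> parsed graph (parsing via OpenBabel is
# the hot spot when fingerprinting the same molecule against many leads)
.mol_cache <- new.env(parent = emptyenv())

#' Canonical SMILES via the perception backend
#'
#' Returns the backend's canonical SMILES for each input, or `NA` for strings
#' the backend cannot parse. Stereochemistry descriptors are preserved in the
#' canonical string but ignored by [fingerprint_compounds()].
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector, `NA` where unparseable.
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    out <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", source = paste0(s, "\n")),
      error = function(e) ""
    )
    line <- strsplit(out, "\n", fixed = TRUE)[[1]][1]
    if (is.na(line)) return(NA_character_)
    can <- sub("[\t ].*$", "", line)
    if (nzchar(can)) can else NA_character_
  }, character(1), USE.NAMES = FALSE)
}

#' Canonical structure key (largest fragment, salt-stripped)
#'
#' The registry identity of a structure: canonical SMILES of the largest
#' covalent fragment (by heavy-atom count; ties broken toward the
#' lexicographically smaller canonical SMILES). Counter-ions and solvent
#' fragments are thereby ignored when detecting repeated molecules.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of keys, `NA` where unparseable.
#' @export
structure_key <- function(smiles) {
  vapply(smiles, function(s) {
    can <- canonical_smiles(s)
    if (is.na(can)) return(NA_character_)
    frags <- strsplit(can, ".", fixed = TRUE)[[1]]
    if (length(frags) == 1L) return(can)
    sizes <- vapply(frags, .heavy_atom_count, numeric(1))
    frags <- frags[order(-sizes, frags)]
    canonical_smiles(frags[1])
  }, character(1), USE.NAMES = FALSE)
}

# heavy atoms in a SMILES fragment, counted by parsing it
.heavy_atom_count <- function(smiles) {
  g <- tryCatch(mol_graph(smiles), error = function(e) NULL)
  if (is.null(g)) return(0)
  nrow(g$atoms)
}

# standard valences for implicit-H assignment; elements not listed get 0
# implicit hydrogens (metals, noble gases, already-saturated bracket atoms)
.std_valence <- c(
  B = 3, C = 4, N = 3, O = 2, F = 1, Si = 4, P = 3, S = 2,
  Cl = 1, Br = 1, I = 1
)

#' Molecular graph of a single structure
#'
#' Parses one SMILES and returns the heavy-atom graph used by the descriptor
#' and fingerprint code: an `atoms` tibble (element, formal charge, aromatic
#' flag, ring-membership flag, implicit hydrogen count, heavy-atom degree) and
#' a `bonds` tibble (kekulized order, aromatic flag, ring flag), plus the
#' number of aromatic rings under smallest-ring perception.
#'
#' @param smiles A single SMILES string.
#' @return A list with elements `atoms`, `bonds`, `n_aromatic_rings`.
#' @export
mol_graph <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  hit <- get0(smiles, envir = .mol_cache, inherits = FALSE)
  if (!is.null(hit)) return(hit)

  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles, "m"))),
    error = function(e) NULL
  )
  if (is.null(sdf) || length(sdf) == 0L) {
    stop("SMILES could not be parsed by the molecule-perception backend: ",
         smiles, call. = FALSE)
  }
  mol <- sdf[[1]]
  ab <- ChemmineR::atomblock(mol)
  bb <- ChemmineR::bondblock(mol)

  elements <- sub("_\\d+$", "", rownames(ab))
  n_atoms <- length(elements)
  charge_code <- if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, n_atoms)
  charge <- ifelse(charge_code %in% 1:7 & charge_code != 4,
                   4 - charge_code, 0L)

  if (is.null(dim(bb)) && length(bb) > 0) bb <- matrix(bb, nrow = 1,
                                                       dimnames = list(NULL, names(bb)))
  # bond-free molecules come back as a 2-column placeholder block
  n_bonds <- if (is.null(bb) || ncol(bb) < 3) 0L else nrow(bb)
  a1 <- if (n_bonds) as.integer(bb[, 1]) else integer(0)
  a2 <- if (n_bonds) as.integer(bb[, 2]) else integer(0)
  order <- if (n_bonds) as.integer(bb[, 3]) else integer(0)

  # ring and aromaticity perception (smallest rings only, so fused-system
  # envelope cycles are not double counted)
  ring_info <- tryCatch(
    ChemmineR::rings(sdf[1], upper = Inf, type = "all", arom = TRUE,
                     inner = TRUE),
    error = function(e) list(RINGS = list(), AROMATIC = logical(0))
  )
  rings <- ring_info$RINGS
  arom_flags <- ring_info$AROMATIC
  if (is.null(rings)) rings <- list()
  if (is.null(arom_flags)) arom_flags <- rep(FALSE, length(rings))

  atom_index <- stats::setNames(seq_len(n_atoms), rownames(ab))
  in_ring <- rep(FALSE, n_atoms)
  aromatic_atom <- rep(FALSE, n_atoms)
  bond_key <- function(i, j) paste(pmin(i, j), pmax(i, j))
  ring_bonds <- character(0)
  aromatic_bonds <- character(0)
  for (ri in seq_along(rings)) {
    idx <- unname(atom_index[rings[[ri]]])
    in_ring[idx] <- TRUE
    pairs <- bond_key(idx, c(idx[-1], idx[1]))
    ring_bonds <- c(ring_bonds, pairs)
    if (isTRUE(arom_flags[ri])) {
      aromatic_atom[idx] <- TRUE
      aromatic_bonds <- c(aromatic_bonds, pairs)
    }
  }
  bkeys <- bond_key(a1, a2)
  bond_in_ring <- bkeys %in% ring_bonds
  bond_aromatic <- bkeys %in% aromatic_bonds

  degree <- tabulate(c(a1, a2), nbins = n_atoms)
  bond_order_sum <- vapply(seq_len(n_atoms), function(i) {
    sum(order[a1 == i | a2 == i])
  }, numeric(1))
  valence <- unname(.std_valence[elements])
  valence[is.na(valence)] <- 0
  eff_valence <- ifelse(elements == "C", valence - abs(charge),
                        valence + charge)
  # hypervalent S/P (sulfones, phosphates) carry no implicit H anyway
  n_h <- pmax(0L, as.integer(round(eff_valence - bond_order_sum)))
  n_h[valence == 0] <- 0L

  g <- list(
    atoms = tibble::tibble(
      idx = seq_len(n_atoms),
      element = elements,
      charge = as.integer(charge),
      aromatic = aromatic_atom,
      in_ring = in_ring,
      n_h = n_h,
      degree = as.integer(degree)
    ),
    bonds = tibble::tibble(
      a1 = a1, a2 = a2, order = order,
      aromatic = bond_aromatic, in_ring = bond_in_ring
    ),
    n_aromatic_rings = sum(arom_flags),
    n_rings = length(rings)
  )
  assign(smiles, g, envir = .mol_cache)
  g
}

# OpenBabel whole-molecule properties (MW, logP, TPSA, molar refractivity)
# for a named SMILES vector; unparseable entries come back as NA rows.
.ob_properties <- function(smiles, ids) {
  res <- tibble::tibble(
    compound_id = ids,
    mw = NA_real_, alogp = NA_real_, psa = NA_real_, mr = NA_real_
  )
  for (i in seq_along(smiles)) {
    sdf <- tryCatch(
      suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles[i], ids[i]))),
      error = function(e) NULL
    )
    if (is.null(sdf) || length(sdf) == 0L) next
    p <- tryCatch(ChemmineR::propOB(sdf), error = function(e) NULL)
    if (is.null(p) || nrow(p) == 0L) next
    res$mw[i] <- p$MW[1]
    res$alogp[i] <- p$logP[1]
    res$psa[i] <- p$TPSA[1]
    res$mr[i] <- p$MR[1]
  }
  res
}

# SMARTS match counts over a set of molecules (OpenBabel matcher);
# returns an integer matrix [molecule x pattern]
.smarts_counts <- function(smiles, ids, patterns) {
  out <- matrix(0L, nrow = length(smiles), ncol = length(patterns),
                dimnames = list(ids, names(patterns)))
  parsed <- !is.na(smiles)
  if (!any(parsed)) return(out)
  sdf <- tryCatch(
    suppressWarnings(ChemmineR::smiles2sdf(stats::setNames(smiles[parsed],
                                                           ids[parsed]))),
    error = function(e) NULL
  )
  if (is.null(sdf) || length(sdf) == 0L) return(out)
  kept <- ChemmineR::cid(sdf)
  for (j in seq_along(patterns)) {
    counts <- tryCatch(
      suppressWarnings(ChemmineR::smartsSearchOB(sdf, patterns[[j]],
                                                 uniqueMatches = TRUE)),
      error = function(e) stats::setNames(rep(0L, length(kept)), kept)
    )
    out[names(counts), j] <- as.integer(counts)
  }
  out
}
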