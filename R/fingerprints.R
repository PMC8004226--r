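# Hashed path fingerprints ("extended": atom paths plus ring/atomic
# properties) and Tanimoto similarity.
#
# The fingerprint is fully pinned so bits are reproducible across platforms:
#  * features = all simple atom paths of 0..max_path_length bonds (a single
#    atom is the 0-bond path);
#  * atom invariant = (element, aromatic flag, in-ring flag, formal charge),
#    bond invariant = kekulized order or "a" for aromatic bonds;
#  * the path string is the lexicographically smaller of the two traversal
#    directions;
#  * each distinct path string is hashed with 32-bit FNV-1a; bit index =
#    hash mod n_bits. Stereochemistry is ignored.

# 32-bit FNV-1a over the UTF-8 bytes of a string, in exact double arithmetic
.fnv1a32 <- function(s) {
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    h0 <- h %% 65536
    h <- (h - h0) + bitwXor(h0, b)          # xor touches the low byte only
    h1 <- h %/% 65536; h0 <- h %% 65536     # multiply mod 2^32
    h <- (((h1 * 16777619) %% 65536) * 65536 + h0 * 16777619) %% 4294967296
  }
  h
}

# canonical path strings of one molecule graph
.mol_path_features <- function(g, max_path_length = 6) {
  a <- g$atoms
  atok <- paste0(a$element,
                 ifelse(a$aromatic, ":ar", ""),
                 ifelse(a$in_ring, ":R", ""),
                 ifelse(a$charge != 0, sprintf("%+d", a$charge), ""))
  n <- nrow(a)
  adj <- vector("list", n)
  b <- g$bonds
  if (nrow(b) > 0) {
    btok <- ifelse(b$aromatic, "a", as.character(b$order))
    for (k in seq_len(nrow(b))) {
      adj[[b$a1[k]]] <- c(adj[[b$a1[k]]], list(c(b$a2[k], btok[k])))
      adj[[b$a2[k]]] <- c(adj[[b$a2[k]]], list(c(b$a1[k], btok[k])))
    }
  }
  acc <- new.env(parent = emptyenv()); acc$out <- character(0)
  dfs <- function(cur, visited, toks, n_bonds) {
    fwd <- paste(toks, collapse = "|")
    rev_ <- paste(rev(toks), collapse = "|")
    acc$out <- c(acc$out, if (fwd <= rev_) fwd else rev_)
    if (n_bonds >= max_path_length) return(invisible())
    for (nb in adj[[cur]]) {
      nxt <- as.integer(nb[1])
      if (!(nxt %in% visited)) {
        dfs(nxt, c(visited, nxt), c(toks, nb[2], atok[nxt]), n_bonds + 1L)
      }
    }
  }
  for (i in seq_len(n)) dfs(i, i, atok[i], 0L)
  unique(acc$out)
}

#' Compute extended path fingerprints
#'
#' Fingerprints every valid compound of a compound table. Bit-deterministic:
#' the same canonical structure yields the same bits on any platform.
#'
#' @param compounds A compound tibble, or a character vector of SMILES.
#' @param n_bits Fingerprint length; one of 512, 1024 (default), 2048.
#' @param max_path_length Maximum path length in bonds (default 6).
#' @return A tibble with `compound_id`, `n_bits`, `n_bits_set` and a
#'   list-column `bits` of sorted 0-based set-bit positions.
#' @export
fingerprint_compounds <- function(compounds, n_bits = 1024,
                                  max_path_length = 6) {
  if (!n_bits %in% c(512, 1024, 2048)) {
    stop("n_bits must be one of 512, 1024, 2048", call. = FALSE)
  }
  if (is.character(compounds)) {
    ids <- if (!is.null(names(compounds))) names(compounds)
           else as.character(seq_along(compounds))
    compounds <- tibble::tibble(compound_id = ids, smiles = compounds)
  }
  compounds <- .as_compound_tbl(compounds)
  bad <- compounds$compound_id[!compounds$valid]
  if (length(bad) > 0) {
    stop("cannot fingerprint unparseable compounds: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  # canonicalize first so input atom order cannot leak into the bits
  can <- if ("canonical_smiles" %in% names(compounds)) {
    compounds$canonical_smiles
  } else {
    canonical_smiles(compounds$smiles)
  }
  bits <- lapply(can, function(s) {
    feats <- .mol_path_features(mol_graph(s), max_path_length)
    sort(unique(vapply(feats, .fnv1a32, numeric(1)) %% n_bits))
  })
  tibble::tibble(
    compound_id = compounds$compound_id,
    n_bits = as.integer(n_bits),
    n_bits_set = lengths(bits),
    bits = lapply(bits, as.integer)
  )
}

#' Tanimoto coefficient of two bit sets
#'
#' `|A and B| / |A or B|` on set-bit positions. Two all-zero fingerprints
#' give 0 with a warning: featureless records should not look identical.
#'
#' @param a,b Integer vectors of set-bit positions (rows of the `bits`
#'   column of [fingerprint_compounds()] output).
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  if (length(a) == 0 && length(b) == 0) {
    warning("both fingerprints are empty; Tanimoto defined as 0",
            call. = FALSE)
    return(0)
  }
  n_and <- length(intersect(a, b))
  n_or <- length(a) + length(b) - n_and
  n_and / n_or
}

#' Tanimoto distance matrix of a fingerprint table
#'
#' `d[i, j] = 1 - tanimoto(i, j)`: the Jaccard distance, a metric on bit
#' sets. Rows/columns are named by `compound_id`.
#'
#' @param fps Fingerprint tibble from [fingerprint_compounds()].
#' @return A symmetric numeric matrix with zero diagonal.
#' @export
tanimoto_distance_matrix <- function(fps) {
  fps <- tibble::as_tibble(fps)
  n <- nrow(fps)
  if (n < 2L) stop("need at least 2 fingerprints", call. = FALSE)
  if (length(unique(fps$n_bits)) != 1L) {
    stop("fingerprints have differing bit lengths", call. = FALSE)
  }
  d <- matrix(0, n, n, dimnames = list(fps$compound_id, fps$compound_id))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- 1 - tanimoto(fps$bits[[i]], fps$bits[[j]])
    }
  }
  d
}

#' Serialize fingerprints to hex strings
#'
#' @param fps Fingerprint tibble.
#' @return A tibble with `compound_id`, `n_bits`, `hex` (little-endian
#'   nibbles: hex digit k encodes bits 4k..4k+3).
#' @export
fingerprints_to_hex <- function(fps) {
  fps <- tibble::as_tibble(fps)
  hex <- vapply(seq_len(nrow(fps)), function(i) {
    nb <- fps$n_bits[i]
    v <- integer(nb / 4)
    for (b in fps$bits[[i]]) {
      k <- b %/% 4
      v[k + 1] <- v[k + 1] + 2^(b %% 4)
    }
    paste(format.hexmode(v), collapse = "")
  }, character(1))
  tibble::tibble(compound_id = fps$compound_id, n_bits = fps$n_bits,
                 hex = hex)
}

#' Parse hex-serialized fingerprints
#'
#' Inverse of [fingerprints_to_hex()].
#'
#' @param hex_tbl Tibble with `compound_id`, `n_bits`, `hex`.
#' @return A fingerprint tibble.
#' @export
fingerprints_from_hex <- function(hex_tbl) {
  hex_tbl <- tibble::as_tibble(hex_tbl)
  bits <- lapply(seq_len(nrow(hex_tbl)), function(i) {
    v <- strtoi(strsplit(hex_tbl$hex[i], "")[[1]], base = 16L)
    out <- integer(0)
    for (k in seq_along(v)) {
      for (p in 0:3) {
        if (bitwAnd(v[k], bitwShiftL(1L, p)) != 0) {
          out <- c(out, (k - 1L) * 4L + p)
        }
      }
    }
    out
  })
  tibble::tibble(compound_id = hex_tbl$compound_id,
                 n_bits = as.integer(hex_tbl$n_bits),
                 n_bits_set = lengths(bits), bits = bits)
}
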