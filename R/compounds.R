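# Compound library I/O and the deduplicated registry.
#
# A compound table is an ordinary tibble with columns
#   compound_id, name, smiles, source, valid, parse_error
# plus, after canonicalize_compounds(), canonical_smiles and structure_key.
# Invalid records are never silently dropped: they stay in the table flagged
# `valid = FALSE` (the quarantine), and downstream stages work on the valid
# subset.

.compound_cols <- c("compound_id", "name", "smiles", "source")

#' Read a compound library
#'
#' Reads a compound library from CSV (`compound_id`, `smiles`, optional
#' `name`, `source` columns), a SMILES file (one record per line: SMILES,
#' whitespace, then an identifier), or an SDF (V2000). Records whose SMILES
#' the perception backend cannot parse are flagged `valid = FALSE` with the
#' reason in `parse_error`; they are counted, reported, and retained.
#'
#' @param path Path to the library file.
#' @param format `"auto"` (by extension), `"csv"`, `"smiles"`, or `"sdf"`.
#' @param source Library tag recorded for every compound (defaults to the
#'   file name).
#' @return A compound tibble. Attribute `n_invalid` carries the number of
#'   unparseable records.
#' @export
read_compounds <- function(path, format = c("auto", "csv", "smiles", "sdf"),
                           source = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("compound library file not found: ", path, call. = FALSE)
  }
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext,
      csv = "csv", smi = "smiles", smiles = "smiles", sdf = "sdf",
      stop("cannot infer library format from extension: ", ext, call. = FALSE)
    )
  }
  if (is.null(source)) source <- basename(path)

  tbl <- switch(format,
    csv = {
      df <- utils::read.csv(path, stringsAsFactors = FALSE,
                            check.names = FALSE)
      need <- c("compound_id", "smiles")
      if (!all(need %in% names(df))) {
        stop("csv library must have columns compound_id and smiles",
             call. = FALSE)
      }
      tibble::tibble(
        compound_id = as.character(df$compound_id),
        name = if ("name" %in% names(df)) as.character(df$name)
               else as.character(df$compound_id),
        smiles = as.character(df$smiles),
        source = if ("source" %in% names(df)) as.character(df$source)
                 else source
      )
    },
    smiles = {
      lines <- readLines(path, warn = FALSE)
      lines <- lines[nzchar(trimws(lines))]
      parts <- strsplit(trimws(lines), "[ \t]+")
      tibble::tibble(
        smiles = vapply(parts, `[`, character(1), 1),
        compound_id = vapply(parts, function(p) {
          if (length(p) >= 2) p[2] else p[1]
        }, character(1)),
        name = vapply(parts, function(p) {
          if (length(p) >= 2) p[2] else p[1]
        }, character(1)),
        source = source
      )[, .compound_cols]
    },
    sdf = {
      sdf <- ChemmineR::read.SDFset(path)
      ids <- ChemmineR::sdfid(sdf)
      smi <- tryCatch(
        as.character(ChemmineR::sdf2smiles(sdf)),
        error = function(e) rep(NA_character_, length(sdf))
      )
      tibble::tibble(compound_id = as.character(ids),
                     name = as.character(ids),
                     smiles = smi, source = source)
    }
  )

  if (anyDuplicated(tbl$compound_id)) {
    dups <- unique(tbl$compound_id[duplicated(tbl$compound_id)])
    stop("duplicate compound_id values in library: ",
         paste(dups, collapse = ", "), call. = FALSE)
  }

  can <- canonical_smiles(tbl$smiles)
  tbl$valid <- !is.na(can)
  tbl$parse_error <- ifelse(tbl$valid, NA_character_,
                            "SMILES not parseable by backend")
  n_invalid <- sum(!tbl$valid)
  if (sum(tbl$valid) == 0L) {
    stop("no parseable records in library: ", path, call. = FALSE)
  }
  if (n_invalid > 0) {
    message(n_invalid, " of ", nrow(tbl),
            " records could not be parsed and were quarantined")
  }
  attr(tbl, "n_invalid") <- n_invalid
  tbl
}

#' Canonicalize a compound table
#'
#' Adds `canonical_smiles` (backend canonical form) and `structure_key`
#' (canonical SMILES of the largest covalent fragment after salt stripping,
#' the identity used for duplicate detection) to every valid record.
#'
#' @param compounds A compound tibble.
#' @return The tibble with `canonical_smiles` and `structure_key` columns.
#' @export
canonicalize_compounds <- function(compounds) {
  compounds <- .as_compound_tbl(compounds)
  compounds$canonical_smiles <- canonical_smiles(compounds$smiles)
  compounds$structure_key <- structure_key(compounds$smiles)
  compounds$valid <- compounds$valid & !is.na(compounds$structure_key)
  compounds
}

#' De-duplicate a compound table by canonical structure
#'
#' Keeps the first-seen record per canonical structure key. The mapping from
#' dropped to kept identifiers is attached as attribute `dedup_map`
#' (a tibble with columns `compound_id`, `kept_id`, one row per input record).
#' Idempotent. Invalid records are dropped here (they have no structure key)
#' after being counted.
#'
#' @param compounds A compound tibble (canonicalized first if needed).
#' @return The deduplicated tibble, insertion order preserved.
#' @export
dedup_compounds <- function(compounds) {
  compounds <- .as_compound_tbl(compounds)
  if (nrow(compounds) == 0L) {
    attr(compounds, "dedup_map") <-
      tibble::tibble(compound_id = character(0), kept_id = character(0))
    return(compounds)
  }
  if (!"structure_key" %in% names(compounds)) {
    compounds <- canonicalize_compounds(compounds)
  }
  valid <- compounds[compounds$valid, , drop = FALSE]
  first_idx <- !duplicated(valid$structure_key)
  firsts <- valid[first_idx, , drop = FALSE]
  kept_for <- firsts$compound_id[match(valid$structure_key,
                                       firsts$structure_key)]
  map <- tibble::tibble(compound_id = valid$compound_id, kept_id = kept_for)
  out <- valid[first_idx, , drop = FALSE]
  attr(out, "dedup_map") <- map
  out
}

#' Write a compound table to CSV
#'
#' @param compounds A compound tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_compounds <- function(compounds, path) {
  utils::write.csv(as.data.frame(compounds), path, row.names = FALSE,
                   na = "")
  invisible(path)
}

#' Quarantined (unparseable) records of a compound table
#'
#' @param compounds A compound tibble.
#' @return The subset with `valid = FALSE`.
#' @export
quarantined_compounds <- function(compounds) {
  compounds <- .as_compound_tbl(compounds)
  compounds[!compounds$valid, , drop = FALSE]
}

# coerce a bare data frame (compound_id + smiles at minimum) into the
# standard compound tibble shape
.as_compound_tbl <- function(x) {
  stopifnot(is.data.frame(x))
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0L) {
    if (!"valid" %in% names(x)) x$valid <- logical(0)
    return(x)
  }
  if (!all(c("compound_id", "smiles") %in% names(x))) {
    stop("a compound table needs compound_id and smiles columns",
         call. = FALSE)
  }
  x$compound_id <- as.character(x$compound_id)
  if (!"name" %in% names(x)) x$name <- x$compound_id
  if (!"source" %in% names(x)) x$source <- "user"
  if (!"valid" %in% names(x)) x$valid <- !is.na(canonical_smiles(x$smiles))
  if (!"parse_error" %in% names(x)) {
    x$parse_error <- ifelse(x$valid, NA_character_, "SMILES not parseable")
  }
  x
}
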