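#' Read a compound collection from a SMILES or SDF file
#'
#' Parses a compound library into a collection tibble with one row per
#' record. SMILES files hold one whitespace-separated `SMILES id` pair per
#' line; lines starting with `#` are ignored. SDF files are V2000, with the
#' molecule title line used as the identifier. Every structure is
#' canonicalized with OpenBabel; records that fail to parse are counted,
#' reported, and excluded unless `keep_failures = TRUE`.
#'
#' @param path Path to the input file.
#' @param format `"smiles"` or `"sdf"`. Defaults to a guess from the file
#'   extension (`.smi`/`.smiles` vs `.sdf`).
#' @param name Dataset label stored in the `source` column (defaults to the
#'   file name without extension).
#' @param keep_failures Keep unparsable records (with `parse_ok = FALSE` and
#'   `NA` structure) instead of dropping them.
#' @return A tibble with columns `id`, `smiles` (canonical), `source`, and
#'   `parse_ok`, carrying the dataset label as the `"name"` attribute.
#' @examples
#' \donttest{
#' tf <- tempfile(fileext = ".smi")
#' writeLines(c("c1ccccc1 benzene", "CCO ethanol"), tf)
#' read_collection(tf, name = "demo")
#' }
#' @export
read_collection <- function(path, format = NULL, name = NULL,
                            keep_failures = FALSE) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("Input file does not exist: '%s'", path))
  }
  format <- format %||%
    (if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "smiles")
  format <- match.arg(format, c("smiles", "sdf"))
  name <- name %||% sub("\\.[^.]*$", "", basename(path))

  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    smi <- sub("[ \t].*$", "", lines)
    id <- trimws(sub("^[^ \t]+", "", lines))
    id[!nzchar(id)] <- paste0("mol_", which(!nzchar(id)))
  } else {
    txt <- readLines(path, warn = FALSE)
    recs <- split(txt, cumsum(c(1, head(txt, -1) == "$$$$")))
    recs <- recs[vapply(recs, function(r) any(nzchar(trimws(r))), logical(1))]
    smi <- character(length(recs))
    id <- character(length(recs))
    for (i in seq_along(recs)) {
      body <- recs[[i]]
      if (!any(body == "$$$$")) body <- c(body, "$$$$")
      id[i] <- trimws(body[[1]])
      out <- tryCatch(
        ob_convert("SDF", "CAN", paste(body, collapse = "\n")),
        error = function(e) ""
      )
      line <- strsplit(out, "\n", fixed = TRUE)[[1]][1]
      smi[i] <- if (is.na(line) || !nzchar(line)) NA_character_ else sub("[ \t].*$", "", line)
    }
    id[!nzchar(id)] <- paste0("mol_", which(!nzchar(id)))
  }

  can <- ifelse(is.na(smi), NA_character_, ob_canonical(smi))
  ok <- !is.na(can) & nzchar(can)
  n_failed <- sum(!ok)
  if (n_failed > 0) {
    rlang::inform(sprintf(
      "%s: %d record(s) failed to parse and were %s.",
      name, n_failed, if (keep_failures) "retained with parse_ok = FALSE" else "excluded"
    ))
  }
  out <- tibble::tibble(
    id = as.character(id),
    smiles = can,
    source = name,
    parse_ok = ok
  )
  if (!keep_failures) out <- out[out$parse_ok, , drop = FALSE]
  if (sum(out$parse_ok) == 0) {
    rlang::abort(sprintf("No parseable records in '%s'.", path))
  }
  attr(out, "name") <- name
  out
}

#' Write a collection to a SMILES or SDF file
#'
#' Lossless for canonical structure and identifier: a round trip through
#' [read_collection()] preserves the multiset of canonical SMILES. SDF
#' output is V2000 with the identifier on the molecule title line.
#'
#' @param x Collection tibble (columns `id`, `smiles`).
#' @param path Output file path.
#' @param format `"smiles"` or `"sdf"` (default guessed from extension).
#' @return `path`, invisibly.
#' @export
write_collection <- function(x, path, format = NULL) {
  assert_collection(x)
  format <- format %||%
    (if (grepl("\\.sdf$", path, ignore.case = TRUE)) "sdf" else "smiles")
  format <- match.arg(format, c("smiles", "sdf"))
  if (nrow(x) == 0) {
    rlang::warn("Writing an empty collection.")
    writeLines(character(0), path)
    return(invisible(path))
  }
  if (format == "smiles") {
    writeLines(paste(x$smiles, x$id), path)
  } else {
    sdf <- smiles_to_sdfset(x$smiles, x$id)
    ChemmineR::write.SDF(sdf, path, cid = TRUE)
  }
  invisible(path)
}

#' Standardize structures (salt stripping, neutralization, canonicalization)
#'
#' Applies the cleaning sequence used before any analysis: optional removal
#' of stereochemistry annotations, retention of the largest covalently
#' connected fragment (ties broken by lexicographic order of the canonical
#' fragment string), charge neutralization where a proton can be added or
#' removed without violating standard valence (quaternary nitrogens and
#' other non-neutralizable centers keep their charge), and OpenBabel
#' canonicalization. The operation is idempotent.
#'
#' @param x Collection tibble.
#' @param neutralize Neutralize formal charges where chemically valid.
#' @param ignore_stereo Drop stereochemistry before canonicalization
#'   (the default: analyses here are 2D-topological).
#' @param largest_fragment Keep only the largest connected fragment.
#' @return The collection with standardized `smiles`; records that fail to
#'   re-parse are dropped with a message.
#' @export
standardize_collection <- function(x, neutralize = TRUE, ignore_stereo = TRUE,
                                   largest_fragment = TRUE) {
  assert_collection(x)
  std <- standardize_smiles(x$smiles,
    neutralize = neutralize,
    ignore_stereo = ignore_stereo,
    largest_fragment = largest_fragment
  )
  x$smiles <- std
  bad <- is.na(std)
  if (any(bad)) {
    rlang::inform(sprintf(
      "%d record(s) could not be standardized and were dropped.", sum(bad)
    ))
    x <- x[!bad, , drop = FALSE]
  }
  x
}

#' @rdname standardize_collection
#' @param smiles Character vector of SMILES strings.
#' @export
standardize_smiles <- function(smiles, neutralize = TRUE, ignore_stereo = TRUE,
                               largest_fragment = TRUE) {
  s <- as.character(smiles)
  if (ignore_stereo) s <- strip_stereo(s)
  can <- ob_canonical(s)

  # largest covalent fragment (salt / solvent stripping)
  if (largest_fragment) {
    multi <- which(!is.na(can) & grepl(".", can, fixed = TRUE))
    for (i in multi) {
      frags <- strsplit(can[i], ".", fixed = TRUE)[[1]]
      sizes <- heavy_atom_count(frags)
      best <- frags[sizes == max(sizes)]
      can[i] <- sort(best)[1]
    }
  }

  # neutralization needs formal charges from the connection table
  if (neutralize) {
    charged <- which(!is.na(can) & grepl("\\[[^\\]]*[+-]", can))
    for (i in charged) {
      can[i] <- neutralize_smiles_one(can[i])
    }
  }
  ifelse(is.na(can), NA_character_, ob_canonical(can))
}

# Zero the formal charge of atoms where the proton transfer is valence-
# legal: cations that carry at least one implicit hydrogen, anions of
# C/N/O/S/P. Other charged centers (e.g. quaternary N) are retained.
neutralize_smiles_one <- function(smiles) {
  g <- tryCatch(mol_graph(smiles), error = function(e) NULL)
  if (is.null(g)) return(smiles)
  atoms <- g$atoms
  fix <- (atoms$charge > 0 & atoms$h >= 1) |
    (atoms$charge < 0 & atoms$element %in% c("C", "N", "O", "S", "P"))
  if (!any(fix)) return(smiles)
  ab <- g$atomblock
  if (!"C6" %in% colnames(ab)) return(smiles)
  ab[fix, "C6"] <- 0
  hdr <- g$header
  sdf <- methods::new("SDF",
    header = hdr, atomblock = ab,
    bondblock = g$bondblock, datablock = character(0)
  )
  txt <- paste(c(ChemmineR::sdf2str(sdf), "$$$$"), collapse = "\n")
  out <- tryCatch(ob_convert("SDF", "CAN", txt), error = function(e) "")
  line <- strsplit(out, "\n", fixed = TRUE)[[1]][1]
  if (is.na(line) || !nzchar(line)) return(smiles)
  sub("[ \t].*$", "", line)
}

#' Remove duplicate structures from a collection
#'
#' One record per canonical structure; the first occurrence wins and input
#' order is preserved. Assumes structures are already standardized (see
#' [standardize_collection()]).
#'
#' @param x Collection tibble.
#' @return The deduplicated collection; the number of removed records is
#'   reported with a message.
#' @export
dedup_collection <- function(x) {
  assert_collection(x)
  keep <- !duplicated(x$smiles)
  removed <- sum(!keep)
  if (removed > 0) {
    rlang::inform(sprintf("Removed %d duplicate structure(s).", removed))
  }
  out <- x[keep, , drop = FALSE]
  attr(out, "name") <- attr(x, "name")
  out
}
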