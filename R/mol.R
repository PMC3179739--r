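# Internal molecule layer: canonicalization and molecular-graph construction
# on top of ChemmineR/ChemmineOB (OpenBabel). All chemistry parsing goes
# through OpenBabel; this file only adapts its output into a light graph
# representation (atom/bond tibbles) used by the fingerprint, property and
# scaffold code.

.mol_cache <- new.env(parent = emptyenv())

ob_convert <- function(from, to, source) {
  ChemmineOB::convertFormat(from, to, source = source)
}

# canonical SMILES of a single record; NA if OpenBabel cannot parse it
ob_canonical_one <- function(smiles) {
  out <- tryCatch(
    ob_convert("SMI", "CAN", paste0(smiles, " t\n")),
    error = function(e) ""
  )
  line <- strsplit(out, "\n", fixed = TRUE)[[1]][1]
  if (is.na(line) || !nzchar(line)) return(NA_character_)
  sub("[ \t].*$", "", line)
}

# vectorized canonicalization. OpenBabel stops a batch at the first invalid
# record, so records are tagged with an index title, the batch output is
# mapped back by title, and only the missing records are retried one by one.
ob_canonical <- function(smiles) {
  n <- length(smiles)
  if (n == 0) return(character(0))
  smi <- sub("[ \t].*$", "", smiles) # defensively drop any embedded titles
  out <- rep(NA_character_, n)
  src <- paste0(smi, " t", seq_len(n), collapse = "\n")
  batch <- tryCatch(ob_convert("SMI", "CAN", paste0(src, "\n")),
    error = function(e) ""
  )
  lines <- strsplit(batch, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  if (length(lines)) {
    can <- sub("[ \t].*$", "", lines)
    idx <- suppressWarnings(as.integer(sub("^.*[ \t]t", "", lines)))
    ok <- !is.na(idx) & idx >= 1 & idx <= n & nzchar(can)
    out[idx[ok]] <- can[ok]
  }
  for (i in which(is.na(out))) out[i] <- ob_canonical_one(smi[i])
  out
}

# SDFset for a vector of valid SMILES; ids become molecule titles
smiles_to_sdfset <- function(smiles, ids = NULL) {
  ids <- ids %||% paste0("mol_", seq_along(smiles))
  sdf <- ChemmineR::smiles2sdf(setNames(smiles, make.unique(as.character(ids))))
  ChemmineR::cid(sdf) <- make.unique(as.character(ids))
  sdf
}

# ---------------------------------------------------------------------------
# molecular graph

# Build the internal graph for one ChemmineR SDF object. Atoms carry element,
# formal charge, implicit hydrogen count, degree, ring and aromatic flags;
# bonds carry order plus ring/aromatic flags. Ring perception and
# aromaticity come from ChemmineR::rings() (smallest rings, Hueckel test).
mol_graph_from_sdf <- function(sdf_one) {
  ab <- sdf_one@atomblock
  bb <- sdf_one@bondblock
  n_atoms <- nrow(ab)
  element <- sub("_.*$", "", rownames(ab))
  charge <- decode_charge(if ("C6" %in% colnames(ab)) ab[, "C6"] else rep(0, n_atoms))

  if (is.null(bb) || nrow(bb) == 0) {
    bonds <- tibble::tibble(
      a1 = integer(0), a2 = integer(0), order = integer(0),
      arom = logical(0), in_ring = logical(0)
    )
    degree <- rep(0L, n_atoms)
    bsum <- rep(0, n_atoms)
    ring_atom <- rep(FALSE, n_atoms)
    arom_atom <- rep(FALSE, n_atoms)
    ring_list <- list()
    ring_arom <- logical(0)
  } else {
    a1 <- as.integer(bb[, 1]); a2 <- as.integer(bb[, 2])
    ord <- as.integer(bb[, 3])
    degree <- tabulate(c(a1, a2), nbins = n_atoms)
    bsum <- vapply(seq_len(n_atoms), function(i) {
      sum(ord[a1 == i | a2 == i])
    }, numeric(1))

    # ring membership: a bond is in a ring iff it is not a bridge
    g <- igraph::graph_from_data_frame(
      data.frame(from = a1, to = a2),
      directed = FALSE,
      vertices = data.frame(name = seq_len(n_atoms))
    )
    bridge_eids <- igraph::bridges(g)
    in_ring_bond <- !(seq_along(a1) %in% as.integer(bridge_eids))
    ring_atom <- rep(FALSE, n_atoms)
    ring_atom[unique(c(a1[in_ring_bond], a2[in_ring_bond]))] <- TRUE

    ring_info <- tryCatch(
      ChemmineR::rings(sdf_one, upper = Inf, type = "all", arom = TRUE, inner = TRUE),
      error = function(e) list(RINGS = list(), AROMATIC = logical(0))
    )
    ring_list <- lapply(ring_info$RINGS, function(r) {
      as.integer(sub("^.*_", "", r))
    })
    ring_arom <- as.logical(ring_info$AROMATIC)
    arom_atom <- rep(FALSE, n_atoms)
    if (length(ring_list)) {
      for (k in seq_along(ring_list)) {
        if (isTRUE(ring_arom[k])) arom_atom[ring_list[[k]]] <- TRUE
      }
    }
    bonds <- tibble::tibble(
      a1 = a1, a2 = a2, order = ord,
      arom = in_ring_bond & arom_atom[a1] & arom_atom[a2],
      in_ring = in_ring_bond
    )
  }

  atoms <- tibble::tibble(
    idx = seq_len(n_atoms),
    element = element,
    charge = charge,
    degree = degree,
    h = implicit_h(element, charge, bsum),
    in_ring = ring_atom,
    arom = arom_atom
  )
  list(
    atoms = atoms, bonds = bonds,
    rings = ring_list, ring_arom = ring_arom,
    atomblock = ab, bondblock = bb, header = sdf_one@header
  )
}

# single heavy atoms (methane, water, halides) cannot round-trip through a
# V2000 connection table in ChemmineR; their graphs are built directly from
# the atom token
single_atom_graph <- function(smiles) {
  s <- gsub("^\\[|\\]$", "", trimws(smiles))
  m <- regmatches(s, regexec("^([A-Za-z][a-z]?)(H[0-9]*)?([+-][0-9]*)?$", s))[[1]]
  if (length(m) == 0) rlang::abort(sprintf("Cannot parse single-atom SMILES '%s'.", smiles))
  element <- m[2]
  # lone aromatic token cannot occur for an isolated atom
  element <- paste0(toupper(substr(element, 1, 1)), substring(element, 2))
  charge <- if (nzchar(m[4])) {
    sgn <- if (startsWith(m[4], "-")) -1L else 1L
    mag <- sub("^[+-]", "", m[4])
    sgn * (if (nzchar(mag)) as.integer(mag) else 1L)
  } else 0L
  h <- if (nzchar(m[3])) {
    hh <- sub("^H", "", m[3])
    if (nzchar(hh)) as.integer(hh) else 1L
  } else {
    implicit_h(element, charge, 0)
  }
  atoms <- tibble::tibble(
    idx = 1L, element = element, charge = charge, degree = 0L,
    h = as.integer(h), in_ring = FALSE, arom = FALSE
  )
  bonds <- tibble::tibble(
    a1 = integer(0), a2 = integer(0), order = integer(0),
    arom = logical(0), in_ring = logical(0)
  )
  list(atoms = atoms, bonds = bonds, rings = list(), ring_arom = logical(0),
       atomblock = NULL, bondblock = NULL, header = NULL)
}

# graphs for a vector of canonical SMILES, with memoization keyed on the
# canonical string (pipeline stages repeatedly revisit the same structures)
mol_graphs <- function(smiles) {
  out <- vector("list", length(smiles))
  key <- as.character(smiles)
  missing <- which(!vapply(key, exists, logical(1), envir = .mol_cache) & !is.na(key))
  if (length(missing)) {
    single <- heavy_atom_count(key[missing]) <= 1
    for (j in which(single)) {
      assign(key[missing[j]], single_atom_graph(key[missing[j]]), envir = .mol_cache)
    }
    multi <- missing[!single]
    if (length(multi)) {
      sdf <- smiles_to_sdfset(smiles[multi], paste0("g", multi))
      for (j in seq_along(multi)) {
        g <- mol_graph_from_sdf(sdf[[j]])
        assign(key[multi[j]], g, envir = .mol_cache)
      }
    }
  }
  for (i in seq_along(key)) {
    out[[i]] <- if (is.na(key[i])) NULL else get(key[i], envir = .mol_cache)
  }
  out
}

mol_graph <- function(smiles) mol_graphs(smiles)[[1]]

# canonical SMILES of the subgraph induced on `keep` atom indices, written
# back through an SDF connection table so OpenBabel recanonicalizes it
subgraph_smiles <- function(graph, keep) {
  keep <- sort(unique(as.integer(keep)))
  ab <- graph$atomblock[keep, , drop = FALSE]
  bb <- graph$bondblock
  if (!is.null(bb) && nrow(bb) > 0) {
    sel <- bb[, 1] %in% keep & bb[, 2] %in% keep
    bb <- bb[sel, , drop = FALSE]
    remap <- setNames(seq_along(keep), keep)
    bb[, 1] <- remap[as.character(bb[, 1])]
    bb[, 2] <- remap[as.character(bb[, 2])]
  } else {
    bb <- matrix(0, nrow = 0, ncol = 7)
  }
  hdr <- graph$header
  hdr["Counts_Line"] <- sprintf(
    "%3d%3d  0  0  0  0  0  0  0  0999 V2000", nrow(ab), nrow(bb)
  )
  sdf <- methods::new("SDF",
    header = hdr, atomblock = ab, bondblock = bb,
    datablock = character(0)
  )
  txt <- paste(c(ChemmineR::sdf2str(sdf), "$$$$"), collapse = "\n")
  out <- tryCatch(ob_convert("SDF", "CAN", txt), error = function(e) "")
  line <- strsplit(out, "\n", fixed = TRUE)[[1]][1]
  if (is.na(line) || !nzchar(line)) return(NA_character_)
  sub("[ \t].*$", "", line)
}
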