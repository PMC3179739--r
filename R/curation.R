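# Redundancy reduction: atom-type descriptors, CLARA-style k-medoids
# clustering to representatives, the lipid filter, and seeded random subsets.

.atom_type_elements <- c("C", "N", "O", "S", "P", "F", "Cl", "Br", "I", "B")

atom_type_alphabet <- function() {
  el <- c(.atom_type_elements, "other")
  grid <- expand.grid(
    element = el, arom = c("ar", "al"), ring = c("ring", "chain"),
    stringsAsFactors = FALSE
  )
  paste(grid$element, grid$arom, grid$ring, sep = "_")
}

#' Atom-type count descriptor
#'
#' Counts atoms over a fixed alphabet of element x aromaticity x ring
#' membership types (hydrogens implicit, unknown elements pooled into
#' `other`). This is the chemical descriptor used, with Euclidean distance,
#' for redundancy-reducing clustering.
#'
#' @param x Collection tibble.
#' @return A tibble with `id` plus one count column per atom type.
#' @export
atom_type_counts <- function(x) {
  assert_collection(x)
  m <- atom_type_matrix(x$smiles)
  dplyr::bind_cols(tibble::tibble(id = x$id), tibble::as_tibble(m))
}

atom_type_matrix <- function(smiles) {
  alphabet <- atom_type_alphabet()
  graphs <- mol_graphs(smiles)
  m <- matrix(0L, nrow = length(smiles), ncol = length(alphabet),
    dimnames = list(NULL, alphabet)
  )
  for (i in seq_along(graphs)) {
    a <- graphs[[i]]$atoms
    el <- ifelse(a$element %in% .atom_type_elements, a$element, "other")
    key <- paste(el,
      ifelse(a$arom, "ar", "al"),
      ifelse(a$in_ring, "ring", "chain"),
      sep = "_"
    )
    tab <- table(key)
    m[i, names(tab)] <- as.integer(tab)
  }
  m
}

#' Cluster a collection to medoid representatives
#'
#' Reduces a collection to `k = round((1 - target_reduction) * n)` cluster
#' representatives by k-medoids on atom-type count descriptors with
#' Euclidean distance. Every representative is an actual member (medoid) of
#' its cluster; singleton clusters contribute themselves. For collections no
#' larger than `sample_size` the exact PAM algorithm is run on the full
#' distance matrix; larger collections use the sampling-based CLARA scheme
#' (`n_samples` subsamples of size `sample_size`, best total-distance
#' assignment kept). Deterministic for a fixed `seed`.
#'
#' @param x Collection tibble (standardized).
#' @param target_reduction Fraction of the collection to remove, in (0,1).
#'   The default 0.3 reduces each dataset by 30%.
#' @param k Number of representatives; overrides `target_reduction`.
#' @param sample_size CLARA subsample size (default `min(n, 40 + 2k)`).
#' @param n_samples Number of CLARA subsamples.
#' @param seed Integer seed for the CLARA subsampling.
#' @return The sub-collection of representatives, in input order.
#' @export
cluster_representatives <- function(x, target_reduction = 0.3, k = NULL,
                                    sample_size = NULL, n_samples = 5,
                                    seed = 1) {
  assert_collection(x)
  n <- nrow(x)
  if (n < 2) {
    rlang::warn("Collection has fewer than 2 records; returning it unchanged.")
    return(x)
  }
  if (is.null(k)) {
    if (!is.numeric(target_reduction) || target_reduction <= 0 || target_reduction >= 1) {
      rlang::abort("`target_reduction` must be in (0, 1).")
    }
    k <- round((1 - target_reduction) * n)
  }
  k <- max(1L, as.integer(k))
  if (k >= n) {
    rlang::warn("Requested at least as many representatives as records; returning the collection unchanged.")
    return(x)
  }
  m <- atom_type_matrix(x$smiles)
  sample_size <- as.integer(sample_size %||% min(n, 40 + 2 * k))
  sample_size <- min(n, max(sample_size, k + 1))

  if (n <= sample_size) {
    fit <- cluster::pam(stats::dist(m), k = k, diss = TRUE)
    med_idx <- as.integer(fit$id.med)
  } else {
    fit <- withr::with_seed(seed,
      cluster::clara(m, k = k,
        metric = "euclidean", samples = n_samples,
        sampsize = sample_size, pamLike = TRUE
      )
    )
    med_idx <- as.integer(fit$i.med)
  }
  out <- x[sort(med_idx), , drop = FALSE]
  attr(out, "name") <- attr(x, "name")
  out
}

#' Remove lipid-like molecules
#'
#' The default rule removes molecules containing an acyclic, unbranched
#' chain of at least `min_chain_len` sp3 carbons (chain atoms outside rings,
#' carrying only single bonds). This chain-length rule is a documented
#' stand-in for a lipid definition; it can be supplemented with SMARTS
#' patterns (matched through OpenBabel) for fatty-acid, glycerolipid or
#' sphingoid substructures. Idempotent.
#'
#' @param x Collection tibble (standardized).
#' @param min_chain_len Minimum sp3-carbon chain length that triggers removal.
#' @param patterns Optional character vector of SMARTS patterns; any match
#'   also triggers removal.
#' @return The lipid-free collection; removed ids are available in the
#'   `"removed"` attribute.
#' @export
filter_lipids <- function(x, min_chain_len = 12, patterns = NULL) {
  assert_collection(x)
  if (nrow(x) == 0) return(x)
  is_lipid <- vapply(
    mol_graphs(x$smiles), lipid_chain_length, numeric(1)
  ) >= min_chain_len
  if (!is.null(patterns) && length(patterns)) {
    sdf <- smiles_to_sdfset(x$smiles, x$id)
    for (p in patterns) {
      hits <- tryCatch(
        ChemmineR::smartsSearchOB(sdf, p, uniqueMatches = TRUE),
        error = function(e) rep(0, nrow(x))
      )
      is_lipid <- is_lipid | hits > 0
    }
  }
  if (any(is_lipid)) {
    rlang::inform(sprintf("Removed %d lipid-like molecule(s).", sum(is_lipid)))
  }
  out <- x[!is_lipid, , drop = FALSE]
  attr(out, "name") <- attr(x, "name")
  attr(out, "removed") <- x$id[is_lipid]
  out
}

# longest unbranched acyclic sp3-carbon chain; the induced subgraph is a
# forest, so the longest path is the largest component diameter
lipid_chain_length <- function(graph) {
  a <- graph$atoms
  b <- graph$bonds
  sp3 <- a$element == "C" & !a$arom & !a$in_ring
  if (nrow(b) > 0) {
    multi <- unique(c(b$a1[b$order > 1], b$a2[b$order > 1]))
    sp3[multi] <- FALSE
  }
  keep <- which(sp3)
  if (length(keep) == 0) return(0)
  sel <- b$a1 %in% keep & b$a2 %in% keep
  if (!any(sel)) return(1)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(b$a1[sel]), to = as.character(b$a2[sel])),
    directed = FALSE,
    vertices = data.frame(name = as.character(keep))
  )
  igraph::diameter(g, unconnected = TRUE) + 1
}

#' Draw a reproducible random subset
#'
#' Uniform sampling without replacement, reproducible for a fixed seed.
#' Used to draw the analysis subsets (2000 compounds per clustered dataset
#' in the original study design).
#'
#' @param x Collection tibble.
#' @param n Subset size; if `n >= nrow(x)` the collection is returned with a
#'   warning.
#' @param seed Integer seed.
#' @return The sampled sub-collection, in original row order.
#' @export
random_subset <- function(x, n, seed = 1) {
  assert_collection(x)
  if (!is.numeric(n) || n < 0) rlang::abort("`n` must be a non-negative number.")
  if (n >= nrow(x)) {
    if (n > nrow(x)) rlang::warn("`n` exceeds the collection size; returning the full collection.")
    return(x)
  }
  idx <- withr::with_seed(seed, sample.int(nrow(x), n))
  out <- x[sort(idx), , drop = FALSE]
  attr(out, "name") <- attr(x, "name")
  out
}
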