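# Extended-connectivity circular fingerprints, generated by iterative
# neighborhood expansion. Two variants: "connectivity" (ECFP-style initial
# atom codes from element, degree, hydrogen count, charge, ring and aromatic
# flags) and "functional" (FCFP-style 6-bit pharmacophoric role codes:
# H-bond donor, H-bond acceptor, positively ionizable, negatively ionizable,
# aromatic, halogen -- all halogens share one initial code). Feature
# identifiers are stable 32-bit FNV-1a hashes; only set and frequency
# statistics of the identifiers are meaningful downstream, so the hashing
# scheme is implementation-defined by design.

#' Fingerprint specification
#'
#' @param variant `"connectivity"` (ECFP-style) or `"functional"`
#'   (FCFP-style).
#' @param order Even fingerprint order; the number of neighborhood-expansion
#'   iterations is `order / 2` (order 4 = 2 iterations, the common ECFP_4 /
#'   FCFP_4 setting).
#' @return A list with class `"fp_spec"`.
#' @export
fp_spec <- function(variant = c("connectivity", "functional"), order = 4) {
  variant <- match.arg(variant)
  if (!is.numeric(order) || length(order) != 1 || order < 0 || order %% 2 != 0) {
    rlang::abort("`order` must be an even non-negative integer.")
  }
  structure(list(variant = variant, order = as.integer(order)), class = "fp_spec")
}

halogens <- c("F", "Cl", "Br", "I")

# per-atom initial codes (numeric 32-bit hash values)
initial_atom_codes <- function(graph, variant = "connectivity") {
  a <- graph$atoms
  if (variant == "connectivity") {
    key <- paste("A", a$element, a$degree, a$h, a$charge,
      as.integer(a$in_ring), as.integer(a$arom),
      sep = "|"
    )
    return(fnv1a32(key))
  }
  b <- graph$bonds
  # carbons double-bonded to O (amide/acid carbonyls) and the identity of
  # carboxyl hydroxyls drive the ionizable roles
  carbonyl_c <- integer(0)
  if (nrow(b) > 0) {
    dbl_CO <- b[b$order == 2 &
      ((a$element[b$a1] == "C" & a$element[b$a2] == "O") |
        (a$element[b$a2] == "C" & a$element[b$a1] == "O")), , drop = FALSE]
    carbonyl_c <- unique(ifelse(a$element[dbl_CO$a1] == "C", dbl_CO$a1, dbl_CO$a2))
  }
  nbrs <- neighbor_list(graph)
  n <- nrow(a)
  donor <- a$element %in% c("N", "O") & a$h >= 1
  # pyrrole-type nitrogen (aromatic, three connections counting H) is not an
  # acceptor
  pyrrole_n <- a$element == "N" & a$arom & (a$degree + a$h) >= 3
  acceptor <- a$element %in% c("N", "O") & !pyrrole_n
  adj_carbonyl <- vapply(seq_len(n), function(i) any(nbrs[[i]] %in% carbonyl_c), logical(1))
  pos_ion <- a$charge > 0 |
    (a$element == "N" & !a$arom & a$h >= 1 & !adj_carbonyl)
  neg_ion <- a$charge < 0 |
    (a$element == "O" & a$h >= 1 & adj_carbonyl)
  halogen <- a$element %in% halogens
  key <- paste("F", as.integer(donor), as.integer(acceptor),
    as.integer(pos_ion), as.integer(neg_ion),
    as.integer(a$arom), as.integer(halogen),
    sep = "|"
  )
  fnv1a32(key)
}

neighbor_list <- function(graph) {
  n <- nrow(graph$atoms)
  nbrs <- vector("list", n)
  b <- graph$bonds
  if (nrow(b) > 0) {
    for (j in seq_len(nrow(b))) {
      nbrs[[b$a1[j]]] <- c(nbrs[[b$a1[j]]], b$a2[j])
      nbrs[[b$a2[j]]] <- c(nbrs[[b$a2[j]]], b$a1[j])
    }
  }
  nbrs
}

# full multiset of circular-fingerprint features for one molecule graph.
# Returns a tibble(feature, count, iter). Environments covering an atom set
# already generated at an earlier iteration are duplicates and are dropped;
# among duplicates arising at the same iteration the smallest feature id is
# kept (one instance).
fp_multiset_graph <- function(graph, variant = "connectivity", n_iter = 2) {
  a <- graph$atoms
  n <- nrow(a)
  if (n == 0) {
    return(tibble::tibble(feature = numeric(0), count = integer(0), iter = integer(0)))
  }
  b <- graph$bonds
  nbrs <- neighbor_list(graph)
  bond_code <- matrix(0L, nrow = 0, ncol = 3)
  if (nrow(b) > 0) {
    code <- ifelse(b$arom, 4L, b$order)
    bond_code <- rbind(
      cbind(b$a1, b$a2, code),
      cbind(b$a2, b$a1, code)
    )
  }

  codes <- initial_atom_codes(graph, variant)
  env <- lapply(seq_len(n), function(i) i)
  seen <- character(0)

  inst_feature <- numeric(0)
  inst_iter <- integer(0)

  for (r in 0:n_iter) {
    if (r > 0) {
      new_codes <- numeric(n)
      new_env <- vector("list", n)
      for (i in seq_len(n)) {
        ni <- nbrs[[i]]
        if (length(ni) == 0) {
          new_codes[i] <- codes[i]
          new_env[[i]] <- env[[i]]
          next
        }
        bc <- bond_code[bond_code[, 1] == i, , drop = FALSE]
        pairs <- paste0(bc[, 3], ":", format(codes[bc[, 2]], scientific = FALSE, trim = TRUE))
        pairs <- sort(pairs)
        key <- paste("I", r,
          format(codes[i], scientific = FALSE, trim = TRUE),
          paste(pairs, collapse = "|"),
          sep = "|"
        )
        new_codes[i] <- fnv1a32(key)
        new_env[[i]] <- sort(unique(c(env[[i]], unlist(env[ni]))))
      }
      codes <- new_codes
      env <- new_env
    }
    env_key <- vapply(env, paste, character(1), collapse = ",")
    # skip environments identical to one from an earlier iteration
    fresh <- !(env_key %in% seen)
    if (any(fresh)) {
      ek <- env_key[fresh]
      cd <- codes[fresh]
      # within-iteration duplicates: keep the smallest feature id, once
      keep_first <- !duplicated(ek)
      grp_min <- tapply(cd, ek, min)
      ek_u <- ek[keep_first]
      inst_feature <- c(inst_feature, unname(grp_min[ek_u]))
      inst_iter <- c(inst_iter, rep(r, sum(keep_first)))
      seen <- c(seen, ek_u)
    }
  }
  out <- tibble::tibble(feature = inst_feature, iter = inst_iter)
  out <- dplyr::count(out, .data$feature, .data$iter, name = "count")
  # a feature id generated at several iterations keeps its earliest tag
  out <- dplyr::arrange(out, .data$iter, .data$feature)
  dplyr::select(out, "feature", "count", "iter")
}

#' Per-molecule circular fingerprint features
#'
#' Generates the circular-fingerprint feature multiset of every molecule in
#' a collection: one row per (molecule, feature) with its occurrence count
#' and the iteration at which the feature first appears (`iter`, so order
#' `2 * iter` fingerprints are the rows with `iter <= order / 2`).
#'
#' @param x Collection tibble.
#' @param variant Fingerprint variant, see [fp_spec()].
#' @param order Fingerprint order (even; iterations = order / 2).
#' @return A tibble with columns `id`, `feature`, `count`, `iter`.
#' @export
fingerprint_features <- function(x, variant = c("connectivity", "functional"),
                                 order = 4) {
  assert_collection(x)
  spec <- fp_spec(match.arg(variant), order)
  graphs <- mol_graphs(x$smiles)
  res <- purrr::map2(graphs, x$id, function(g, id) {
    fp <- fp_multiset_graph(g, spec$variant, spec$order / 2L)
    fp$id <- id
    fp
  })
  dplyr::select(dplyr::bind_rows(res), "id", "feature", "count", "iter")
}

# internal: multiset for one SMILES as a named count vector
fp_multiset <- function(smiles, variant = "connectivity", order = 4) {
  fp <- fp_multiset_graph(mol_graph(smiles), variant, as.integer(order) %/% 2L)
  setNames(fp$count, format(fp$feature, scientific = FALSE, trim = TRUE))
}

#' Dataset feature-frequency vector
#'
#' Sums per-molecule feature multiset counts across a collection, yielding
#' the feature -> total frequency table that the frequency-weighted
#' (nonbinary) Tanimoto comparison of whole datasets is computed from.
#'
#' @inheritParams fingerprint_features
#' @return A tibble with columns `feature` and `freq`, carrying the number
#'   of distinct features as the `"n_features"` attribute.
#' @export
dataset_feature_frequencies <- function(x, variant = c("connectivity", "functional"),
                                        order = 4) {
  assert_collection(x)
  if (nrow(x) == 0) rlang::abort("Cannot compute feature frequencies of an empty collection.")
  feats <- fingerprint_features(x, variant = variant, order = order)
  out <- dplyr::summarise(
    dplyr::group_by(feats, .data$feature),
    freq = sum(.data$count), .groups = "drop"
  )
  out <- dplyr::arrange(out, .data$feature)
  attr(out, "n_features") <- nrow(out)
  out
}

#' Number of non-redundant fingerprint features in a dataset
#'
#' @inheritParams fingerprint_features
#' @return Integer count of distinct feature identifiers.
#' @export
nonredundant_feature_count <- function(x, variant = c("connectivity", "functional"),
                                       order = 4) {
  nrow(dataset_feature_frequencies(x, variant = variant, order = order))
}

#' Feature-diversity curve across fingerprint orders
#'
#' Tabulates the number of non-redundant circular-fingerprint features per
#' dataset at each requested order. Because the construction is cumulative
#' (order k features are a subset of order k + 2 features), each dataset row
#' is non-decreasing in order.
#'
#' @param collections Named list of collection tibbles.
#' @param orders Even fingerprint orders to evaluate.
#' @param variant Fingerprint variant (diversity analysis conventionally
#'   uses the connectivity variant).
#' @return A tibble with columns `dataset`, `order`, `n_features`.
#' @export
diversity_curve <- function(collections, orders = c(2, 4, 6, 8),
                            variant = c("connectivity", "functional")) {
  variant <- match.arg(variant)
  if (length(orders) == 0) {
    return(tibble::tibble(
      dataset = character(0), order = integer(0), n_features = integer(0)
    ))
  }
  if (is.null(names(collections)) || any(!nzchar(names(collections)))) {
    names(collections) <- paste0("dataset_", seq_along(collections))
  }
  max_order <- max(orders)
  purrr::imap_dfr(collections, function(coll, nm) {
    feats <- fingerprint_features(coll, variant = variant, order = max_order)
    tibble::tibble(
      dataset = nm,
      order = as.integer(sort(orders)),
      n_features = vapply(sort(orders), function(o) {
        dplyr::n_distinct(feats$feature[feats$iter <= o / 2])
      }, integer(1))
    )
  })
}
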