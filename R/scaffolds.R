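# Bemis-Murcko scaffold extraction and scaffold-level statistics: the core
# ring + linker framework of each molecule (side chains removed, linkers
# kept), scaffold frequency tables with singleton and aromatic statistics,
# top-N scaffolds, pairwise shared-scaffold matrices, and the
# missing-scaffold report.

#' Murcko scaffold of each molecule
#'
#' Iteratively prunes terminal heavy atoms until only ring atoms and the
#' linker atoms connecting rings remain, then canonicalizes the remaining
#' framework. Acyclic molecules have no scaffold (`NA`). By default
#' exocyclic multiple-bond atoms (e.g. a carbonyl oxygen on a ring) are
#' pruned too, giving the pure atomic framework; `keep_exocyclic = TRUE`
#' retains terminal atoms attached by a double or triple bond, a variant
#' some Murcko implementations use. Scaffold identity keeps element and
#' bond-order information (benzene and pyridine are distinct scaffolds).
#' The operation is idempotent: the scaffold of a scaffold is itself.
#'
#' @param smiles Character vector of (standardized) SMILES.
#' @param keep_exocyclic Retain terminal atoms bound by a multiple bond.
#' @return Character vector of canonical scaffold SMILES, `NA` for acyclic
#'   or unparsable input.
#' @examples
#' \donttest{
#' murcko_scaffold(c("Cc1ccccc1", "CCO")) # benzene, NA
#' }
#' @export
murcko_scaffold <- function(smiles, keep_exocyclic = FALSE) {
  vapply(as.character(smiles), function(s) {
    if (is.na(s)) return(NA_character_)
    g <- tryCatch(mol_graph(s), error = function(e) NULL)
    if (is.null(g)) return(NA_character_)
    murcko_scaffold_graph(g, keep_exocyclic)
  }, character(1), USE.NAMES = FALSE)
}

murcko_scaffold_graph <- function(g, keep_exocyclic = FALSE) {
  n <- nrow(g$atoms)
  if (n == 0 || nrow(g$bonds) == 0 || !any(g$atoms$in_ring)) {
    return(NA_character_)
  }
  alive <- rep(TRUE, n)
  a1 <- g$bonds$a1
  a2 <- g$bonds$a2
  ord <- g$bonds$order
  # pure atomic framework: iteratively prune terminal heavy atoms (ring
  # atoms are never terminal while their ring partners survive)
  repeat {
    deg <- tabulate(c(a1[alive[a1] & alive[a2]], a2[alive[a1] & alive[a2]]), nbins = n)
    term <- alive & deg <= 1 & !g$atoms$in_ring
    if (!any(term)) break
    alive[term] <- FALSE
  }
  if (keep_exocyclic) {
    # re-attach pruned atoms multiple-bonded to a framework atom
    back <- (ord > 1) & (alive[a1] != alive[a2])
    alive[unique(c(a1[back], a2[back]))] <- TRUE
  }
  keep <- which(alive)
  if (length(keep) == 0) return(NA_character_)
  subgraph_smiles(g, keep)
}

#' Scaffold frequency table of a collection
#'
#' Tabulates canonical Murcko scaffolds over a collection. Aromaticity of
#' each scaffold is re-perceived on the isolated framework, not inherited
#' from the parent molecule; a scaffold is aromatic when it contains at
#' least one aromatic ring. Acyclic molecules contribute nothing, so the
#' total scaffold occurrence count can be below the dataset size.
#'
#' @param x Collection tibble.
#' @param keep_exocyclic Passed to [murcko_scaffold()].
#' @return A `scaffold_table`: a tibble with columns `scaffold`, `count`,
#'   `n_rings`, `n_aromatic_rings`, `aromatic`, sorted by decreasing count,
#'   carrying the dataset label and size as attributes. [glance()] returns
#'   the singleton/aromatic summary statistics.
#' @export
scaffold_table <- function(x, keep_exocyclic = FALSE) {
  assert_collection(x)
  if (nrow(x) == 0) rlang::abort("Cannot build a scaffold table from an empty collection.")
  sc <- murcko_scaffold(x$smiles, keep_exocyclic = keep_exocyclic)
  sc <- sc[!is.na(sc)]
  if (length(sc) == 0) {
    rlang::warn("No scaffolds: every molecule is acyclic.")
    counts <- tibble::tibble(
      scaffold = character(0), count = integer(0),
      n_rings = integer(0), n_aromatic_rings = integer(0), aromatic = logical(0)
    )
  } else {
    counts <- dplyr::count(tibble::tibble(scaffold = sc), .data$scaffold,
      name = "count", sort = TRUE
    )
    info <- scaffold_ring_info(counts$scaffold)
    counts <- dplyr::bind_cols(counts, info)
  }
  structure(counts,
    class = c("scaffold_table", class(tibble::tibble())),
    dataset = collection_name(x),
    dataset_size = nrow(x)
  )
}

# ring and aromatic-ring counts re-perceived on the isolated scaffolds
scaffold_ring_info <- function(scaffolds) {
  graphs <- mol_graphs(scaffolds)
  n_rings <- vapply(graphs, function(g) {
    n_comp <- if (nrow(g$bonds) == 0) nrow(g$atoms) else {
      igraph::count_components(igraph::graph_from_data_frame(
        data.frame(from = g$bonds$a1, to = g$bonds$a2),
        directed = FALSE, vertices = data.frame(name = seq_len(nrow(g$atoms)))
      ))
    }
    as.integer(nrow(g$bonds) - nrow(g$atoms) + n_comp)
  }, integer(1))
  n_arom <- vapply(graphs, function(g) {
    as.integer(sum(g$ring_arom))
  }, integer(1))
  tibble::tibble(
    n_rings = n_rings,
    n_aromatic_rings = n_arom,
    aromatic = n_arom >= 1
  )
}

#' Derived scaffold percentages from raw counts
#'
#' The arithmetic behind scaffold summary tables: scaffold occurrence
#' relative to dataset size, singletons and aromatic scaffolds relative to
#' the number of scaffolds, and the recurring complement
#' (`100 - pct_singletons`). Exposed so printed counts can be turned into
#' the derived percentages directly.
#'
#' @param n_scaffolds Number of distinct scaffolds.
#' @param dataset_size Number of molecules in the dataset.
#' @param n_singletons Number of scaffolds occurring exactly once.
#' @param n_aromatic Number of scaffolds with at least one aromatic ring.
#' @return A one-row tibble of counts and percentages (percentages are 0
#'   when their denominator is 0).
#' @export
scaffold_percentages <- function(n_scaffolds, dataset_size,
                                 n_singletons, n_aromatic) {
  pct <- function(num, den) if (den > 0) 100 * num / den else 0
  tibble::tibble(
    dataset_size = dataset_size,
    n_scaffolds = n_scaffolds,
    pct_occurrence = pct(n_scaffolds, dataset_size),
    n_singletons = n_singletons,
    pct_singletons = pct(n_singletons, n_scaffolds),
    pct_recurring = if (n_scaffolds > 0) 100 - pct(n_singletons, n_scaffolds) else 0,
    n_aromatic = n_aromatic,
    pct_aromatic = pct(n_aromatic, n_scaffolds)
  )
}

#' @rdname scaffold_table
#' @param x A `scaffold_table`.
#' @param ... Unused.
#' @export
glance.scaffold_table <- function(x, ...) {
  if (nrow(x) == 0) {
    out <- scaffold_percentages(0L, attr(x, "dataset_size"), 0L, 0L)
  } else {
    out <- scaffold_percentages(
      n_scaffolds = nrow(x),
      dataset_size = attr(x, "dataset_size"),
      n_singletons = sum(x$count == 1),
      n_aromatic = sum(x$aromatic)
    )
  }
  dplyr::bind_cols(tibble::tibble(dataset = attr(x, "dataset")), out)
}

#' @rdname scaffold_table
#' @export
tidy.scaffold_table <- function(x, ...) {
  tibble::as_tibble(x)
}

#' Most frequent scaffolds
#'
#' Ranks scaffolds by decreasing occurrence count (ties broken by the
#' canonical scaffold string) with percentages relative to the total number
#' of scaffold occurrences in the dataset.
#'
#' @param t A `scaffold_table`.
#' @param n Number of top scaffolds (the full ranking if larger than the
#'   number of distinct scaffolds).
#' @return A tibble with columns `scaffold`, `count`, `pct`.
#' @export
top_scaffolds <- function(t, n = 5) {
  if (!is.numeric(n) || n < 1) rlang::abort("`n` must be >= 1.")
  total <- sum(t$count)
  out <- dplyr::arrange(tibble::as_tibble(t), dplyr::desc(.data$count), .data$scaffold)
  out <- utils::head(out, n)
  tibble::tibble(
    scaffold = out$scaffold,
    count = out$count,
    pct = if (total > 0) 100 * out$count / total else rep(0, nrow(out))
  )
}

#' Shared-scaffold arithmetic for one dataset pair
#'
#' Given the scaffold-set sizes of two datasets and the size of their
#' intersection, derives the shared percentages: relative to the union of
#' the two scaffold sets and relative to each dataset ("the contribution of
#' each dataset to the set of shared scaffolds").
#'
#' @param n_a,n_b Numbers of distinct scaffolds in datasets A and B.
#' @param n_shared Number of scaffolds present in both.
#' @return A one-row tibble with `n_shared`, `pct_union`, `pct_a`, `pct_b`.
#' @export
shared_scaffold_cell <- function(n_a, n_b, n_shared) {
  if (n_shared > min(n_a, n_b)) {
    rlang::abort("`n_shared` cannot exceed the smaller scaffold set.")
  }
  union_n <- n_a + n_b - n_shared
  tibble::tibble(
    n_shared = n_shared,
    pct_union = if (union_n > 0) 100 * n_shared / union_n else 100,
    pct_a = if (n_a > 0) 100 * n_shared / n_a else 0,
    pct_b = if (n_b > 0) 100 * n_shared / n_b else 0
  )
}

#' Pairwise shared-scaffold matrix
#'
#' Intersects the canonical scaffold sets of every dataset pair and derives
#' the shared-scaffold percentages of [shared_scaffold_cell()]. Symmetric in
#' `n_shared` and `pct_union`; `pct_a`/`pct_b` swap when the pair is
#' reversed. The diagonal has `pct_union = 100`.
#'
#' @param tables Named list (length >= 2) of `scaffold_table` objects.
#' @return A `shared_scaffold_matrix`: a tibble with one row per ordered
#'   pair (upper triangle plus diagonal), columns `dataset_a`, `dataset_b`,
#'   `n_a`, `n_b`, `n_shared`, `pct_union`, `pct_a`, `pct_b`.
#' @export
shared_scaffold_matrix <- function(tables) {
  if (length(tables) < 2) rlang::abort("At least two scaffold tables are required.")
  if (is.null(names(tables)) || any(!nzchar(names(tables)))) {
    names(tables) <- vapply(tables, function(t) attr(t, "dataset") %||% "dataset", character(1))
  }
  labels <- names(tables)
  sets <- purrr::map(tables, function(t) unique(t$scaffold))
  rows <- list()
  for (i in seq_along(labels)) {
    for (j in i:length(labels)) {
      cell <- shared_scaffold_cell(
        n_a = length(sets[[i]]),
        n_b = length(sets[[j]]),
        n_shared = length(intersect(sets[[i]], sets[[j]]))
      )
      rows[[length(rows) + 1L]] <- dplyr::bind_cols(
        tibble::tibble(
          dataset_a = labels[i], dataset_b = labels[j],
          n_a = length(sets[[i]]), n_b = length(sets[[j]])
        ),
        cell
      )
    }
  }
  structure(dplyr::bind_rows(rows),
    class = c("shared_scaffold_matrix", class(tibble::tibble()))
  )
}

#' Scaffolds close to a reference set but absent from an exclusion set
#'
#' Reports scaffolds present in `source`, absent from `exclusion`, whose
#' best binary Tanimoto similarity (connectivity circular fingerprints of
#' the scaffold structures) to any `reference` scaffold reaches
#' `min_similarity`. This is the "missing scaffold" analysis: e.g.
#' metabolite scaffolds with close drug counterparts that current lead
#' libraries do not cover.
#'
#' @param source `scaffold_table` to draw candidates from.
#' @param reference `scaffold_table` of counterparts (must be non-empty).
#' @param exclusion `scaffold_table` whose scaffolds are excluded.
#' @param min_similarity Minimum best-match binary Tanimoto in \[0, 1\].
#' @param order Fingerprint order used for the comparison.
#' @return A tibble with columns `scaffold`, `best_match`, `similarity`,
#'   sorted by decreasing similarity.
#' @export
missing_scaffold_report <- function(source, reference, exclusion,
                                    min_similarity = 0.9, order = 4) {
  if (nrow(reference) == 0) rlang::abort("`reference` scaffold table is empty.")
  if (min_similarity < 0 || min_similarity > 1) {
    rlang::abort("`min_similarity` must be in [0, 1].")
  }
  cand <- setdiff(unique(source$scaffold), unique(exclusion$scaffold))
  ref <- unique(reference$scaffold)
  if (length(cand) == 0) {
    return(tibble::tibble(
      scaffold = character(0), best_match = character(0), similarity = numeric(0)
    ))
  }
  cand_fp <- purrr::map(cand, fp_multiset, variant = "connectivity", order = order)
  ref_fp <- purrr::map(ref, fp_multiset, variant = "connectivity", order = order)
  rows <- purrr::map_dfr(seq_along(cand), function(i) {
    sims <- vapply(ref_fp, function(f) tanimoto_binary(cand_fp[[i]], f), numeric(1))
    best <- which.max(sims)
    tibble::tibble(
      scaffold = cand[i],
      best_match = ref[best],
      similarity = sims[best]
    )
  })
  out <- rows[rows$similarity >= min_similarity, , drop = FALSE]
  dplyr::arrange(out, dplyr::desc(.data$similarity), .data$scaffold)
}
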