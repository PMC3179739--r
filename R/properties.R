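# Whole-molecule physicochemical descriptors: the four Lipinski descriptors
# (MW, AlogP, HBD, HBA) plus molecular polar surface area, rotatable bonds,
# an ESOL-style solubility estimate, and ring count; rule-of-five
# classification and box-plot summary statistics.

#' Compute the physicochemical property table
#'
#' Adds eight descriptor columns to a collection:
#' * `mw` -- molecular weight (g/mol, OpenBabel average atomic masses);
#' * `alogp` -- atomic-contribution log P (OpenBabel's group-contribution
#'   model, standing in for Ghose-Crippen AlogP);
#' * `hbd` -- hydrogen-bond donors, Lipinski convention: count of N-H and
#'   O-H hydrogens;
#' * `hba` -- hydrogen-bond acceptors, Lipinski convention: count of N and O
#'   atoms;
#' * `mpsa` -- topological (Ertl) polar surface area, in square Angstroms;
#' * `n_rotatable` -- non-ring single bonds between two heavy atoms that
#'   each carry at least one further heavy neighbor, amide C-N bonds
#'   excluded;
#' * `logs` -- ESOL-style aqueous solubility estimate, log(mol/L):
#'   `0.16 - 0.63 alogp - 0.0062 mw + 0.066 n_rotatable - 0.74 aromatic_proportion`.
#'   A documented surrogate for proprietary solubility models;
#' * `n_rings` -- smallest-set-of-smallest-rings cardinality (the cyclomatic
#'   number; fused bicyclics count 2).
#'
#' All descriptors are invariant to input atom ordering.
#'
#' @param x Collection tibble (standardized).
#' @return `x` with the eight property columns appended.
#' @export
compute_properties <- function(x) {
  assert_collection(x)
  if (nrow(x) == 0) {
    return(dplyr::bind_cols(x, tibble::tibble(
      mw = numeric(0), alogp = numeric(0), hbd = integer(0), hba = integer(0),
      mpsa = numeric(0), n_rotatable = integer(0), logs = numeric(0),
      n_rings = integer(0)
    )))
  }
  graphs <- mol_graphs(x$smiles)
  # single heavy atoms cannot pass through the connection-table descriptor
  # path; their MW comes from atomic weights and the partition/PSA models
  # degenerate to 0
  multi <- which(heavy_atom_count(x$smiles) > 1)
  mw <- alogp <- mpsa <- numeric(nrow(x))
  if (length(multi)) {
    sdf <- smiles_to_sdfset(x$smiles[multi], paste0("p", multi))
    pr <- ChemmineR::propOB(sdf)
    mw[multi] <- as.numeric(pr$MW)
    alogp[multi] <- as.numeric(pr$logP)
    mpsa[multi] <- as.numeric(pr$TPSA)
  }
  for (i in setdiff(seq_len(nrow(x)), multi)) {
    a <- graphs[[i]]$atoms
    m <- unname(.atomic_masses[a$element])
    m[is.na(m)] <- 0
    mw[i] <- sum(m) + sum(a$h) * .atomic_masses[["H"]]
  }

  hbd <- vapply(graphs, function(g) {
    sum(g$atoms$h[g$atoms$element %in% c("N", "O")])
  }, numeric(1))
  hba <- vapply(graphs, function(g) {
    sum(g$atoms$element %in% c("N", "O"))
  }, numeric(1))
  n_rot <- vapply(graphs, count_rotatable, numeric(1))
  n_rings <- vapply(graphs, function(g) {
    n_comp <- if (nrow(g$bonds) == 0) nrow(g$atoms) else {
      igraph::count_components(igraph::graph_from_data_frame(
        data.frame(from = g$bonds$a1, to = g$bonds$a2),
        directed = FALSE,
        vertices = data.frame(name = seq_len(nrow(g$atoms)))
      ))
    }
    nrow(g$bonds) - nrow(g$atoms) + n_comp
  }, numeric(1))
  arom_prop <- vapply(graphs, function(g) {
    if (nrow(g$atoms) == 0) 0 else mean(g$atoms$arom)
  }, numeric(1))

  logs <- 0.16 - 0.63 * alogp - 0.0062 * mw + 0.066 * n_rot - 0.74 * arom_prop

  dplyr::bind_cols(x, tibble::tibble(
    mw = mw,
    alogp = alogp,
    hbd = as.integer(hbd),
    hba = as.integer(hba),
    mpsa = mpsa,
    n_rotatable = as.integer(n_rot),
    logs = logs,
    n_rings = as.integer(n_rings)
  ))
}

# rotatable bonds: single, acyclic, both ends with >= 2 heavy neighbors,
# amide C-N excluded
count_rotatable <- function(g) {
  b <- g$bonds
  if (nrow(b) == 0) return(0)
  a <- g$atoms
  cand <- b$order == 1 & !b$in_ring & a$degree[b$a1] >= 2 & a$degree[b$a2] >= 2
  if (!any(cand)) return(0)
  carbonyl_c <- integer(0)
  dbl <- b[b$order == 2, , drop = FALSE]
  if (nrow(dbl) > 0) {
    co <- (a$element[dbl$a1] == "C" & a$element[dbl$a2] == "O") |
      (a$element[dbl$a2] == "C" & a$element[dbl$a1] == "O")
    carbonyl_c <- unique(c(
      dbl$a1[co & a$element[dbl$a1] == "C"],
      dbl$a2[co & a$element[dbl$a2] == "C"]
    ))
  }
  amide <- (a$element[b$a1] == "N" & b$a2 %in% carbonyl_c) |
    (a$element[b$a2] == "N" & b$a1 %in% carbonyl_c)
  sum(cand & !amide)
}

#' Count rule-of-five violations
#'
#' Number of Lipinski thresholds exceeded (strict inequality: boundary
#' values such as MW = 500 do not count as violations).
#'
#' @param props A property table from [compute_properties()] (or any data
#'   frame with `mw`, `alogp`, `hbd`, `hba` columns).
#' @param mw_max,alogp_max,hbd_max,hba_max Rule-of-five thresholds.
#' @return Integer vector of violation counts in 0..4.
#' @export
ro5_violations <- function(props, mw_max = 500, alogp_max = 5,
                           hbd_max = 5, hba_max = 10) {
  need <- c("mw", "alogp", "hbd", "hba")
  if (!all(need %in% names(props))) {
    rlang::abort("`props` must contain columns mw, alogp, hbd, hba (see compute_properties()).")
  }
  as.integer(
    (props$mw > mw_max) + (props$alogp > alogp_max) +
      (props$hbd > hbd_max) + (props$hba > hba_max)
  )
}

#' Percentage of molecules failing the rule-of-five test
#'
#' A molecule "fails" when it violates at least one Lipinski condition.
#'
#' @param x Collection tibble, or a property table already carrying the
#'   Lipinski columns.
#' @inheritParams ro5_violations
#' @return Percentage in \[0, 100\].
#' @export
ro5_failure_fraction <- function(x, mw_max = 500, alogp_max = 5,
                                 hbd_max = 5, hba_max = 10) {
  if (nrow(x) == 0) rlang::abort("Cannot compute the failure fraction of an empty collection.")
  if (!all(c("mw", "alogp", "hbd", "hba") %in% names(x))) {
    x <- compute_properties(x)
  }
  v <- ro5_violations(x,
    mw_max = mw_max, alogp_max = alogp_max,
    hbd_max = hbd_max, hba_max = hba_max
  )
  100 * mean(v >= 1)
}

#' Box-plot summary statistics per dataset and descriptor
#'
#' Five-number summary plus mean for each descriptor in each dataset, the
#' numbers behind property box plots. Quartiles use linear interpolation
#' (`stats::quantile` type 7 by default; configurable).
#'
#' @param props A property table with a `source` column (bind rows of
#'   [compute_properties()] results), or a named list of collections (then
#'   properties are computed first).
#' @param descriptors Descriptor columns to summarise.
#' @param quartile_type `type` passed to [stats::quantile()].
#' @return A tibble with columns `dataset`, `descriptor`, `min`, `q1`,
#'   `median`, `q3`, `max`, `mean`.
#' @export
boxplot_summaries <- function(props,
                              descriptors = c(
                                "mw", "alogp", "hbd", "hba",
                                "mpsa", "n_rotatable", "logs", "n_rings"
                              ),
                              quartile_type = 7) {
  if (is.list(props) && !is.data.frame(props)) {
    if (is.null(names(props))) names(props) <- paste0("dataset_", seq_along(props))
    props <- purrr::imap_dfr(props, function(coll, nm) {
      p <- compute_properties(coll)
      p$source <- nm
      p
    })
  }
  if (!"source" %in% names(props)) props$source <- "collection"
  descriptors <- intersect(descriptors, names(props))
  long <- tidyr::pivot_longer(
    props[, c("source", descriptors)],
    cols = dplyr::all_of(descriptors),
    names_to = "descriptor", values_to = "value"
  )
  dplyr::summarise(
    dplyr::group_by(long, dataset = .data$source, .data$descriptor),
    min = min(.data$value),
    q1 = stats::quantile(.data$value, 0.25, type = quartile_type, names = FALSE),
    median = stats::median(.data$value),
    q3 = stats::quantile(.data$value, 0.75, type = quartile_type, names = FALSE),
    max = max(.data$value),
    mean = mean(.data$value),
    .groups = "drop"
  )
}
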