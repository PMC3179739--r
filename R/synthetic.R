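# Synthetic compound libraries with known ground truth for every pipeline
# stage. Molecules are built as a sampled ring-system scaffold plus terminal
# side-chain decorations, so the planted scaffold is provably the Murcko
# scaffold of the emitted molecule (no decoration can form a ring).
# Lipid-like members are fatty-acid chains that trigger the curation filter
# by construction; rule-of-five failures are planted by iodine-loading small
# scaffolds past the molecular-weight threshold.

# terminal decoration fragments: branch string, the fragment as a free
# molecule (for mass bookkeeping), and whether it is "light" (guaranteed not
# to push a small pass-safe scaffold over any Lipinski threshold)
.decorations <- data.frame(
  branch = c("C", "CC", "CCC", "O", "N", "OC", "F",
             "Cl", "Br", "C(=O)O", "C#N", "C(F)(F)F", "CO", "CN"),
  free   = c("C", "CC", "CCC", "O", "N", "CO", "F",
             "Cl", "Br", "C(=O)O", "C#N", "C(F)(F)F", "CO", "CN"),
  light  = c(TRUE, TRUE, FALSE, TRUE, TRUE, TRUE, TRUE,
             FALSE, FALSE, FALSE, FALSE, FALSE, TRUE, TRUE),
  # mass added when the branch replaces one hydrogen (standard atomic
  # weights)
  added_mw = c(14.027, 28.054, 42.081, 15.999, 15.015, 30.026, 17.990,
               34.445, 78.896, 44.009, 25.010, 67.998, 30.026, 29.041),
  stringsAsFactors = FALSE
)

#' Built-in scaffold pool
#'
#' The default pool of common ring systems (single rings, fused bicyclics,
#' linked ring assemblies, a steroid-like fused system) used by the
#' synthetic library generator. `aromatic` marks pools with at least one
#' aromatic ring; `pass_safe` marks small, low-lipophilicity scaffolds for
#' which a lightly decorated molecule is guaranteed to pass the
#' rule-of-five test.
#'
#' @return A tibble with columns `smiles`, `name`, `aromatic`, `pass_safe`.
#' @export
default_scaffold_pool <- function() {
  path <- system.file("extdata", "scaffold_pool.tsv", package = "scaffdiv")
  tibble::as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
}

#' Synthetic library specification
#'
#' @param n_molecules Library size.
#' @param scaffold_pool Pool tibble (see [default_scaffold_pool()]); rows
#'   need `smiles`, `name`, `aromatic` (and `pass_safe` when Ro5 failures
#'   are planted).
#' @param recurrence Scaffold recurrence distribution: `"zipf"` (skewed,
#'   rank weights `1/rank^zipf_s` over a shuffled pool -- many singletons,
#'   matching the skewed recurrence seen in real libraries), `"uniform"`, or
#'   `"explicit"` (give `explicit_counts`).
#' @param zipf_s Zipf exponent (default 1.5).
#' @param explicit_counts Named integer vector (names = pool scaffold
#'   names) used when `recurrence = "explicit"`.
#' @param aromatic_fraction Target fraction of molecules built on aromatic
#'   scaffolds (`NULL` leaves it to the recurrence sampling).
#' @param decoration_rate Mean number of terminal decorations per molecule
#'   (Poisson, capped by free positions).
#' @param lipid_fraction Fraction of molecules emitted as fatty-acid chains
#'   (C13-C20), which carry no scaffold and trigger the lipid filter.
#' @param ro5_fail_fraction Fraction of molecules planted to fail the
#'   rule-of-five (MW pushed beyond 500 by iodine decorations on pass-safe
#'   scaffolds; the remaining molecules are restricted to lightly decorated
#'   pass-safe scaffolds so their pass labels are also guaranteed).
#' @param name Dataset label.
#' @param seed Integer seed; generation is fully reproducible.
#' @return A `library_spec` list.
#' @export
library_spec <- function(n_molecules,
                         scaffold_pool = NULL,
                         recurrence = c("zipf", "uniform", "explicit"),
                         zipf_s = 1.5,
                         explicit_counts = NULL,
                         aromatic_fraction = NULL,
                         decoration_rate = 1.2,
                         lipid_fraction = 0,
                         ro5_fail_fraction = 0,
                         name = "synthetic",
                         seed = 1) {
  recurrence <- match.arg(recurrence)
  if (!is.numeric(n_molecules) || n_molecules < 1) {
    rlang::abort("`n_molecules` must be >= 1.")
  }
  for (f in c(lipid_fraction, ro5_fail_fraction)) {
    if (f < 0 || f > 1) rlang::abort("Fractions must be in [0, 1].")
  }
  if (recurrence == "explicit" && is.null(explicit_counts)) {
    rlang::abort("`explicit_counts` is required for explicit recurrence.")
  }
  structure(list(
    n_molecules = as.integer(n_molecules),
    scaffold_pool = scaffold_pool %||% default_scaffold_pool(),
    recurrence = recurrence,
    zipf_s = zipf_s,
    explicit_counts = explicit_counts,
    aromatic_fraction = aromatic_fraction,
    decoration_rate = decoration_rate,
    lipid_fraction = lipid_fraction,
    ro5_fail_fraction = ro5_fail_fraction,
    name = name,
    seed = as.integer(seed)
  ), class = "library_spec")
}

# sample() treats a length-1 numeric as 1:x; always index explicitly
sample_vec <- function(x, size = length(x), replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

# attachment positions (string offsets after the atom token incl. ring
# digits) of carbons carrying at least one implicit hydrogen, mapped through
# the SMILES token order = connection-table atom order
attachment_positions <- function(smiles) {
  toks <- gregexpr("Cl|Br|\\[[^]]+\\]|[BCNOSPFI]|[bcnops]", smiles)[[1]]
  lens <- attr(toks, "match.length")
  g <- mol_graph(smiles)
  a <- g$atoms
  stopifnot(length(toks) == nrow(a))
  pos <- integer(0)
  for (i in seq_along(toks)) {
    if (!(a$element[i] == "C" && a$h[i] >= 1)) next
    end <- toks[i] + lens[i] - 1L
    # include trailing ring-closure digits in the token
    while (end < nchar(smiles) && grepl("^[0-9%]", substr(smiles, end + 1L, end + 1L))) {
      end <- end + 1L
    }
    pos <- c(pos, end)
  }
  pos
}

decorate_smiles <- function(smiles, positions, branches) {
  if (length(positions) == 0) return(smiles)
  ord <- order(positions, decreasing = TRUE)
  for (k in ord) {
    smiles <- paste0(
      substr(smiles, 1, positions[k]),
      "(", branches[k], ")",
      substr(smiles, positions[k] + 1L, nchar(smiles))
    )
  }
  smiles
}

pool_attachments <- function(pool) {
  lapply(pool$smiles, attachment_positions)
}

pool_masses <- function(pool) {
  sdf <- smiles_to_sdfset(pool$smiles, paste0("s", seq_len(nrow(pool))))
  as.numeric(ChemmineR::propOB(sdf)$MW)
}

sample_scaffold_rows <- function(pool, n, recurrence, zipf_s, explicit_counts,
                                 aromatic_fraction) {
  if (recurrence == "explicit") {
    key <- if (all(names(explicit_counts) %in% pool$name)) pool$name else pool$smiles
    idx <- match(names(explicit_counts), key)
    if (anyNA(idx)) rlang::abort("`explicit_counts` names not found in the scaffold pool.")
    return(sample_vec(rep(idx, times = explicit_counts)))
  }
  weights_for <- function(rows) {
    p <- length(rows)
    w <- switch(recurrence,
      zipf = (seq_len(p))^(-zipf_s),
      uniform = rep(1, p)
    )
    # random rank assignment decouples recurrence rank from pool order
    setNames(w[sample.int(p)], rows)
  }
  if (is.null(aromatic_fraction)) {
    w <- weights_for(seq_len(nrow(pool)))
    return(sample_vec(as.integer(names(w)), n, replace = TRUE, prob = w))
  }
  n_arom <- round(aromatic_fraction * n)
  rows_a <- which(pool$aromatic)
  rows_n <- which(!pool$aromatic)
  if (length(rows_a) == 0 || length(rows_n) == 0) {
    rlang::abort("Pool must contain both aromatic and non-aromatic scaffolds for `aromatic_fraction`.")
  }
  wa <- weights_for(rows_a)
  wn <- weights_for(rows_n)
  out <- c(
    sample_vec(as.integer(names(wa)), n_arom, replace = TRUE, prob = wa),
    sample_vec(as.integer(names(wn)), n - n_arom, replace = TRUE, prob = wn)
  )
  sample_vec(out)
}

#' Generate a synthetic compound library with ground truth
#'
#' Each molecule is a sampled scaffold with sampled terminal decorations;
#' the emitted SMILES is canonical. The ground-truth sidecar records, per
#' molecule, the planted canonical scaffold (`NA` for lipids), the lipid
#' label and the planted rule-of-five label, so that pipeline recovery can
#' be checked exactly.
#'
#' @param spec A [library_spec()].
#' @return A list of class `"synthetic_library"` with elements `collection`
#'   (tibble: `id`, `smiles`, `source`), `truth` (tibble: `id`,
#'   `scaffold`, `scaffold_name`, `is_lipid`, `ro5_fail`,
#'   `n_decorations`), and `scaffold_counts` (realized counts per planted
#'   scaffold).
#' @export
generate_library <- function(spec) {
  stopifnot(inherits(spec, "library_spec"))
  withr::with_seed(spec$seed, generate_library_impl(spec))
}

generate_library_impl <- function(spec) {
  pool <- spec$scaffold_pool
  n <- spec$n_molecules
  n_lip <- round(spec$lipid_fraction * n)
  n_fail <- round(spec$ro5_fail_fraction * n)
  n_core <- n - n_lip - n_fail

  core_pool_rows <- seq_len(nrow(pool))
  if (n_fail > 0) {
    if (!"pass_safe" %in% names(pool)) {
      rlang::abort("Planting Ro5 failures requires a `pass_safe` column in the pool.")
    }
    core_pool_rows <- which(pool$pass_safe)
  }
  core_pool <- pool[core_pool_rows, , drop = FALSE]
  canon_pool <- ob_canonical(pool$smiles)
  attach <- pool_attachments(pool)

  smiles <- character(n)
  scaff_row <- rep(NA_integer_, n)
  is_lipid <- rep(FALSE, n)
  ro5_fail <- rep(FALSE, n)
  n_dec <- integer(n)

  slot <- sample_vec(rep(c("core", "fail", "lipid"), c(n_core, n_fail, n_lip)))

  # core molecules: scaffold + light-ish decorations
  core_idx <- which(slot == "core")
  if (length(core_idx)) {
    rows_local <- sample_scaffold_rows(
      core_pool, length(core_idx), spec$recurrence, spec$zipf_s,
      spec$explicit_counts, spec$aromatic_fraction
    )
    rows <- core_pool_rows[rows_local]
    dec_pool <- if (n_fail > 0) .decorations[.decorations$light, ] else .decorations
    for (k in seq_along(core_idx)) {
      i <- core_idx[k]
      r <- rows[k]
      pos <- attach[[r]]
      kk <- min(stats::rpois(1, spec$decoration_rate), length(pos), 2L + 2L * (n_fail == 0))
      scaff_row[i] <- r
      n_dec[i] <- kk
      if (kk > 0) {
        p_sel <- sample_vec(pos, kk)
        br <- sample_vec(dec_pool$branch, kk, replace = TRUE)
        smiles[i] <- decorate_smiles(pool$smiles[r], p_sel, br)
      } else {
        smiles[i] <- pool$smiles[r]
      }
    }
  }

  # planted Ro5 failures: iodine-load a pass-safe scaffold past MW 500
  fail_idx <- which(slot == "fail")
  if (length(fail_idx)) {
    mw_pool <- pool_masses(pool)
    m_iodine <- 126.90447 - 1.00794
    ok_rows <- core_pool_rows[vapply(core_pool_rows, function(r) {
      length(attach[[r]]) * m_iodine + mw_pool[r] > 510
    }, logical(1))]
    if (length(ok_rows) == 0) rlang::abort("No scaffold can carry enough iodines to fail Ro5.")
    for (i in fail_idx) {
      r <- sample_vec(ok_rows, 1)
      need <- ceiling((510 - mw_pool[r]) / m_iodine)
      kk <- min(max(need, 1L), length(attach[[r]]))
      p_sel <- sample_vec(attach[[r]], kk)
      smiles[i] <- decorate_smiles(pool$smiles[r], p_sel, rep("I", kk))
      scaff_row[i] <- r
      ro5_fail[i] <- TRUE
      n_dec[i] <- kk
    }
  }

  # lipid-like members: C13-C20 fatty acids (acyclic, no scaffold; the
  # saturated chain beyond the carboxyl carbon is >= 12 sp3 carbons, so the
  # curation filter removes them by construction)
  lip_idx <- which(slot == "lipid")
  if (length(lip_idx)) {
    chain <- sample_vec(12:19, length(lip_idx), replace = TRUE)
    smiles[lip_idx] <- paste0(strrep("C", chain), "C(=O)O")
    is_lipid[lip_idx] <- TRUE
    # long-chain fatty acids exceed the lipophilicity threshold
    ro5_fail[lip_idx] <- TRUE
  }

  ids <- sprintf("%s_%04d", spec$name, seq_len(n))
  can <- ob_canonical(smiles)
  if (anyNA(can)) {
    rlang::abort("Internal error: generated an unparsable structure.")
  }
  truth <- tibble::tibble(
    id = ids,
    scaffold = ifelse(is.na(scaff_row), NA_character_, canon_pool[scaff_row]),
    scaffold_name = ifelse(is.na(scaff_row), NA_character_, pool$name[scaff_row]),
    is_lipid = is_lipid,
    ro5_fail = ro5_fail,
    n_decorations = n_dec
  )
  collection <- tibble::tibble(id = ids, smiles = can, source = spec$name)
  attr(collection, "name") <- spec$name
  counts <- dplyr::count(
    dplyr::filter(truth, !is.na(.data$scaffold)),
    .data$scaffold,
    name = "count", sort = TRUE
  )
  structure(list(
    collection = collection,
    truth = truth,
    scaffold_counts = counts
  ), class = "synthetic_library")
}

#' Generate two libraries with a planted scaffold-pool overlap
#'
#' The two scaffold pools share exactly `round(overlap_fraction * pool_size)`
#' scaffolds, drawn from the built-in pool; with `ensure_realized = TRUE`
#' (default) every pool scaffold is used at least once, so the realized
#' shared-scaffold count equals the planted pool overlap.
#'
#' @param n_a,n_b Library sizes.
#' @param pool_size Scaffolds per library pool.
#' @param overlap_fraction Fraction of each pool that is shared, in \[0, 1\].
#' @param ensure_realized Guarantee each pool scaffold appears at least once
#'   (requires `n >= pool_size`).
#' @param seed Integer seed.
#' @param names Dataset labels for the pair.
#' @return A list with `a`, `b` (synthetic libraries) and `truth` (shared
#'   canonical scaffolds and planted overlap size).
#' @export
generate_overlapping_pair <- function(n_a, n_b, pool_size = 20,
                                      overlap_fraction = 0.5,
                                      ensure_realized = TRUE,
                                      seed = 1,
                                      names = c("lib_a", "lib_b")) {
  if (overlap_fraction < 0 || overlap_fraction > 1) {
    rlang::abort("`overlap_fraction` must be in [0, 1].")
  }
  pool <- default_scaffold_pool()
  n_shared <- round(overlap_fraction * pool_size)
  need <- 2 * pool_size - n_shared
  if (need > nrow(pool)) {
    rlang::abort(sprintf(
      "Pool overlap design needs %d distinct scaffolds but only %d are available.",
      need, nrow(pool)
    ))
  }
  idx <- withr::with_seed(seed, sample.int(nrow(pool), need))
  shared <- idx[seq_len(n_shared)]
  only_a <- idx[n_shared + seq_len(pool_size - n_shared)]
  only_b <- idx[pool_size - n_shared + n_shared + seq_len(pool_size - n_shared)]
  pool_a <- pool[c(shared, only_a), , drop = FALSE]
  pool_b <- pool[c(shared, only_b), , drop = FALSE]

  make <- function(p, n, nm, sd) {
    if (ensure_realized) {
      if (n < nrow(p)) rlang::abort("`ensure_realized` needs n >= pool_size.")
      extra <- stats::rmultinom(1, n - nrow(p), (seq_len(nrow(p)))^(-1.5))[, 1]
      counts <- setNames(1L + extra, p$name)
      sp <- library_spec(n, scaffold_pool = p,
        recurrence = "explicit", explicit_counts = counts,
        name = nm, seed = sd
      )
    } else {
      sp <- library_spec(n, scaffold_pool = p, name = nm, seed = sd)
    }
    generate_library(sp)
  }
  out <- withr::with_seed(seed + 1L, list(
    a = make(pool_a, n_a, names[1], seed + 2L),
    b = make(pool_b, n_b, names[2], seed + 3L)
  ))
  out$truth <- list(
    shared_scaffolds = ob_canonical(pool$smiles[shared]),
    n_shared_planted = n_shared
  )
  out
}

#' Generate a library biased toward target descriptor means
#'
#' Decoration sampling is steered until the per-molecule molecular weight
#' approximates a normal draw around `mw_mean`; achieved descriptor means
#' are recorded in the ground truth (generator self-report).
#'
#' @param n Library size.
#' @param mw_mean Target mean molecular weight (g/mol).
#' @param mw_sd Spread of per-molecule targets.
#' @param seed Integer seed.
#' @param name Dataset label.
#' @return A `synthetic_library` whose `truth` carries `achieved_mw_mean`.
#' @export
generate_property_biased <- function(n, mw_mean = 300, mw_sd = 25,
                                     seed = 1, name = "biased") {
  pool <- default_scaffold_pool()
  out <- withr::with_seed(seed, {
    attach <- pool_attachments(pool)
    mw_pool <- pool_masses(pool)
    frag_mw <- .decorations$added_mw
    npos <- lengths(attach)
    # a scaffold is usable when some decoration load can reach the target band
    usable <- which(mw_pool < mw_mean + mw_sd &
      mw_pool + npos * max(frag_mw) >= mw_mean - mw_sd)
    if (length(usable) == 0) {
      rlang::warn("No scaffold can reach the target mean; best effort.")
      usable <- order(abs(mw_pool - mw_mean))[1:3]
    }
    smiles <- character(n)
    for (i in seq_len(n)) {
      target <- stats::rnorm(1, mw_mean, mw_sd)
      r <- sample_vec(usable, 1)
      cur <- mw_pool[r]
      pos <- sample_vec(attach[[r]])
      br <- character(0)
      used <- integer(0)
      while (length(used) < length(pos)) {
        slots_left <- length(pos) - length(used)
        remaining <- target - cur
        if (remaining < min(frag_mw) / 2) break
        ok <- which(frag_mw <= remaining + min(frag_mw) / 2)
        if (length(ok) == 0) break
        # balance the mass deficit across remaining attachment slots
        ideal <- remaining / slots_left
        cand <- ok[order(abs(frag_mw[ok] - ideal))][1]
        used <- c(used, pos[length(used) + 1L])
        br <- c(br, .decorations$branch[cand])
        cur <- cur + frag_mw[cand]
      }
      smiles[i] <- decorate_smiles(pool$smiles[r], used, br)
    }
    smiles
  })
  can <- ob_canonical(out)
  ids <- sprintf("%s_%04d", name, seq_len(n))
  collection <- tibble::tibble(id = ids, smiles = can, source = name)
  attr(collection, "name") <- name
  ach <- mean(as.numeric(
    ChemmineR::propOB(smiles_to_sdfset(can, ids))$MW
  ))
  structure(list(
    collection = collection,
    truth = tibble::tibble(id = ids, target_mw_mean = mw_mean),
    achieved_mw_mean = ach
  ), class = "synthetic_library")
}
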