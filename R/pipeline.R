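# End-to-end orchestration: a single validated configuration drives
# curate -> fingerprint -> similarity -> properties -> scaffolds, writing
# the full set of report tables as CSV plus a JSON run manifest.

default_config <- function() {
  list(
    datasets = list(),
    standardize = list(neutralize = TRUE, ignore_stereo = TRUE),
    clustering = list(enabled = TRUE, target_reduction = 0.3, seed = 1,
                      n_samples = 5, sample_size = NULL),
    lipid_filter = list(enabled = FALSE, min_chain_len = 12, datasets = NULL),
    subset = list(enabled = TRUE, n = 2000, seed = 1),
    fingerprints = list(variant = "connectivity", orders = c(2, 4, 6, 8)),
    similarity = list(variant = "functional", order = 4, mode = "nonbinary"),
    ro5 = list(mw_max = 500, alogp_max = 5, hbd_max = 5, hba_max = 10),
    scaffolds = list(keep_exocyclic = FALSE, top_n = 5,
                     missing = NULL),
    output_dir = "scaffdiv_output"
  )
}

#' Validate a pipeline configuration
#'
#' Checks a configuration (a nested list, or a path to a YAML/JSON file)
#' against the pipeline schema: unknown keys are an error (fail-closed),
#' every referenced dataset path must exist, sizes must be positive, and
#' missing seeds are defaulted with a warning. Returns the fully merged
#' configuration.
#'
#' @param config Nested list, or path to a YAML or JSON configuration file.
#' @return The validated configuration list.
#' @export
validate_config <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- if (grepl("\\.json$", config, ignore.case = TRUE)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  if (!is.list(config)) rlang::abort("`config` must be a list or a path to a YAML/JSON file.")
  def <- default_config()
  errors <- character(0)

  unknown <- setdiff(names(config), names(def))
  if (length(unknown)) {
    errors <- c(errors, sprintf("Unknown configuration key(s): %s", paste(unknown, collapse = ", ")))
  }
  for (section in intersect(names(config), names(def))) {
    if (section == "datasets") next
    bad <- setdiff(names(config[[section]]), names(def[[section]]))
    if (length(bad)) {
      errors <- c(errors, sprintf("Unknown key(s) in `%s`: %s", section, paste(bad, collapse = ", ")))
    }
  }

  merged <- def
  for (section in intersect(names(config), names(def))) {
    if (is.list(def[[section]]) && section != "datasets") {
      merged[[section]][names(config[[section]])] <- config[[section]]
    } else {
      merged[[section]] <- config[[section]]
    }
  }

  if (length(merged$datasets) == 0) {
    errors <- c(errors, "At least one dataset must be configured.")
  }
  for (d in merged$datasets) {
    lab <- d$label %||% "<unlabelled>"
    if (is.null(d$path)) {
      errors <- c(errors, sprintf("Dataset '%s' has no path.", lab))
    } else if (!file.exists(d$path)) {
      errors <- c(errors, sprintf("Dataset '%s': path does not exist: %s", lab, d$path))
    }
  }
  labels <- vapply(merged$datasets, function(d) d$label %||% "", character(1))
  if (anyDuplicated(labels[nzchar(labels)])) {
    errors <- c(errors, "Dataset labels must be unique.")
  }
  if (!is.null(merged$subset$n) && merged$subset$n <= 0) {
    errors <- c(errors, "`subset.n` must be positive.")
  }
  tr <- merged$clustering$target_reduction
  if (!is.numeric(tr) || tr <= 0 || tr >= 1) {
    errors <- c(errors, "`clustering.target_reduction` must be in (0, 1).")
  }
  if (length(errors)) {
    rlang::abort(paste(c("Invalid configuration:", errors), collapse = "\n  - "))
  }
  for (key in c("clustering", "subset")) {
    if (is.null(config[[key]]$seed)) {
      rlang::warn(sprintf("`%s.seed` not set; defaulting to %d.", key, merged[[key]]$seed))
    }
  }
  merged
}

#' Run the full comparative diversity analysis
#'
#' Executes the complete pipeline on the configured datasets: read and
#' standardize, deduplicate, optional lipid filtering, clustering to
#' medoid representatives, seeded random subsets, then the four analysis
#' blocks -- feature-diversity curve, pairwise dataset Tanimoto matrix,
#' rule-of-five summary (clustered and random-subset columns),
#' property box-plot summaries, scaffold tables with shared-scaffold
#' matrix, top scaffolds, and (when configured) the missing-scaffold
#' report. All tables are written as CSV into `output_dir` together with a
#' JSON manifest (package version, seeds, per-stage record counts, config
#' hash). Reruns with identical configuration and seeds produce
#' byte-identical tables.
#'
#' @param config Configuration list or file path, see [validate_config()].
#' @return Invisibly, a list with every result table and the manifest.
#' @export
run_full_analysis <- function(config) {
  cfg <- validate_config(config)
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  stage_counts <- list()

  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      rlang::abort(sprintf("Pipeline stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  # --- curation ------------------------------------------------------------
  clustered <- list()
  subsets <- list()
  for (d in cfg$datasets) {
    lab <- d$label %||% sub("\\.[^.]*$", "", basename(d$path))
    coll <- run_stage(paste0("read:", lab), read_collection(d$path, format = d$format, name = lab))
    n_read <- nrow(coll)
    coll <- run_stage(paste0("standardize:", lab), suppressMessages(
      standardize_collection(coll,
        neutralize = cfg$standardize$neutralize,
        ignore_stereo = cfg$standardize$ignore_stereo
      )
    ))
    coll <- suppressMessages(dedup_collection(coll))
    n_dedup <- nrow(coll)
    apply_lipid <- isTRUE(cfg$lipid_filter$enabled) &&
      (is.null(cfg$lipid_filter$datasets) || lab %in% cfg$lipid_filter$datasets)
    if (apply_lipid) {
      coll <- run_stage(paste0("lipid_filter:", lab), suppressMessages(
        filter_lipids(coll, min_chain_len = cfg$lipid_filter$min_chain_len)
      ))
    }
    n_filtered <- nrow(coll)
    if (isTRUE(cfg$clustering$enabled) && nrow(coll) >= 4) {
      coll_cl <- run_stage(paste0("cluster:", lab), cluster_representatives(
        coll,
        target_reduction = cfg$clustering$target_reduction,
        sample_size = cfg$clustering$sample_size,
        n_samples = cfg$clustering$n_samples,
        seed = cfg$clustering$seed
      ))
    } else {
      coll_cl <- coll
    }
    clustered[[lab]] <- coll_cl
    subsets[[lab]] <- if (isTRUE(cfg$subset$enabled)) {
      suppressWarnings(random_subset(coll_cl, cfg$subset$n, seed = cfg$subset$seed))
    } else {
      coll_cl
    }
    stage_counts[[lab]] <- list(
      read = n_read, deduplicated = n_dedup, after_filter = n_filtered,
      clustered = nrow(coll_cl), subset = nrow(subsets[[lab]])
    )
  }

  out_file <- function(x) file.path(cfg$output_dir, x)

  # --- preliminary analysis: diversity + similarity on the subsets ---------
  div <- run_stage("diversity", diversity_curve(subsets,
    orders = cfg$fingerprints$orders, variant = cfg$fingerprints$variant
  ))
  utils::write.csv(div, out_file("diversity_curve.csv"), row.names = FALSE)

  sim_tidy <- NULL
  if (length(subsets) >= 2) {
    sim <- run_stage("similarity", dataset_similarity_matrix(subsets,
      variant = cfg$similarity$variant, order = cfg$similarity$order,
      mode = cfg$similarity$mode
    ))
    write_similarity_csv(sim, out_file("similarity_matrix.csv"))
    sim_tidy <- tidy(sim)
  } else {
    sim <- NULL
  }

  # --- properties ----------------------------------------------------------
  props_cl <- purrr::imap(clustered, function(c, nm) compute_properties(c))
  props_sub <- purrr::imap(subsets, function(c, nm) compute_properties(c))
  ro5 <- purrr::imap_dfr(props_cl, function(p, nm) {
    tibble::tibble(
      dataset = nm,
      n_clustered = nrow(p),
      pct_fail_clustered = ro5_failure_fraction(p,
        mw_max = cfg$ro5$mw_max, alogp_max = cfg$ro5$alogp_max,
        hbd_max = cfg$ro5$hbd_max, hba_max = cfg$ro5$hba_max
      ),
      n_subset = nrow(props_sub[[nm]]),
      pct_fail_subset = ro5_failure_fraction(props_sub[[nm]],
        mw_max = cfg$ro5$mw_max, alogp_max = cfg$ro5$alogp_max,
        hbd_max = cfg$ro5$hbd_max, hba_max = cfg$ro5$hba_max
      )
    )
  })
  utils::write.csv(ro5, out_file("ro5_summary.csv"), row.names = FALSE)

  prop_tbl <- dplyr::bind_rows(props_sub)
  summaries <- run_stage("properties", boxplot_summaries(prop_tbl))
  utils::write.csv(summaries, out_file("property_summaries.csv"), row.names = FALSE)

  # --- scaffold analysis (on the clustered datasets) -----------------------
  tables <- purrr::imap(clustered, function(c, nm) {
    run_stage(paste0("scaffolds:", nm), suppressWarnings(
      scaffold_table(c, keep_exocyclic = cfg$scaffolds$keep_exocyclic)
    ))
  })
  scaffold_summary <- purrr::map_dfr(tables, glance)
  utils::write.csv(scaffold_summary, out_file("scaffold_summary.csv"), row.names = FALSE)

  top <- purrr::imap_dfr(tables, function(t, nm) {
    out <- top_scaffolds(t, cfg$scaffolds$top_n)
    out$dataset <- nm
    dplyr::select(out, "dataset", "scaffold", "count", "pct")
  })
  utils::write.csv(top, out_file("top_scaffolds.csv"), row.names = FALSE)

  shared <- NULL
  if (length(tables) >= 2) {
    shared <- run_stage("shared_scaffolds", shared_scaffold_matrix(tables))
    utils::write.csv(as.data.frame(shared), out_file("shared_scaffolds.csv"),
      row.names = FALSE
    )
  }

  missing <- NULL
  mcfg <- cfg$scaffolds$missing
  if (!is.null(mcfg)) {
    for (key in c("source", "reference", "exclusion")) {
      if (is.null(mcfg[[key]]) || !mcfg[[key]] %in% names(tables)) {
        rlang::abort(sprintf("`scaffolds.missing.%s` must name a configured dataset.", key))
      }
    }
    missing <- run_stage("missing_scaffolds", missing_scaffold_report(
      tables[[mcfg$source]], tables[[mcfg$reference]], tables[[mcfg$exclusion]],
      min_similarity = mcfg$min_similarity %||% 0.9
    ))
    utils::write.csv(missing, out_file("missing_scaffolds.csv"), row.names = FALSE)
  }

  manifest <- list(
    package = "scaffdiv",
    version = as.character(utils::packageVersion("scaffdiv")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    config_hash = rlang::hash(cfg),
    seeds = list(clustering = cfg$clustering$seed, subset = cfg$subset$seed),
    stage_counts = stage_counts
  )
  jsonlite::write_json(manifest, out_file("manifest.json"),
    auto_unbox = TRUE, pretty = TRUE
  )

  invisible(list(
    clustered = clustered,
    subsets = subsets,
    diversity_curve = div,
    similarity = sim,
    similarity_pairs = sim_tidy,
    ro5_summary = ro5,
    property_summaries = summaries,
    scaffold_tables = tables,
    scaffold_summary = scaffold_summary,
    top_scaffolds = top,
    shared_scaffolds = shared,
    missing_scaffolds = missing,
    manifest = manifest
  ))
}
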