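test_that("Murcko scaffolds prune side chains but keep linkers", {
  expect_equal(murcko_scaffold("Cc1ccccc1"), "c1ccccc1")
  expect_equal(
    murcko_scaffold("C(c1ccccc1)Cc1ccccc1"),
    scaffdiv:::ob_canonical("c1ccc(CCc2ccccc2)cc1")
  )
  expect_true(is.na(murcko_scaffold("CCO")))
  # exocyclic carbonyl: pruned by default, retained behind the flag
  expect_equal(murcko_scaffold("O=C1CCCC1"), "C1CCCC1")
  expect_equal(
    murcko_scaffold("O=C1CCCC1", keep_exocyclic = TRUE),
    scaffdiv:::ob_canonical("O=C1CCCC1")
  )
  # element identity is retained: benzene and pyridine stay distinct
  expect_false(murcko_scaffold("Cc1ccccc1") == murcko_scaffold("Cc1ccncc1"))
})

test_that("scaffold extraction is idempotent and decoration invariant", {
  lib <- generate_library(library_spec(40, seed = 13))
  sc <- murcko_scaffold(lib$collection$smiles)
  keep <- !is.na(sc)
  expect_equal(murcko_scaffold(sc[keep]), sc[keep])
  # adding terminal substituents never changes the scaffold (planted truth)
  expect_equal(sc[keep], lib$truth$scaffold[keep])
})

test_that("scaffold tables count singletons and aromatic scaffolds", {
  coll <- make_coll(c("Cc1ccccc1", "CCc1ccccc1", "c1ccncc1"),
    ids = c("toluene", "ethylbenzene", "pyridine")
  )
  t <- scaffold_table(coll)
  expect_equal(nrow(t), 2)
  expect_equal(sort(t$count), c(1L, 2L))
  g <- glance(t)
  expect_equal(g$n_scaffolds, 2)
  expect_equal(g$n_singletons, 1)
  expect_equal(g$pct_singletons, 50)
  expect_equal(g$pct_aromatic, 100)
  expect_equal(g$pct_occurrence, 100 * 2 / 3, tolerance = 1e-12)

  expect_warning(t0 <- scaffold_table(make_coll(c("CCO", "CCC"))), "acyclic")
  expect_equal(nrow(t0), 0)
  expect_equal(glance(t0)$n_scaffolds, 0)
  expect_equal(glance(t0)$pct_singletons, 0)
})

test_that("planted singleton counts are recovered exactly", {
  pool <- default_scaffold_pool()
  counts <- stats::setNames(c(rep(1L, 8), rep(3L, 12)), pool$name[1:20])
  lib <- generate_library(library_spec(sum(counts),
    recurrence = "explicit", explicit_counts = counts, seed = 4
  ))
  g <- glance(scaffold_table(lib$collection))
  expect_equal(g$n_scaffolds, 20)
  expect_equal(g$n_singletons, 8)
})

test_that("top scaffolds rank by count with normalized percentages", {
  t <- structure(
    tibble::tibble(
      scaffold = c("benzene", "pyridine", "furan"),
      count = c(36L, 40L, 24L),
      n_rings = 1L, n_aromatic_rings = 1L, aromatic = TRUE
    ),
    class = c("scaffold_table", class(tibble::tibble())),
    dataset = "toy", dataset_size = 100L
  )
  top <- top_scaffolds(t, 1)
  expect_equal(top$scaffold, "pyridine")
  top_all <- top_scaffolds(t, 10)
  expect_equal(nrow(top_all), 3)
  expect_equal(sum(top_all$pct), 100, tolerance = 1e-9)
  expect_equal(top_all$pct[top_all$scaffold == "benzene"], 36)
})

test_that("shared-scaffold cells reproduce the printed-count arithmetic", {
  cell <- shared_scaffold_cell(1874, 296, 123)
  expect_equal(cell$pct_union, 6.0, tolerance = 0.01)
  expect_equal(cell$pct_a, 6.6, tolerance = 0.01)
  expect_equal(cell$pct_b, 41.6, tolerance = 0.01)
  expect_error(shared_scaffold_cell(10, 5, 6), "exceed")
})

test_that("shared-scaffold matrices match brute-force set intersection", {
  libs <- withr::with_seed(55, list(
    a = generate_library(library_spec(30, seed = 101, name = "a")),
    b = generate_library(library_spec(30, seed = 102, name = "b")),
    c = generate_library(library_spec(30, seed = 103, name = "c"))
  ))
  tables <- purrr::map(libs, ~ scaffold_table(.x$collection))
  m <- shared_scaffold_matrix(tables)
  for (r in seq_len(nrow(m))) {
    sa <- unique(tables[[m$dataset_a[r]]]$scaffold)
    sb <- unique(tables[[m$dataset_b[r]]]$scaffold)
    expect_equal(m$n_shared[r], length(intersect(sa, sb)))
    # union percentage is the binary Tanimoto of the scaffold sets
    expect_equal(m$pct_union[r], 100 * oracle_tanimoto_binary(sa, sb))
  }
  diag_rows <- m[m$dataset_a == m$dataset_b, ]
  expect_true(all(diag_rows$pct_union == 100))
  # pct_union <= min(pct_a, pct_b), all within [0, 100]
  expect_true(all(m$pct_union <= pmin(m$pct_a, m$pct_b) + 1e-9))
  expect_true(all(m$pct_union >= 0 & m$pct_union <= 100))

  # identical tables: everything shared
  m2 <- shared_scaffold_matrix(list(x = tables$a, y = tables$a))
  cell <- m2[m2$dataset_a == "x" & m2$dataset_b == "y", ]
  expect_equal(cell$n_shared, nrow(tables$a))
  expect_equal(cell$pct_union, 100)
})

test_that("missing-scaffold reports honour exclusion and the similarity threshold", {
  src <- scaffold_table(make_coll(
    c("Cc1ccccc1", "CC1CCNCC1", "CC1CCCCC1"), ids = c("s1", "s2", "s3")
  ))
  ref <- scaffold_table(make_coll(
    c("CCc1ccccc1", "CC1CCOCC1"), ids = c("r1", "r2")
  ))
  excl <- scaffold_table(make_coll("CC1CCNCC1", ids = "e1"))

  # identical scaffold (benzene) absent from exclusion: reported at 1.0
  rep1 <- missing_scaffold_report(src, ref, excl, min_similarity = 1)
  expect_equal(rep1$scaffold, "c1ccccc1")
  expect_equal(rep1$similarity, 1)

  # scaffolds in the exclusion set are never reported, at any threshold
  rep0 <- missing_scaffold_report(src, ref, excl, min_similarity = 0)
  expect_false(murcko_scaffold("CC1CCNCC1") %in% rep0$scaffold)

  # threshold behaviour matches brute-force best-match similarities
  cand <- setdiff(src$scaffold, excl$scaffold)
  best <- vapply(cand, function(s) {
    max(vapply(ref$scaffold, function(r) {
      tanimoto_binary(
        scaffdiv:::fp_multiset(s, "connectivity", 4),
        scaffdiv:::fp_multiset(r, "connectivity", 4)
      )
    }, numeric(1)))
  }, numeric(1))
  thr <- 0.5
  repT <- missing_scaffold_report(src, ref, excl, min_similarity = thr)
  expect_setequal(repT$scaffold, cand[best >= thr])

  expect_error(
    missing_scaffold_report(src, src[0, ], excl),
    "empty"
  )
})
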