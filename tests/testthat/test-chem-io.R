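test_that("SMILES files parse into collections with failures logged", {
  tf <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("c1ccccc1 benzene", "CCO ethanol", "CC(=O)O acetic_acid"), tf)
  coll <- read_collection(tf, name = "demo")
  expect_equal(nrow(coll), 3)
  expect_setequal(coll$id, c("benzene", "ethanol", "acetic_acid"))
  expect_true(all(coll$parse_ok))
  expect_equal(attr(coll, "name"), "demo")

  writeLines(c("CCO ethanol", "C1CC broken", "c1ccccc1 benzene", "# a comment"), tf)
  expect_message(coll2 <- read_collection(tf), "1 record")
  expect_equal(nrow(coll2), 2)

  writeLines("C1CC only_bad", tf)
  expect_error(read_collection(tf), "No parseable")
  expect_error(read_collection("does/not/exist.smi"), "does not exist")
})

test_that("write/read round trip preserves canonical structures (SMILES and SDF)", {
  coll <- make_coll(c("c1ccccc1", "CCO", "CC(=O)O", "Clc1ccc(cc1)C1CCNCC1",
                      "OCC1OC(O)C(O)C(O)C1O"))
  coll$smiles <- standardize_smiles(coll$smiles)
  for (fmt in c("smiles", "sdf")) {
    tf <- withr::local_tempfile(fileext = if (fmt == "sdf") ".sdf" else ".smi")
    write_collection(coll, tf, format = fmt)
    back <- read_collection(tf, format = fmt)
    expect_equal(sort(back$smiles), sort(coll$smiles), info = fmt)
    expect_setequal(back$id, coll$id)
  }
})

test_that("empty collections write with a warning", {
  tf <- withr::local_tempfile(fileext = ".smi")
  expect_warning(write_collection(make_coll(character(0)), tf), "empty")
  expect_true(file.exists(tf))
})

test_that("standardization strips salts, neutralizes, and is idempotent", {
  expect_equal(standardize_smiles("CC(=O)[O-].[Na+]"), "CC(=O)O")
  expect_equal(standardize_smiles("c1ccccc1"), "c1ccccc1")
  # quaternary nitrogen cannot lose a proton: charge retained
  expect_match(standardize_smiles("C[N+](C)(C)C"), "N\\+")
  # zwitterion: both centers are neutralizable
  expect_equal(standardize_smiles("[NH3+]CC(=O)[O-]"), standardize_smiles("NCC(=O)O"))

  mixed <- c("CC(=O)[O-].[Na+]", "c1ccccc1", "[NH3+]CCc1ccccc1",
             "CC(C)Cc1ccc(cc1)C(C)C(=O)O", "OC(=O)c1ccccc1.[Na+]")
  once <- standardize_smiles(mixed)
  twice <- standardize_smiles(once)
  expect_equal(twice, once)
})

test_that("canonicalization is idempotent on generated molecules", {
  lib <- generate_library(library_spec(40, seed = 42))
  can <- lib$collection$smiles
  expect_equal(scaffdiv:::ob_canonical(can), can)
})

test_that("deduplication keeps the first record per structure and is order-stable", {
  coll <- make_coll(c("c1ccccc1", "c1ccccc1", "CCO"), ids = c("a", "b", "c"))
  expect_message(out <- dedup_collection(coll), "1 duplicate")
  expect_equal(out$id, c("a", "c"))
  distinct <- make_coll(c("c1ccccc1", "CCO", "CC(=O)O"))
  expect_equal(nrow(dedup_collection(distinct)), 3)

  # planted duplicates shrink the collection by exactly k
  lib <- generate_library(library_spec(30, seed = 8))
  base <- suppressMessages(dedup_collection(lib$collection))
  k <- 7
  dup_rows <- base[withr::with_seed(1, sample(seq_len(nrow(base)), k)), ]
  dup_rows$id <- paste0(dup_rows$id, "_dup")
  planted <- dplyr::bind_rows(base, dup_rows)
  out <- suppressMessages(dedup_collection(planted))
  expect_equal(nrow(out), nrow(planted) - k)
  expect_equal(suppressMessages(dedup_collection(out))$id, out$id)
})
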