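test_that("initial codes respect symmetry and the functional halogen rule", {
  # all six benzene carbons share one initial code
  g <- scaffdiv:::mol_graph("c1ccccc1")
  expect_equal(length(unique(scaffdiv:::initial_atom_codes(g, "connectivity"))), 1)
  # the connectivity variant distinguishes the two ethanol carbons
  ge <- scaffdiv:::mol_graph("CCO")
  expect_equal(length(unique(scaffdiv:::initial_atom_codes(ge, "connectivity"))), 3)
  # functional variant: Cl and Br are one pharmacophoric type, so
  # chloro- and bromobenzene share their full order-0 feature set
  cl <- fingerprint_features(make_coll("Clc1ccccc1"), variant = "functional", order = 0)
  br <- fingerprint_features(make_coll("Brc1ccccc1"), variant = "functional", order = 0)
  expect_setequal(cl$feature, br$feature)
  # the connectivity variant keeps them apart
  cl_c <- fingerprint_features(make_coll("Clc1ccccc1"), variant = "connectivity", order = 0)
  br_c <- fingerprint_features(make_coll("Brc1ccccc1"), variant = "connectivity", order = 0)
  expect_false(setequal(cl_c$feature, br_c$feature))
})

test_that("circular fingerprints match hand-enumerated feature counts", {
  # methane: single heavy atom, one feature at order 0
  expect_equal(nrow(fingerprint_features(make_coll("C"), order = 0)), 1)
  # benzene at order 2: one atom-level + one first-shell feature, each with
  # six symmetry-equivalent instances
  bz <- fingerprint_features(make_coll("c1ccccc1"), order = 2)
  expect_equal(nrow(bz), 2)
  expect_equal(sort(unique(bz$count)), 6L)
})

test_that("feature sets are cumulative and permutation invariant", {
  lib <- generate_library(library_spec(30, seed = 77))
  feats <- fingerprint_features(lib$collection, order = 8)
  for (id in unique(feats$id)[1:10]) {
    f <- feats[feats$id == id, ]
    for (o in c(2, 4, 6)) {
      low <- f$feature[f$iter <= o / 2]
      high <- f$feature[f$iter <= o / 2 + 1]
      expect_true(all(low %in% high))
    }
  }
  # atom-order invariance: equivalent SMILES written differently
  a <- fingerprint_features(make_coll("OCC"), order = 4)
  b <- fingerprint_features(make_coll("CCO"), order = 4)
  expect_equal(
    dplyr::arrange(a[, c("feature", "count")], feature),
    dplyr::arrange(b[, c("feature", "count")], feature)
  )
})

test_that("dataset frequencies are additive over molecules and collections", {
  one <- dataset_feature_frequencies(make_coll("c1ccccc1"), order = 4)
  two <- dataset_feature_frequencies(
    make_coll(c("c1ccccc1", "c1ccccc1")), order = 4
  )
  merged <- dplyr::left_join(one, two, by = "feature")
  expect_equal(merged$freq.y, 2 * merged$freq.x)
  expect_equal(nrow(two), nrow(one))

  a <- make_coll(c("c1ccccc1", "CCO"))
  b <- make_coll(c("c1ccncc1", "CC(=O)O"), ids = c("m3", "m4"))
  fa <- dataset_feature_frequencies(a, order = 4)
  fb <- dataset_feature_frequencies(b, order = 4)
  fu <- dataset_feature_frequencies(dplyr::bind_rows(a, b), order = 4)
  manual <- dplyr::summarise(
    dplyr::group_by(dplyr::bind_rows(fa, fb), feature),
    freq = sum(freq), .groups = "drop"
  )
  expect_equal(
    dplyr::arrange(fu, feature)$freq,
    dplyr::arrange(manual, feature)$freq
  )
  expect_error(dataset_feature_frequencies(make_coll(character(0))), "empty")
})

test_that("non-redundant feature counts ignore duplication and grow with order", {
  coll <- make_coll(c("Cc1ccccc1O", "CC(N)C(=O)O"))
  dup <- dplyr::bind_rows(coll, coll)
  dup$id <- paste0("d", seq_len(nrow(dup)))
  expect_equal(
    nonredundant_feature_count(coll, order = 4),
    nonredundant_feature_count(dup, order = 4)
  )
  expect_gte(
    nonredundant_feature_count(coll, order = 8),
    nonredundant_feature_count(coll, order = 2)
  )
})

test_that("diversity curves are monotone and rank library diversity correctly", {
  expect_equal(nrow(diversity_curve(list(a = make_coll("CCO")), orders = integer(0))), 0)

  # low diversity: one scaffold, many decorations; high diversity: every
  # molecule a different scaffold
  pool <- default_scaffold_pool()
  low <- generate_library(library_spec(20,
    scaffold_pool = pool[pool$name == "benzene", ],
    recurrence = "uniform", seed = 5
  ))
  high <- generate_library(library_spec(20,
    recurrence = "explicit",
    explicit_counts = stats::setNames(rep(1L, 20), pool$name[1:20]),
    seed = 5
  ))
  curve <- diversity_curve(
    list(low = low$collection, high = high$collection),
    orders = c(2, 4, 6, 8)
  )
  for (ds in c("low", "high")) {
    v <- curve$n_features[curve$dataset == ds]
    expect_true(all(diff(v) >= 0))
  }
  wide <- tidyr::pivot_wider(curve, names_from = dataset, values_from = n_features)
  expect_true(all(wide$low < wide$high))
})
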