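test_that("binary Tanimoto matches set arithmetic", {
  expect_equal(tanimoto_binary(c("a", "b", "c"), c("a", "b", "c")), 1)
  expect_equal(tanimoto_binary(c("a", "b"), c("c", "d")), 0)
  expect_equal(tanimoto_binary(c("a", "b", "c"), c("a", "b", "d")), 0.5)
  expect_warning(out <- tanimoto_binary(character(0), character(0)), "empty")
  expect_equal(out, 0)
})

test_that("nonbinary Tanimoto matches the frequency formula", {
  expect_equal(
    tanimoto_nonbinary(c(a = 2, b = 1), c(a = 1, b = 1, c = 1)),
    0.6
  )
  v <- c(x = 3, y = 7)
  expect_equal(tanimoto_nonbinary(v, v), 1)
  expect_equal(tanimoto_nonbinary(c(a = 2), c(b = 5)), 0)
  expect_warning(out <- tanimoto_nonbinary(numeric(0), numeric(0)), "empty")
  expect_equal(out, 0)
  # frequency vectors are compared by value, not scale: T < 1 when one
  # dataset is a doubled copy of the other
  expect_lt(tanimoto_nonbinary(v, 2 * v), 1)
})

test_that("random multiset pairs agree with the naive oracles", {
  withr::with_seed(99, {
    for (i in 1:100) {
      a <- random_multiset()
      b <- random_multiset()
      expect_equal(tanimoto_binary(a, b), oracle_tanimoto_binary(names(a), names(b)),
        tolerance = 1e-12
      )
      tnb <- tanimoto_nonbinary(a, b)
      expect_equal(tnb, oracle_tanimoto_nonbinary(a, b), tolerance = 1e-12)
      expect_equal(tnb, tanimoto_nonbinary(b, a))
      expect_gte(tnb, 0)
      expect_lte(tnb, 1)
    }
  })
})

test_that("dataset similarity matrices are symmetric with unit diagonal", {
  a <- make_coll(c("c1ccccc1", "CCO", "Cc1ccccc1"))
  b <- make_coll(c("c1ccncc1", "CC(=O)O"))
  c3 <- make_coll(c("Clc1ccccc1", "CCN"))
  m <- dataset_similarity_matrix(list(A = a, B = b, C = c3), order = 4)
  expect_equal(diag(unclass(m)), c(A = 1, B = 1, C = 1))
  expect_equal(unclass(m), t(unclass(m)), tolerance = 1e-12)
  expect_true(all(m >= 0 & m <= 1))

  # matrix entries equal looped nonbinary coefficients on the frequency
  # vectors (oracle composition)
  fa <- dataset_feature_frequencies(a, variant = "functional", order = 4)
  fb <- dataset_feature_frequencies(b, variant = "functional", order = 4)
  expect_equal(m["A", "B"], tanimoto_nonbinary(fa, fb))

  # one dataset under two labels: off-diagonal 1
  m2 <- dataset_similarity_matrix(list(x = a, y = a))
  expect_equal(m2["x", "y"], 1)

  expect_error(
    dataset_similarity_matrix(list(A = a, B = make_coll(character(0)))),
    "B"
  )
  expect_error(dataset_similarity_matrix(list(only = a)), "two")
})

test_that("order sensitivity reports one matrix per order with sane trends", {
  a <- make_coll(c("Cc1ccccc1", "CCc1ccccc1"))
  rep1 <- order_sensitivity_report(list(x = a, y = a), orders = c(2, 4))
  expect_equal(nrow(rep1), 2)
  expect_true(all(rep1$tanimoto == 1))

  # libraries sharing only small fragments: higher orders dilute the shared
  # low-order features
  b <- make_coll(c("Oc1ccc(Cl)cc1", "NCc1cccnc1"))
  rep2 <- order_sensitivity_report(list(a = a, b = b), orders = c(2, 8))
  t2 <- rep2$tanimoto[rep2$order == 2]
  t8 <- rep2$tanimoto[rep2$order == 8]
  expect_lte(t8, t2)
})

test_that("similarity matrices tidy and export cleanly", {
  a <- make_coll(c("c1ccccc1", "CCO"))
  b <- make_coll("c1ccncc1")
  m <- dataset_similarity_matrix(list(A = a, B = b))
  td <- tidy(m)
  expect_equal(nrow(td), 1)
  expect_named(td, c("dataset_a", "dataset_b", "tanimoto"))
  tf <- withr::local_tempfile(fileext = ".csv")
  write_similarity_csv(m, tf)
  back <- utils::read.csv(tf, check.names = FALSE)
  expect_equal(back$dataset, c("A", "B"))
  expect_equal(back$A, unname(unclass(m)[, "A"]))
})
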