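test_that("descriptor conventions match hand counts", {
  p <- compute_properties(make_coll(c("CCO", "c1ccccc1"), ids = c("ethanol", "benzene")))
  et <- p[p$id == "ethanol", ]
  expect_equal(et$hbd, 1L)
  expect_equal(et$hba, 1L)
  expect_equal(et$n_rings, 0L)
  expect_equal(et$n_rotatable, 0L)
  bz <- p[p$id == "benzene", ]
  expect_equal(bz$n_rings, 1L)
  expect_equal(bz$hbd, 0L)
  expect_equal(bz$hba, 0L)
  expect_equal(bz$mpsa, 0)
  expect_equal(bz$mw, 78.11, tolerance = 0.01 / 78.11)

  # amide C-N is not rotatable; the flanking bonds are
  am <- compute_properties(make_coll("CCC(=O)NC"))
  expect_equal(am$n_rotatable, 1L)
  # fused bicyclic counts two rings
  naph <- compute_properties(make_coll("c1ccc2ccccc2c1"))
  expect_equal(naph$n_rings, 2L)
})

test_that("descriptors are invariant to input atom ordering", {
  a <- compute_properties(make_coll("OCC(N)c1ccccc1"))
  b <- compute_properties(make_coll("c1ccccc1C(N)CO"))
  cols <- c("mw", "alogp", "hbd", "hba", "mpsa", "n_rotatable", "logs", "n_rings")
  expect_equal(a[cols], b[cols])
})

test_that("rule-of-five violations use strict thresholds and are monotone", {
  props <- tibble::tibble(
    mw = c(180, 600, 500), alogp = c(1.3, 6, 5),
    hbd = c(1, 6, 5), hba = c(4, 11, 10)
  )
  expect_equal(ro5_violations(props), c(0L, 4L, 0L))

  base <- tibble::tibble(mw = 400, alogp = 4, hbd = 4, hba = 8)
  v0 <- ro5_violations(base)
  for (col in names(base)) {
    up <- base
    up[[col]] <- up[[col]] * 2
    expect_gte(ro5_violations(up), v0)
  }
})

test_that("failure fractions respond to planted failures and duplication", {
  passing <- compute_properties(make_coll(c("c1ccccc1", "CCO", "c1ccncc1")))
  expect_equal(ro5_failure_fraction(passing), 0)

  lib <- generate_library(library_spec(80, seed = 17, ro5_fail_fraction = 0.25))
  frac <- ro5_failure_fraction(lib$collection)
  expect_gte(frac, 20)
  expect_lte(frac, 30)

  # duplicating a failing molecule strictly increases the fraction
  props <- compute_properties(lib$collection)
  fail_row <- props[ro5_violations(props) >= 1, ][1, ]
  more <- dplyr::bind_rows(props, fail_row)
  expect_gt(ro5_failure_fraction(more), frac)
  expect_error(ro5_failure_fraction(props[0, ]), "empty")
})

test_that("boxplot summaries use linear-interpolation quartiles", {
  props <- tibble::tibble(source = "x", mw = c(1, 2, 3, 4, 5))
  s <- boxplot_summaries(props, descriptors = "mw")
  expect_equal(s$q1, 2)
  expect_equal(s$median, 3)
  expect_equal(s$q3, 4)
  expect_equal(s$min, 1)
  expect_equal(s$max, 5)

  const <- tibble::tibble(source = "y", mw = rep(7, 10))
  sc <- boxplot_summaries(const, descriptors = "mw")
  expect_equal(sc$min, sc$max)
  expect_equal(sc$mean, 7)
  expect_true(all(with(s, min <= q1 & q1 <= median & median <= q3 & q3 <= max)))
})

test_that("property-biased libraries land near their target means", {
  lo <- generate_property_biased(40, mw_mean = 300, seed = 6)
  hi <- generate_property_biased(40, mw_mean = 450, seed = 6)
  expect_lt(lo$achieved_mw_mean, hi$achieved_mw_mean)
  s <- boxplot_summaries(list(lo = lo$collection, hi = hi$collection),
    descriptors = "mw"
  )
  expect_equal(s$mean[s$dataset == "lo"], 300, tolerance = 10 / 300)
  expect_equal(s$mean[s$dataset == "hi"], 450, tolerance = 10 / 450)
})
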