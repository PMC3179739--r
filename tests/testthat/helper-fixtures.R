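# Shared fixtures and independent oracles, all built in code.

make_coll <- function(smiles, ids = paste0("m", seq_along(smiles)),
                      source = "test") {
  out <- tibble::tibble(id = ids, smiles = smiles, source = source)
  attr(out, "name") <- source
  out
}

# --- independent similarity oracles (naive set/sum arithmetic) -------------

oracle_tanimoto_binary <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  if (length(a) == 0 && length(b) == 0) return(0)
  n_ab <- sum(a %in% b)
  n_ab / (length(a) + length(b) - n_ab)
}

oracle_tanimoto_nonbinary <- function(va, vb) {
  feats <- unique(c(names(va), names(vb)))
  num <- 0
  da <- 0
  db <- 0
  for (f in feats) {
    xa <- if (f %in% names(va)) va[[f]] else 0
    xb <- if (f %in% names(vb)) vb[[f]] else 0
    num <- num + xa * xb
    da <- da + xa^2
    db <- db + xb^2
  }
  if (da + db == 0) return(0)
  num / (da + db - num)
}

random_multiset <- function(alphabet_size = 30, max_features = 12,
                           max_count = 6) {
  k <- sample.int(max_features, 1)
  feats <- sample(paste0("f", seq_len(alphabet_size)), k)
  stats::setNames(sample.int(max_count, k, replace = TRUE), feats)
}

# --- exhaustive k-medoids oracle (k = 2) -----------------------------------

oracle_best_medoid_cost <- function(d, k = 2) {
  d <- as.matrix(d)
  n <- nrow(d)
  best <- Inf
  for (med in utils::combn(n, k, simplify = FALSE)) {
    cost <- sum(apply(d[, med, drop = FALSE], 1, min))
    best <- min(best, cost)
  }
  best
}

medoid_cost <- function(d, medoids) {
  d <- as.matrix(d)
  sum(apply(d[, medoids, drop = FALSE], 1, min))
}
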