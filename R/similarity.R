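# Binary and frequency-weighted (nonbinary) Tanimoto coefficients, at the
# molecule and the whole-dataset level.

#' Binary Tanimoto coefficient
#'
#' `T_b = N_AB / (N_A + N_B - N_AB)` over distinct feature identifiers,
#' where `N_A` and `N_B` are the feature-set sizes and `N_AB` the number of
#' features common to both. When both sets are empty the coefficient is
#' degenerate (0/0) and is defined as 0 with a warning.
#'
#' @param a,b Feature sets: vectors of feature identifiers, or named count
#'   vectors / tibbles with a `feature` column (only the identifiers are
#'   used).
#' @return A coefficient in \[0, 1\].
#' @export
tanimoto_binary <- function(a, b) {
  fa <- feature_ids(a)
  fb <- feature_ids(b)
  if (length(fa) == 0 && length(fb) == 0) {
    rlang::warn("Both feature sets are empty; Tanimoto defined as 0.")
    return(0)
  }
  n_ab <- length(intersect(fa, fb))
  n_ab / (length(fa) + length(fb) - n_ab)
}

#' Frequency-weighted (nonbinary) Tanimoto coefficient
#'
#' `T_nb = sum(x_iA * x_iB) / (sum(x_iA^2) + sum(x_iB^2) - sum(x_iA * x_iB))`
#' with the sums running over the union of features (absent features count
#' 0). This is the dataset-level comparison: `x_iA` is the total occurrence
#' frequency of feature i in dataset A. Both-empty input is degenerate and
#' returns 0 with a warning.
#'
#' @param a,b Frequency vectors: named numeric vectors (names are feature
#'   identifiers) or tibbles with `feature` and `freq` columns as returned
#'   by [dataset_feature_frequencies()].
#' @return A coefficient in \[0, 1\]; exactly 1 iff the two frequency
#'   vectors are identical.
#' @export
tanimoto_nonbinary <- function(a, b) {
  va <- freq_vector(a)
  vb <- freq_vector(b)
  if (length(va) == 0 && length(vb) == 0) {
    rlang::warn("Both frequency vectors are empty; Tanimoto defined as 0.")
    return(0)
  }
  feats <- union(names(va), names(vb))
  xa <- xb <- numeric(length(feats))
  names(xa) <- names(xb) <- feats
  xa[names(va)] <- va
  xb[names(vb)] <- vb
  cross <- sum(xa * xb)
  denom <- sum(xa^2) + sum(xb^2) - cross
  if (denom == 0) return(0)
  cross / denom
}

feature_ids <- function(x) {
  if (is.data.frame(x)) return(unique(as.character(x$feature)))
  if (!is.null(names(x)) && length(x)) return(unique(names(x)))
  unique(as.character(x))
}

freq_vector <- function(x) {
  if (is.data.frame(x)) {
    return(setNames(as.numeric(x$freq), as.character(x$feature)))
  }
  if (is.null(names(x)) && length(x)) {
    rlang::abort("Frequency vectors must be named by feature identifier.")
  }
  setNames(as.numeric(x), names(x))
}

#' Pairwise dataset similarity matrix
#'
#' Computes all pairwise Tanimoto coefficients between datasets from their
#' circular-fingerprint feature frequency vectors. The default emulates the
#' whole-dataset comparison setting of the original analysis: functional
#' (FCFP-style) fingerprints of order 4 with frequency weighting.
#'
#' @param collections Named list (length >= 2) of collection tibbles.
#' @param variant Fingerprint variant.
#' @param order Fingerprint order.
#' @param mode `"nonbinary"` (frequency-weighted) or `"binary"`.
#' @return A `similarity_matrix` object: a symmetric numeric matrix with
#'   unit diagonal and dataset labels, carrying the fingerprint settings as
#'   attributes. Use [tidy()] for a long tibble.
#' @export
dataset_similarity_matrix <- function(collections,
                                      variant = c("functional", "connectivity"),
                                      order = 4,
                                      mode = c("nonbinary", "binary")) {
  variant <- match.arg(variant)
  mode <- match.arg(mode)
  if (length(collections) < 2) {
    rlang::abort("At least two collections are required.")
  }
  if (is.null(names(collections)) || any(!nzchar(names(collections)))) {
    names(collections) <- paste0("dataset_", seq_along(collections))
  }
  empty <- names(collections)[vapply(collections, nrow, integer(1)) == 0]
  if (length(empty)) {
    rlang::abort(sprintf("Empty collection(s): %s", paste(empty, collapse = ", ")))
  }
  freqs <- purrr::map(collections, dataset_feature_frequencies,
    variant = variant, order = order
  )
  labels <- names(collections)
  m <- diag(1, length(labels))
  dimnames(m) <- list(labels, labels)
  for (i in seq_along(labels)) {
    for (j in seq_len(i - 1L)) {
      v <- if (mode == "nonbinary") {
        tanimoto_nonbinary(freqs[[i]], freqs[[j]])
      } else {
        tanimoto_binary(freqs[[i]], freqs[[j]])
      }
      m[i, j] <- m[j, i] <- v
    }
  }
  structure(m,
    class = c("similarity_matrix", "matrix"),
    variant = variant, order = order, mode = mode
  )
}

#' @export
print.similarity_matrix <- function(x, digits = 2, ...) {
  cat(sprintf(
    "Dataset similarity matrix (%s Tanimoto, %s fingerprints, order %d)\n",
    attr(x, "mode"), attr(x, "variant"), attr(x, "order")
  ))
  m <- matrix(round(as.numeric(x), digits),
    nrow = nrow(x), dimnames = dimnames(x)
  )
  print(m, ...)
  invisible(x)
}

#' Tanimoto similarity across fingerprint orders
#'
#' Recomputes the pairwise frequency-weighted Tanimoto matrix at each
#' requested fingerprint order, reporting the per-pair trend. As fragment
#' size grows, shared small fragments are diluted by order-specific larger
#' ones, so coefficients typically drift downward with order (reported, not
#' asserted).
#'
#' @inheritParams dataset_similarity_matrix
#' @param orders Even fingerprint orders to evaluate.
#' @return A tibble with columns `order`, `dataset_a`, `dataset_b`, `tanimoto`.
#' @export
order_sensitivity_report <- function(collections, orders = c(2, 4, 6, 8),
                                     variant = c("functional", "connectivity"),
                                     mode = c("nonbinary", "binary")) {
  variant <- match.arg(variant)
  mode <- match.arg(mode)
  purrr::map_dfr(sort(orders), function(o) {
    m <- dataset_similarity_matrix(collections,
      variant = variant, order = o, mode = mode
    )
    out <- tidy.similarity_matrix(m)
    out$order <- as.integer(o)
    dplyr::select(out, "order", "dataset_a", "dataset_b", "tanimoto")
  })
}

#' @rdname dataset_similarity_matrix
#' @param x A `similarity_matrix`.
#' @param ... Unused.
#' @export
tidy.similarity_matrix <- function(x, ...) {
  labels <- rownames(x)
  pairs <- which(upper.tri(x, diag = FALSE), arr.ind = TRUE)
  tibble::tibble(
    dataset_a = labels[pairs[, 1]],
    dataset_b = labels[pairs[, 2]],
    tanimoto = x[pairs]
  )
}

#' Write a similarity matrix as CSV (labels as header row/column)
#'
#' @param x A `similarity_matrix`.
#' @param path Output CSV path.
#' @export
write_similarity_csv <- function(x, path) {
  df <- data.frame(dataset = rownames(x), unclass(x), check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
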