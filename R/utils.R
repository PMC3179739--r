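# Internal helpers shared across modules.

# V2000 charge-code column (C6 of the ChemmineR atomblock) -> formal charge
decode_charge <- function(code) {
  map <- c(`0` = 0, `1` = 3, `2` = 2, `3` = 1, `4` = 0, `5` = -1, `6` = -2, `7` = -3)
  out <- unname(map[as.character(code)])
  out[is.na(out)] <- 0
  out
}

encode_charge <- function(charge) {
  map <- c(`3` = 1, `2` = 2, `1` = 3, `0` = 0, `-1` = 5, `-2` = 6, `-3` = 7)
  out <- unname(map[as.character(charge)])
  out[is.na(out)] <- 0
  out
}

# default valences used to derive implicit hydrogen counts from a kekulized
# connection table
.default_valence <- c(
  B = 3, C = 4, N = 3, O = 2, P = 3, S = 2,
  F = 1, Cl = 1, Br = 1, I = 1
)

implicit_h <- function(element, charge, bond_order_sum) {
  val <- unname(.default_valence[element])
  val[is.na(val)] <- 0
  # charged-atom valence: N+/O+/S+/P+ gain a bond, anions lose one; the
  # carbocation is special-cased (3 bonds, no hydride gain)
  eff <- val + charge
  eff[element == "C" & charge > 0] <- 3
  eff[!(element %in% c("N", "P", "O", "S", "C")) & charge != 0] <-
    val[!(element %in% c("N", "P", "O", "S", "C")) & charge != 0]
  pmax(0L, as.integer(round(eff - bond_order_sum)))
}

# standard atomic weights for the elements the pipeline handles directly
.atomic_masses <- c(
  H = 1.008, B = 10.81, C = 12.011, N = 14.007, O = 15.999, P = 30.974,
  S = 32.06, F = 18.998, Cl = 35.453, Br = 79.904, I = 126.904, Na = 22.99,
  K = 39.098
)

# heavy-atom count of a single SMILES fragment, by token counting (bracket
# atoms, two-letter organic-subset halogens, then single-letter atoms)
heavy_atom_count <- function(smiles) {
  vapply(smiles, function(s) {
    n1 <- stringr::str_count(s, "\\[[^\\]]*\\]")
    s <- gsub("\\[[^\\]]*\\]", "", s)
    n2 <- stringr::str_count(s, "Cl|Br")
    s <- gsub("Cl|Br", "", s)
    n3 <- stringr::str_count(s, "[BCNOSPFIbcnosp]")
    as.integer(n1 + n2 + n3)
  }, integer(1), USE.NAMES = FALSE)
}

# textual removal of stereo annotations (tetrahedral marks and directional
# bonds); safe on valid SMILES and used when stereochemistry is ignored
strip_stereo <- function(smiles) {
  s <- gsub("@", "", smiles, fixed = TRUE)
  s <- gsub("/", "", s, fixed = TRUE)
  s <- gsub("\\", "", s, fixed = TRUE)
  # collapse brackets that became redundant, e.g. [CH] from [C@H] is left
  # as-is: OpenBabel re-normalizes them during canonicalization
  s
}

`%||%` <- rlang::`%||%`

assert_collection <- function(x, arg = "x") {
  if (!is.data.frame(x) || !all(c("id", "smiles") %in% names(x))) {
    rlang::abort(sprintf(
      "`%s` must be a collection data frame with at least `id` and `smiles` columns.",
      arg
    ))
  }
  invisible(x)
}

collection_name <- function(x, default = "collection") {
  attr(x, "name") %||%
    (if ("source" %in% names(x) && nrow(x) > 0) as.character(x$source[[1]]) else default)
}
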