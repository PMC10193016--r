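# Native extended-connectivity (Morgan) fingerprint, radius 2, folded to a
# fixed bit length. Atom identifiers start from (element, aromaticity,
# heavy degree, implicit-H count) and are iteratively refined by hashing
# the sorted (bond token, neighbor identifier) multiset; every identifier
# at every radius sets one folded bit. Bond tokens treat aromatic-aromatic
# ring bonds as a single class so the bits are invariant to the kekule
# structure chosen by the parser.

# deterministic 31-bit polynomial string hash
.str_hash <- function(s) {
  h <- 0
  for (v in utf8ToInt(s)) h <- (h * 131 + v) %% 2147483647
  h
}

# ECFP bit positions (1-based, folded) for one mol_graph
.ecfp_bits_one <- function(g, nbits, radius) {
  n <- .n_atoms(g)
  if (n == 0) return(integer(0))
  hcount <- .implicit_h(g)
  deg <- .degrees(g)
  lab <- vapply(seq_len(n), function(i)
    .str_hash(paste0(g$elements[i], if (g$aromatic[i]) "a" else "",
                     ":", deg[i], ":", hcount[i])), numeric(1))
  ids <- lab
  b <- g$bonds
  btok <- if (nrow(b)) ifelse(g$aromatic[b[, 1]] & g$aromatic[b[, 2]],
                              "a", as.character(b[, 3])) else character(0)
  nbr <- vector("list", n)
  for (i in seq_len(nrow(b))) {
    nbr[[b[i, 1]]] <- c(nbr[[b[i, 1]]], list(c(btok[i], b[i, 2])))
    nbr[[b[i, 2]]] <- c(nbr[[b[i, 2]]], list(c(btok[i], b[i, 1])))
  }
  for (r in seq_len(radius)) {
    lab <- vapply(seq_len(n), function(i) {
      parts <- vapply(nbr[[i]], function(e)
        paste0(e[1], "_", format(lab[as.integer(e[2])], scientific = FALSE)),
        character(1))
      .str_hash(paste0(format(lab[i], scientific = FALSE), "|",
                       paste(sort(parts), collapse = ",")))
    }, numeric(1))
    ids <- c(ids, lab)
  }
  unique(as.integer(ids %% nbits) + 1L)
}

#' Extended-connectivity fingerprints (radius 2)
#'
#' @param smiles character vector of canonical SMILES.
#' @param nbits folded length (default 2048).
#' @param radius neighborhood radius (default 2, the ECFP4 setting).
#' @return binary integer matrix, one row per molecule.
#' @export
ecfp_fingerprint <- function(smiles, nbits = 2048L, radius = 2L) {
  graphs <- .mol_graphs(smiles)
  out <- matrix(0L, length(smiles), nbits)
  for (i in seq_along(graphs)) {
    out[i, .ecfp_bits_one(graphs[[i]], nbits, radius)] <- 1L
  }
  out
}
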