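#' @importFrom stats median plogis predict quantile rnorm runif sd setNames
#' @importFrom utils head read.csv write.csv
NULL

#' Canonicalize SMILES strings
#'
#' Converts structure strings to the toolkit's canonical SMILES form
#' (OpenBabel canonical dialect). Multi-fragment inputs (salts, counter-ions)
#' are reduced to their largest organic fragment before canonicalization.
#' Canonicalization is idempotent: applying it to its own output is a fixed
#' point.
#'
#' @param smiles character vector of structure strings.
#' @param largest_fragment keep only the largest fragment of multi-fragment
#'   (dot-disconnected) inputs. Default `TRUE`.
#' @param on_error `"na"` (default) returns `NA` for unparseable inputs with
#'   a warning identifying them; `"error"` stops.
#' @return character vector of canonical SMILES, `NA` where invalid.
#' @examples
#' canonicalize_smiles(c("OCC", "CCO"))  # both ethanol
#' @export
canonicalize_smiles <- function(smiles, largest_fragment = TRUE,
                                on_error = c("na", "error")) {
  on_error <- match.arg(on_error)
  if (length(smiles) == 0) return(character(0))
  stopifnot(is.character(smiles))
  out <- rep(NA_character_, length(smiles))
  ok <- !is.na(smiles) & nzchar(trimws(smiles))
  if (any(ok)) {
    out[ok] <- .ob_canonical(smiles[ok])
    # An invalid entry can abort the remainder of a batch conversion;
    # retry the failures one at a time before declaring them invalid.
    retry <- ok & is.na(out)
    for (i in which(retry)) out[i] <- .ob_canonical(smiles[i])
  }
  if (largest_fragment) {
    multi <- !is.na(out) & grepl(".", out, fixed = TRUE)
    if (any(multi)) {
      out[multi] <- vapply(out[multi], .largest_fragment, character(1))
      out[multi] <- .ob_canonical(out[multi])
    }
  }
  bad <- is.na(out)
  if (any(bad)) {
    msg <- sprintf("unparseable SMILES rejected: %s",
                   paste(sprintf("[%d] '%s'", which(bad), smiles[bad]),
                         collapse = ", "))
    if (on_error == "error") stop(msg) else warning(msg, call. = FALSE)
  }
  out
}

# Batch OpenBabel SMI -> canonical SMILES; NA for entries OB drops.
.ob_canonical <- function(smiles) {
  n <- length(smiles)
  idx <- seq_len(n)
  inp <- paste(paste0(gsub("[ \t]", "", smiles), " m", idx), collapse = "\n")
  txt <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SMI", "CAN", inp)),
    error = function(e) "")
  res <- rep(NA_character_, n)
  if (!nzchar(txt)) return(res)
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (p in parts) {
    if (length(p) >= 2 && nzchar(p[[1]])) {
      i <- suppressWarnings(as.integer(sub("^m", "", p[[2]])))
      if (!is.na(i)) res[i] <- p[[1]]
    }
  }
  res
}

# Pick the fragment with the most heavy atoms (ties: longest string, then
# lexicographic) from a dot-disconnected SMILES.
.largest_fragment <- function(smi) {
  frags <- strsplit(smi, ".", fixed = TRUE)[[1]]
  counts <- vapply(frags, function(f) length(.smiles_atom_tokens(f)),
                   integer(1))
  frags <- frags[order(-counts, -nchar(frags), frags)]
  frags[[1]]
}

# Atom tokens of a SMILES string, in order of appearance.
.smiles_atom_tokens <- function(smi) {
  pat <- "\\[[^]]+\\]|Br|Cl|Si|Se|As|B|C|N|O|P|S|F|I|b|c|n|o|p|s|se|as|\\*"
  m <- gregexpr(pat, smi)[[1]]
  if (m[1] == -1) return(character(0))
  regmatches(smi, list(m))[[1]]
}

# TRUE where the token denotes an aromatic atom (lowercase SMILES atom).
.token_aromatic <- function(tokens) {
  core <- sub("^\\[[0-9]*", "", tokens)      # strip bracket + isotope
  substr(core, 1, 1) %in% c("b", "c", "n", "o", "p", "s")
}

#' Compute the seven physicochemical properties
#'
#' LogP (Wildman-Crippen as implemented in OpenBabel), hydrogen-bond donors
#' and acceptors, molecular weight (g/mol), topological polar surface area
#' (A^2), rotatable-bond count and ring count for each molecule. Rotatable
#' bonds are acyclic single bonds between two non-terminal heavy atoms;
#' rings are counted as the cyclomatic number (equals the number of smallest
#' rings).
#'
#' @param smiles character vector of (preferably canonical) SMILES.
#' @return data.frame with columns `logp`, `hbd`, `hba`, `mw`, `tpsa`,
#'   `rot_bonds`, `n_rings`, one row per input molecule.
#' @examples
#' compute_properties("CCO")  # ethanol: hbd 1, hba 1, mw ~46.07
#' @export
compute_properties <- function(smiles) {
  stopifnot(length(smiles) >= 1, !anyNA(smiles))
  mols <- .ob_mols(smiles)
  pr <- do.call(rbind, lapply(mols, ChemmineOB::prop_OB))
  graphs <- .mol_graphs(smiles)
  rot <- vapply(graphs, .count_rotatable_bonds, integer(1))
  rng <- vapply(graphs, .count_rings, integer(1))
  data.frame(
    logp = as.numeric(pr$logP),
    hbd = as.integer(pr$HBD),
    hba = as.integer(pr$HBA1),
    mw = as.numeric(pr$MW),
    tpsa = as.numeric(pr$TPSA),
    rot_bonds = rot,
    n_rings = rng
  )
}

.property_names <- c("logp", "hbd", "hba", "mw", "tpsa", "rot_bonds",
                     "n_rings")

# SMILES vector -> list of OpenBabel molecule handles, preserving order.
.ob_mols <- function(smiles) {
  inp <- paste(paste0(smiles, " m", seq_along(smiles)), collapse = "\n")
  mols <- ChemmineOB::forEachMol("SMILES", inp, identity)
  if (length(mols) != length(smiles))
    stop("invalid SMILES encountered during molecule parsing")
  mols
}

# Binary fingerprint matrix (rows = molecules) for an OpenBabel fingerprint
# name ("ECFP4", "MACCS", "FP2", ...).
.ob_fingerprint <- function(smiles, name) {
  m <- ChemmineOB::fingerprint_OB(.ob_mols(smiles), name)
  storage.mode(m) <- "integer"
  m
}
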