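# Lightweight molecular graph layer used by the augmentation engine and the
# property calculators. A graph is a list:
#   elements: character vector of element symbols (no explicit hydrogens)
#   aromatic: logical vector (from the SMILES aromatic perception)
#   bonds:    integer matrix [,c("a1","a2","order")], kekulized orders
# Hydrogens stay implicit throughout; cutting and rejoining single bonds
# preserves every atom's bond-order sum, so edits are valence-valid by
# construction. Formal charges are not carried through graph edits.

#' Parse a SMILES string into a molecular graph
#'
#' @param smiles a single valid SMILES string.
#' @return an object of class `mol_graph` (see source for layout).
#' @keywords internal
mol_graph <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1, !is.na(smiles))
  .mol_graphs(smiles)[[1]]
}

# Batched SMILES -> mol_graph list (one OpenBabel conversion round-trip).
.mol_graphs <- function(smiles) {
  stopifnot(is.character(smiles), !anyNA(smiles))
  inp <- paste(paste0(smiles, " m", seq_along(smiles)), collapse = "\n")
  txt <- suppressWarnings(ChemmineOB::convertFormat("SMI", "SDF",
                                                    paste0(inp, "\n")))
  if (!nzchar(txt)) stop("invalid SMILES in batch")
  blocks <- strsplit(txt, "\\$\\$\\$\\$\n?")[[1]]
  blocks <- blocks[nzchar(trimws(blocks))]
  if (length(blocks) != length(smiles))
    stop("invalid SMILES encountered during molfile conversion")
  lapply(seq_along(blocks), function(i) {
    g <- .parse_molfile(blocks[[i]])
    tokens <- .smiles_atom_tokens(smiles[[i]])
    heavy <- !(g$elements %in% "H")
    if (length(tokens) == sum(heavy)) {
      g$aromatic[heavy] <- .token_aromatic(tokens)
    }
    g
  })
}

# Parse the first V2000 molfile in `txt` (fixed-width columns).
.parse_molfile <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1]]
  counts <- lines[4]
  na <- as.integer(substr(counts, 1, 3))
  nb <- as.integer(substr(counts, 4, 6))
  atom_lines <- lines[4 + seq_len(na)]
  elements <- trimws(substr(atom_lines, 32, 34))
  if (nb > 0) {
    bond_lines <- lines[4 + na + seq_len(nb)]
    bonds <- cbind(a1 = as.integer(substr(bond_lines, 1, 3)),
                   a2 = as.integer(substr(bond_lines, 4, 6)),
                   order = as.integer(substr(bond_lines, 7, 9)))
  } else {
    bonds <- matrix(integer(0), ncol = 3,
                    dimnames = list(NULL, c("a1", "a2", "order")))
  }
  g <- list(elements = elements, aromatic = rep(FALSE, na), bonds = bonds)
  class(g) <- "mol_graph"
  g
}

.n_atoms <- function(g) length(g$elements)
.n_heavy <- function(g) sum(g$elements != "H")

# adjacency list: for each atom, integer vector of (neighbor, bond order)
.adjacency <- function(g) {
  adj <- vector("list", .n_atoms(g))
  b <- g$bonds
  for (i in seq_len(nrow(b))) {
    adj[[b[i, 1]]] <- rbind(adj[[b[i, 1]]], c(b[i, 2], b[i, 3]))
    adj[[b[i, 2]]] <- rbind(adj[[b[i, 2]]], c(b[i, 1], b[i, 3]))
  }
  adj
}

# igraph handle for a mol_graph (edge ids follow bond row order)
.igraph_of <- function(g) {
  ig <- igraph::make_empty_graph(n = .n_atoms(g), directed = FALSE)
  if (nrow(g$bonds))
    ig <- igraph::add_edges(ig, t(g$bonds[, 1:2, drop = FALSE]))
  ig
}

# Connected component containing `start`, with bond `skip` (row index of
# g$bonds) removed. Returns sorted atom indices.
.component_from <- function(g, start, skip = 0L) {
  ig <- .igraph_of(g)
  if (skip > 0L) ig <- igraph::delete_edges(ig, skip)
  sort(as.integer(igraph::subcomponent(ig, start)))
}

# Row indices of bridge bonds (removal disconnects the graph). Ring bonds
# are never bridges.
.bridge_bonds <- function(g) {
  if (nrow(g$bonds) == 0) return(integer(0))
  as.integer(igraph::bridges(.igraph_of(g)))
}

# Induced subgraph on atom indices `keep` (sorted); attaches `map`, the
# new index of each old atom (NA if dropped).
.subgraph <- function(g, keep) {
  keep <- sort(keep)
  map <- rep(NA_integer_, .n_atoms(g))
  map[keep] <- seq_along(keep)
  b <- g$bonds
  sel <- !is.na(map[b[, 1]]) & !is.na(map[b[, 2]])
  bonds <- b[sel, , drop = FALSE]
  bonds[, 1] <- map[bonds[, 1]]
  bonds[, 2] <- map[bonds[, 2]]
  out <- list(elements = g$elements[keep], aromatic = g$aromatic[keep],
              bonds = bonds, map = map)
  class(out) <- "mol_graph"
  out
}

# Join two graphs with a single bond between atom `a` of g1 and atom `b`
# of g2 (indices local to each graph).
.join_graphs <- function(g1, a, g2, b) {
  off <- .n_atoms(g1)
  bonds2 <- g2$bonds
  if (nrow(bonds2)) {
    bonds2[, 1] <- bonds2[, 1] + off
    bonds2[, 2] <- bonds2[, 2] + off
  }
  bonds <- rbind(g1$bonds, bonds2,
                 c(a1 = a, a2 = b + off, order = 1L))
  out <- list(elements = c(g1$elements, g2$elements),
              aromatic = c(g1$aromatic, g2$aromatic), bonds = bonds)
  class(out) <- "mol_graph"
  out
}

# V2000 molfile text for a graph (zero coordinates; OpenBabel re-perceives
# aromaticity and implicit hydrogens from elements + bond orders).
.graph_to_molfile <- function(g, title = "mol") {
  n <- .n_atoms(g)
  nb <- nrow(g$bonds)
  counts <- sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, nb)
  atoms <- sprintf("%10.4f%10.4f%10.4f %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   0, 0, 0, g$elements)
  bonds <- if (nb) sprintf("%3d%3d%3d  0  0  0  0",
                           g$bonds[, 1], g$bonds[, 2], g$bonds[, 3])
           else character(0)
  paste(c(title, "  molscreen", "", counts, atoms, bonds, "M  END", "$$$$", ""),
        collapse = "\n")
}

# Canonical SMILES of one or more graphs via OpenBabel; NA on failure.
.graphs_to_smiles <- function(graphs) {
  txt <- paste(vapply(seq_along(graphs),
                      function(i) .graph_to_molfile(graphs[[i]],
                                                    title = paste0("m", i)),
                      character(1)),
               collapse = "")
  out <- tryCatch(
    suppressWarnings(ChemmineOB::convertFormat("SDF", "CAN", txt)),
    error = function(e) "")
  res <- rep(NA_character_, length(graphs))
  if (!nzchar(out)) return(res)
  lines <- strsplit(out, "\n", fixed = TRUE)[[1]]
  lines <- lines[nzchar(lines)]
  for (p in strsplit(lines, "\t", fixed = TRUE)) {
    if (length(p) >= 2 && nzchar(p[[1]])) {
      i <- suppressWarnings(as.integer(sub("^m", "", trimws(p[[2]]))))
      if (!is.na(i)) res[i] <- p[[1]]
    }
  }
  res
}

# Canonical environment signature of radius `depth` around atom `a`,
# within graph g. A Morgan-style tree unfolding: at each step the walk may
# not immediately backtrack, branches are sorted, ring bonds between
# aromatic atoms contribute an order-independent "a" token so that the
# signature is invariant to the kekule structure chosen by the parser.
.env_signature <- function(g, a, depth, adj = .adjacency(g)) {
  .bond_token <- function(i, j, ord) {
    if (g$aromatic[i] && g$aromatic[j]) "a" else as.character(ord)
  }
  rec <- function(atom, d, parent) {
    lab <- paste0(g$elements[atom], if (g$aromatic[atom]) "'" else "")
    if (d == 0 || is.null(adj[[atom]])) return(lab)
    nb <- adj[[atom]]
    parts <- character(0)
    for (r in seq_len(nrow(nb))) {
      if (nb[r, 1] == parent) next
      parts <- c(parts, paste0(.bond_token(atom, nb[r, 1], nb[r, 2]),
                               rec(nb[r, 1], d - 1, atom)))
    }
    if (!length(parts)) return(lab)
    paste0(lab, "(", paste(sort(parts), collapse = ","), ")")
  }
  rec(a, depth, 0L)
}

# degree vector over heavy atoms
.degrees <- function(g) {
  n <- .n_atoms(g)
  d <- integer(n)
  b <- g$bonds
  for (i in seq_len(nrow(b))) {
    d[b[i, 1]] <- d[b[i, 1]] + 1L
    d[b[i, 2]] <- d[b[i, 2]] + 1L
  }
  d
}

# Implicit hydrogen count per atom from default valences minus the
# kekulized bond-order sum (floored at 0). Charged species are not
# handled (graph edits assume neutral organics).
.implicit_h <- function(g) {
  defval <- c(C = 4, N = 3, O = 2, S = 2, P = 3, F = 1, Cl = 1, Br = 1,
              I = 1, B = 3, Si = 4, Se = 2, H = 1)
  v <- defval[g$elements]
  v[is.na(v)] <- 0
  bsum <- numeric(.n_atoms(g))
  b <- g$bonds
  for (i in seq_len(nrow(b))) {
    bsum[b[i, 1]] <- bsum[b[i, 1]] + b[i, 3]
    bsum[b[i, 2]] <- bsum[b[i, 2]] + b[i, 3]
  }
  pmax(0, v - bsum)
}

# Rotatable bonds: acyclic (bridge) single bonds whose two atoms each have
# degree >= 2. Amide bonds are not excluded (documented choice).
.count_rotatable_bonds <- function(g) {
  if (nrow(g$bonds) == 0) return(0L)
  deg <- .degrees(g)
  br <- .bridge_bonds(g)
  n <- 0L
  for (i in br) {
    b <- g$bonds[i, ]
    if (b[["order"]] == 1L && deg[b[["a1"]]] >= 2 && deg[b[["a2"]]] >= 2)
      n <- n + 1L
  }
  n
}

# Ring count as cyclomatic number: bonds - atoms + components.
.count_rings <- function(g) {
  n <- .n_atoms(g)
  if (n == 0) return(0L)
  comp <- igraph::count_components(.igraph_of(g))
  as.integer(nrow(g$bonds) - n + comp)
}
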