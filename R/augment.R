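# Conservative fragment-replacement augmentation. Seed molecules are
# expanded into structural analogs by cutting single acyclic bonds and
# swapping the removed side for a library fragment whose attachment
# environment (a canonical radius-r signature around the attachment atom)
# matches the seed's retained side. Analogs inherit the seed's label under
# the continuous-SAR premise: an edit confined to an environment-matched
# site makes a large activity jump improbable.

#' Molecule record constructor
#'
#' Builds the canonical molecule table used throughout the package:
#' one row per molecule with id, canonical SMILES, class label
#' (1 active / 0 inactive / NA unknown), provenance and parent link.
#'
#' @param smiles structure strings (canonicalized on construction).
#' @param id molecule identifiers; default `mol_1`, `mol_2`, ...
#' @param label integer labels (1/0/NA).
#' @param provenance one of `"seed"`, `"augmented"`, `"library"`.
#' @param parent_id seed of origin for augmented molecules, else NA.
#' @param canonicalize canonicalize `smiles` first (default TRUE).
#' @return data.frame with columns id, smiles, label, provenance,
#'   parent_id. Invalid SMILES are dropped with a warning.
#' @export
molecule_records <- function(smiles, id = NULL, label = NA_integer_,
                             provenance = "seed", parent_id = NA_character_,
                             canonicalize = TRUE) {
  n <- length(smiles)
  if (is.null(id)) id <- paste0("mol_", seq_len(n))
  can <- if (canonicalize) canonicalize_smiles(smiles) else smiles
  rec <- data.frame(id = as.character(id), smiles = can,
                    label = rep_len(as.integer(label), n),
                    provenance = rep_len(provenance, n),
                    parent_id = rep_len(as.character(parent_id), n),
                    stringsAsFactors = FALSE)
  bad <- is.na(rec$smiles)
  if (any(bad)) rec <- rec[!bad, , drop = FALSE]
  aug <- rec$provenance == "augmented"
  if (any(aug & is.na(rec$parent_id)))
    stop("augmented records require a parent_id")
  rownames(rec) <- NULL
  rec
}

#' Augmentation configuration
#'
#' @param k analogs requested per seed (default 20, the study setting).
#' @param radius context conservatism radius for environment matching
#'   (default 3): a fragment may only be placed at a site whose retained
#'   radius-3 neighborhood matched the library environment key.
#' @param max_heavy_atom_delta cap on the heavy-atom count change of an
#'   edit (default 8), preventing runaway growth.
#' @param rng_seed integer seed making candidate sampling reproducible.
#' @return list of class `augment_config`.
#' @export
augment_config <- function(k = 20L, radius = 3L, max_heavy_atom_delta = 8L,
                           rng_seed = 1L) {
  stopifnot(k >= 0, radius >= 1)
  structure(list(k = as.integer(k), radius = as.integer(radius),
                 max_heavy_atom_delta = as.integer(max_heavy_atom_delta),
                 rng_seed = as.integer(rng_seed)),
            class = "augment_config")
}

#' Build a fragment library from a reference compound collection
#'
#' Every single acyclic (bridge) bond of every reference molecule is cut in
#' both orientations; the retained side is keyed by the canonical
#' signature of radius `radius` around its attachment atom and the removed
#' side is stored as a reattachable fragment under that key. Identical
#' environments collide to one key; fragments are deduplicated per key by
#' their own rooted canonical signature.
#'
#' @param ref_mols molecule records (or character SMILES) of the reference
#'   collection, e.g. [reference_fragment_collection()].
#' @param radius environment radius (default 3).
#' @return object of class `fragment_library`.
#' @export
build_fragment_library <- function(ref_mols, radius = 3L) {
  smiles <- if (is.data.frame(ref_mols)) ref_mols$smiles else ref_mols
  smiles <- unique(smiles[!is.na(smiles)])
  if (length(smiles) == 0) stop("empty reference set")
  entries <- new.env(parent = emptyenv())
  n_pairs <- 0L
  for (smi in smiles) {
    g <- try(mol_graph(smi), silent = TRUE)
    if (inherits(g, "try-error")) next
    adj <- .adjacency(g)
    for (i in .bridge_bonds(g)) {
      if (g$bonds[i, "order"] != 1L) next
      a <- g$bonds[i, "a1"]; b <- g$bonds[i, "a2"]
      for (ori in list(c(a, b), c(b, a))) {
        keep_atom <- ori[1]; drop_atom <- ori[2]
        keep <- .subgraph(g, .component_from(g, keep_atom, skip = i))
        frag <- .subgraph(g, .component_from(g, drop_atom, skip = i))
        key <- .env_signature(keep, keep$map[keep_atom], radius)
        fr <- .make_fragment(frag, frag$map[drop_atom])
        cur <- if (!is.null(entries[[key]])) entries[[key]] else list()
        if (is.null(cur[[fr$sig]])) {
          cur[[fr$sig]] <- fr
          entries[[key]] <- cur
          n_pairs <- n_pairs + 1L
        }
      }
    }
  }
  if (n_pairs == 0L) stop("reference set yielded no cuttable bonds")
  structure(list(entries = entries, radius = as.integer(radius),
                 n_pairs = n_pairs, source = length(smiles)),
            class = "fragment_library")
}

.make_fragment <- function(sub, attach) {
  sub$map <- NULL
  list(graph = sub, attach = attach,
       sig = .env_signature(sub, attach, 24L),
       nheavy = .n_heavy(sub))
}

#' @export
print.fragment_library <- function(x, ...) {
  cat(sprintf(
    "fragment_library: %d environment keys, %d (environment, fragment) pairs, radius %d, %d reference molecules\n",
    length(ls(x$entries)), x$n_pairs, x$radius, x$source))
  invisible(x)
}

# Enumerate all admissible edits for one seed graph. Three edit kinds, all
# gated by the same environment-key matching:
#   mutate - cut a single acyclic bond, swap the removed side for a library
#            fragment admissible at the retained side's environment key;
#   delete - cut and cap with hydrogen (fragment replaced by H);
#   grow   - attach a library fragment at an atom bearing an implicit
#            hydrogen whose environment key is in the library.
.enumerate_edits <- function(g, lib, cfg) {
  edits <- list()
  add <- function(e) edits[[length(edits) + 1L]] <<- e
  half <- .n_heavy(g) / 2
  for (i in .bridge_bonds(g)) {
    if (g$bonds[i, "order"] != 1L) next
    a <- g$bonds[i, "a1"]; b <- g$bonds[i, "a2"]
    for (ori in list(c(a, b), c(b, a))) {
      keep_atom <- ori[1]; drop_atom <- ori[2]
      keep <- .subgraph(g, .component_from(g, keep_atom, skip = i))
      # conservatism: the retained core must dominate the molecule
      if (.n_heavy(keep) < half) next
      dropped <- .subgraph(g, .component_from(g, drop_atom, skip = i))
      key <- .env_signature(keep, keep$map[keep_atom], cfg$radius)
      cand <- lib$entries[[key]]
      if (is.null(cand)) next
      drop_sig <- .env_signature(dropped, dropped$map[drop_atom], 24L)
      drop_nh <- .n_heavy(dropped)
      for (fr in cand) {
        if (fr$sig == drop_sig) next
        if (abs(fr$nheavy - drop_nh) > cfg$max_heavy_atom_delta) next
        add(list(type = "mutate", keep = keep, at = keep$map[keep_atom],
                 frag = fr))
      }
      if (drop_nh <= cfg$max_heavy_atom_delta && .n_heavy(keep) >= 2) {
        add(list(type = "delete", keep = keep, at = NA_integer_,
                 frag = NULL))
      }
    }
  }
  hcount <- .implicit_h(g)
  adj <- .adjacency(g)
  for (atom in which(hcount >= 1 & g$elements != "H")) {
    key <- .env_signature(g, atom, cfg$radius, adj = adj)
    cand <- lib$entries[[key]]
    if (is.null(cand)) next
    for (fr in cand) {
      if (fr$nheavy > cfg$max_heavy_atom_delta) next
      add(list(type = "grow", keep = g, at = atom, frag = fr))
    }
  }
  edits
}

.realize_edit <- function(edit) {
  if (edit$type == "delete") return(.strip_map(edit$keep))
  .join_graphs(.strip_map(edit$keep), edit$at, edit$frag$graph,
               edit$frag$attach)
}

.strip_map <- function(g) { g$map <- NULL; g }

#' Grow one seed molecule into conservative analogs
#'
#' Enumerates all admissible (site, fragment) replacement edits, shuffles
#' them reproducibly, and realizes edits until `cfg$k` unique valid analogs
#' distinct from the seed (and from `exclude`) are obtained.
#'
#' @param seed a one-row molecule record (or a single SMILES string).
#' @param lib a [build_fragment_library()] object.
#' @param cfg an [augment_config()].
#' @param exclude canonical SMILES that may not be emitted (global
#'   deduplication across a dataset).
#' @return molecule records of up to `cfg$k` analogs with
#'   `provenance = "augmented"`, the seed's label and `parent_id`. If fewer
#'   than `k` exist at this conservatism the shortfall is flagged via
#'   attribute `shortfall` and a warning.
#' @export
grow_molecule <- function(seed, lib, cfg = augment_config(),
                          exclude = character(0)) {
  stopifnot(inherits(lib, "fragment_library"))
  if (is.character(seed)) {
    seed <- molecule_records(seed, id = "seed_1")
  }
  stopifnot(nrow(seed) == 1)
  if (cfg$k == 0L) return(seed[0, , drop = FALSE])
  g <- mol_graph(seed$smiles)
  edits <- .enumerate_edits(g, lib, cfg)
  out <- character(0)
  if (length(edits)) {
    set.seed(cfg$rng_seed)
    edits <- edits[sample.int(length(edits))]
    taken <- c(seed$smiles, exclude)
    chunk <- max(16L, 2L * cfg$k)
    pos <- 1L
    while (length(out) < cfg$k && pos <= length(edits)) {
      idx <- pos:min(length(edits), pos + chunk - 1L)
      pos <- pos + length(idx)
      graphs <- lapply(edits[idx], .realize_edit)
      smis <- .graphs_to_smiles(graphs)
      for (s in smis) {
        if (is.na(s) || s %in% taken) next
        taken <- c(taken, s)
        out <- c(out, s)
        if (length(out) >= cfg$k) break
      }
    }
  }
  shortfall <- cfg$k - length(out)
  if (shortfall > 0) {
    warning(sprintf("seed %s: only %d of %d analogs realizable at radius %d",
                    seed$id, length(out), cfg$k, lib$radius), call. = FALSE)
  }
  rec <- molecule_records(out,
                          id = sprintf("%s_a%d", seed$id, seq_along(out)),
                          label = seed$label, provenance = "augmented",
                          parent_id = seed$id, canonicalize = FALSE)
  attr(rec, "shortfall") <- as.integer(max(shortfall, 0L))
  rec
}

#' Augment a labeled seed dataset
#'
#' Applies [grow_molecule()] to every seed with global deduplication by
#' canonical SMILES: an analog colliding with another seed or a previously
#' emitted analog is dropped and regenerated from the remaining candidate
#' edits where possible.
#'
#' @param seeds labeled molecule records.
#' @param lib a [build_fragment_library()].
#' @param cfg an [augment_config()]; per-seed RNG streams are derived from
#'   `cfg$rng_seed` plus the seed's row index.
#' @param strict error (rather than warn) on any per-seed shortfall.
#' @return molecule records: the seeds followed by their analogs. Attribute
#'   `shortfall` holds the per-seed shortfall counts.
#' @export
augment_dataset <- function(seeds, lib, cfg = augment_config(),
                            strict = FALSE) {
  stopifnot(is.data.frame(seeds), nrow(seeds) >= 1)
  if (anyNA(seeds$label)) stop("all seeds must be labeled")
  pieces <- vector("list", nrow(seeds))
  taken <- seeds$smiles
  shortfalls <- integer(nrow(seeds))
  for (i in seq_len(nrow(seeds))) {
    cfg_i <- cfg
    cfg_i$rng_seed <- cfg$rng_seed + i
    rec <- withCallingHandlers(
      grow_molecule(seeds[i, , drop = FALSE], lib, cfg_i, exclude = taken),
      warning = function(w) {
        if (strict) stop(conditionMessage(w), call. = FALSE)
        warning(w); invokeRestart("muffleWarning")
      })
    shortfalls[i] <- attr(rec, "shortfall")
    attr(rec, "shortfall") <- NULL
    taken <- c(taken, rec$smiles)
    pieces[[i]] <- rec
  }
  analogs <- do.call(rbind, pieces)
  base_cols <- c("id", "smiles", "label", "provenance", "parent_id")
  extra <- setdiff(names(seeds), base_cols)
  for (col in extra) analogs[[col]] <- rep(NA, nrow(analogs))
  out <- rbind(seeds[, c(base_cols, extra), drop = FALSE],
               analogs[, c(base_cols, extra), drop = FALSE])
  rownames(out) <- NULL
  attr(out, "shortfall") <- shortfalls
  out
}
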