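# Oracle used below: an analog is a one-site edit of its parent iff some
# single acyclic cut of the analog leaves a retained side whose canonical
# SMILES equals a retained side obtainable from the parent. This walks an
# independent path (subgraph SMILES comparison) from the engine's edit
# bookkeeping.
retained_sides <- function(smiles) {
  g <- molscreen:::mol_graph(smiles)
  sides <- list()
  for (i in molscreen:::.bridge_bonds(g)) {
    if (g$bonds[i, "order"] != 1) next
    for (atom in g$bonds[i, 1:2]) {
      keep <- molscreen:::.subgraph(
        g, molscreen:::.component_from(g, atom, skip = i))
      keep$map <- NULL
      sides[[length(sides) + 1L]] <- keep
    }
  }
  unique(stats::na.omit(molscreen:::.graphs_to_smiles(sides)))
}

test_that("a single-molecule reference yields the hand-enumerated library", {
  # ethane has one cuttable C-C bond; both orientations give the same
  # (environment = methyl, fragment = methyl) pair
  lib <- build_fragment_library("CC", radius = 3)
  expect_s3_class(lib, "fragment_library")
  keys <- ls(lib$entries)
  expect_length(keys, 1)
  frags <- lib$entries[[keys]]
  expect_length(frags, 1)
  expect_equal(frags[[1]]$nheavy, 1)
  expect_equal(frags[[1]]$graph$elements, "C")
})

test_that("empty or uncuttable reference sets error", {
  expect_error(build_fragment_library(character(0)), "empty")
  expect_error(build_fragment_library("c1ccccc1"), "cuttable")
})

test_that("a finer radius never admits more edits at the same seed", {
  ref <- fx_seeds_small()
  lib1 <- build_fragment_library(ref, radius = 1)
  lib3 <- build_fragment_library(ref, radius = 3)
  seed <- fx_seeds_small()[3, ]
  g <- molscreen:::mol_graph(seed$smiles)
  n1 <- length(molscreen:::.enumerate_edits(g, lib1, augment_config(radius = 1)))
  n3 <- length(molscreen:::.enumerate_edits(g, lib3, augment_config(radius = 3)))
  expect_lte(n3, n1)
})

test_that("a seed is editable against a library built from itself", {
  seed <- fx_seeds_small()[1, ]
  lib <- build_fragment_library(seed$smiles, radius = 3)
  out <- suppressWarnings(grow_molecule(seed, lib, augment_config(k = 5)))
  expect_gte(nrow(out), 1)
  expect_false(seed$smiles %in% out$smiles)
})

test_that("k = 0 returns an empty analog set", {
  seed <- fx_seeds_small()[1, ]
  out <- grow_molecule(seed, fx_fragment_library(), augment_config(k = 0))
  expect_equal(nrow(out), 0)
})

test_that("analogs are valid, unique, label-conserving and conservative", {
  lib <- fx_fragment_library()
  seeds <- fx_seeds_small()[c(2, 9, 25), ]
  cfg <- augment_config(k = 10, rng_seed = 77)
  aug <- quiet_augment(seeds, lib, cfg)
  analogs <- aug[aug$provenance == "augmented", ]
  expect_gte(nrow(analogs), 25)
  # validity: every emitted SMILES is its own canonical form
  expect_identical(canonicalize_smiles(analogs$smiles), analogs$smiles)
  # uniqueness across the whole augmented dataset
  expect_false(anyDuplicated(aug$smiles) > 0)
  # label conservation and parent links
  expect_identical(analogs$label,
                   seeds$label[match(analogs$parent_id, seeds$id)])
  expect_true(all(analogs$parent_id %in% seeds$id))
  # conservatism: each analog shares a retained side with its parent
  for (parent in seeds$id) {
    ps <- retained_sides(seeds$smiles[seeds$id == parent])
    kid <- analogs[analogs$parent_id == parent, ]
    for (s in kid$smiles) {
      expect_gt(length(intersect(retained_sides(s), ps)), 0)
    }
  }
})

test_that("augmentation is deterministic given seeds, library and rng_seed", {
  lib <- fx_fragment_library()
  seeds <- fx_seeds_small()[1:3, ]
  cfg <- augment_config(k = 8, rng_seed = 5)
  a1 <- quiet_augment(seeds, lib, cfg)
  a2 <- quiet_augment(seeds, lib, cfg)
  expect_identical(a1, a2)
})

test_that("shortfalls are flagged, warned, and error under strict mode", {
  tiny <- build_fragment_library("CC", radius = 3)
  seeds <- fx_seeds_small()[1, ]
  expect_warning(out <- augment_dataset(seeds, tiny, augment_config(k = 20)),
                 "analogs realizable")
  expect_gt(attr(out, "shortfall")[1], 0)
  expect_error(
    suppressWarnings(augment_dataset(seeds, tiny, augment_config(k = 20),
                                     strict = TRUE)))
})

test_that("augmented records demand a parent id", {
  expect_error(molecule_records("CCO", provenance = "augmented"),
               "parent_id")
})
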