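test_that("canonicalization is idempotent and resolves graph identity", {
  smis <- c("OCC", "CCO", "c1ccccc1", "CC(=O)Oc1ccccc1C(=O)O",
            "N1CCCCC1", "O=C1CC(O)CC(C)O1")
  can <- canonicalize_smiles(smis)
  expect_false(anyNA(can))
  expect_identical(canonicalize_smiles(can), can)  # fixed point
  expect_identical(can[1], can[2])                 # both ethanol
})

test_that("unparseable SMILES are rejected with the input identified", {
  expect_warning(res <- canonicalize_smiles(c("CCO", "C1CC")),
                 "C1CC")
  expect_false(is.na(res[1]))
  expect_true(is.na(res[2]))
  expect_error(canonicalize_smiles("C1CC", on_error = "error"), "C1CC")
})

test_that("multi-fragment salts reduce to the largest organic fragment", {
  salt <- suppressWarnings(canonicalize_smiles("CC(=O)[O-].[Na+]"))
  plain <- canonicalize_smiles("CC(=O)O")
  # the organic anion is kept; counter-ion dropped
  expect_false(grepl(".", salt, fixed = TRUE))
  expect_false(grepl("Na", salt))
})

test_that("the seven properties match hand-checked reference molecules", {
  p <- compute_properties(c("C", "c1ccccc1", "CCO"))
  # methane: no donors/acceptors/rings/rotors
  expect_equal(p$hbd[1], 0)
  expect_equal(p$hba[1], 0)
  expect_equal(p$n_rings[1], 0)
  expect_equal(p$rot_bonds[1], 0)
  # benzene: one aromatic ring, rigid, no donors
  expect_equal(p$n_rings[2], 1)
  expect_equal(p$rot_bonds[2], 0)
  expect_equal(p$hbd[2], 0)
  # ethanol: 1 donor, 1 acceptor, MW from standard atomic masses
  expect_equal(p$hbd[3], 1)
  expect_equal(p$hba[3], 1)
  expect_equal(p$mw[3], 46.07, tolerance = 1e-3)
  expect_true(all(p$mw > 0))
})

test_that("featurization Z-scores the property block and is deterministic", {
  seeds <- fx_seeds_small()
  f <- featurize(seeds)
  expect_equal(ncol(f$features), 2048 + 166 + 7)
  prop_cols <- grep("^prop_", colnames(f$features))
  mu <- colMeans(f$features[, prop_cols])
  sdv <- apply(f$features[, prop_cols], 2, sd)
  nonconst <- f$scaler$sd > 0
  expect_equal(unname(mu[nonconst]), rep(0, sum(nonconst)), tolerance = 1e-10)
  expect_equal(unname(sdv[nonconst]), rep(1, sum(nonconst)), tolerance = 1e-10)
  # fingerprint blocks are binary
  fp_cols <- grep("^(ecfp|maccs)_", colnames(f$features))
  expect_true(all(f$features[, fp_cols] %in% c(0, 1)))
  # pure function of (SMILES, scaler): byte-identical on repeat
  f2 <- featurize(seeds)
  expect_identical(f$features, f2$features)
  # duplicate molecules give identical rows
  dup <- featurize(seeds[c(1, 1, 2), ], scaler = f$scaler)
  expect_identical(dup$features[1, ], dup$features[2, ])
})

test_that("a scaler fitted on a set reproduces fit-transform when reapplied", {
  seeds <- fx_seeds_small()
  f <- featurize(seeds)
  f_re <- featurize(seeds, scaler = f$scaler)
  expect_identical(f$features, f_re$features)
  # x = mu maps to 0
  p <- f$properties[1, , drop = FALSE]
  p[1, ] <- f$scaler$mean
  expect_equal(unname(apply_scaler(p, f$scaler)[1, ]), rep(0, 7))
})

test_that("zero-spread property columns are scaled to 0 with a warning", {
  same <- molecule_records(c("CCO", "CCO"), id = c("a", "b"))
  expect_warning(f <- featurize(same), "zero-spread")
  prop_cols <- grep("^prop_", colnames(f$features))
  expect_true(all(f$features[, prop_cols] == 0))
})

test_that("empty input errors", {
  expect_error(featurize(character(0)), "empty")
})

test_that("Tanimoto similarity: identity is 1, disjoint is 0", {
  fp <- ecfp_fingerprint(c("CCO", "CCO", "c1ccc2cc(Cl)ccc2c1"))
  s <- tanimoto(fp)
  expect_equal(diag(s), rep(1, 3))
  expect_equal(s[1, 2], 1)               # identical molecules
  a <- rbind(c(1, 1, 0, 0), c(0, 0, 1, 1))
  expect_equal(tanimoto(a)[1, 2], 0)     # disjoint bits
  expect_true(all(s >= 0 & s <= 1))
})
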