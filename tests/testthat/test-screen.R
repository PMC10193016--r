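test_that("similarity-network degrees match a brute-force Tanimoto oracle", {
  lib <- molecule_records(c("CCO", "CCCO", "c1ccccc1", "Cc1ccccc1",
                            "c1ccc2ccccc2c1"),
                          id = paste0("m", 1:5))
  fp <- ecfp_fingerprint(lib$smiles)
  net <- build_similarity_network(lib, edge_threshold = 0.3, fp = fp)
  # oracle: all-pairs loop with an independent Tanimoto
  deg <- setNames(integer(5), lib$id)
  for (i in 1:4) for (j in (i + 1):5) {
    if (bf_tanimoto(fp[i, ], fp[j, ]) >= 0.3) {
      deg[i] <- deg[i] + 1L
      deg[j] <- deg[j] + 1L
    }
  }
  expect_identical(net$neighbor_count, deg)
  # symmetry: each edge counted in both endpoint degrees
  expect_equal(sum(net$neighbor_count), 2 * nrow(net$edges))
})

test_that("duplicate structures connect at similarity 1; threshold 1 keeps only them", {
  lib <- molecule_records(c("CCO", "OCC", "c1ccccc1"), id = c("a", "b", "d"))
  net <- build_similarity_network(lib, edge_threshold = 1.0)
  expect_equal(nrow(net$edges), 1)
  expect_equal(net$edges$similarity, 1)
  expect_setequal(c(net$edges$id1, net$edges$id2), c("a", "b"))
  empty <- build_similarity_network(lib[0, ], 0.5)
  expect_length(empty$neighbor_count, 0)
})

test_that("the 2-D embedding honors its contract", {
  set.seed(8)
  x <- matrix(rnorm(30 * 6), 30)
  x[2, ] <- x[1, ]  # planted exact duplicate
  emb <- embed_2d(x, perplexity = 5, rng_seed = 2)
  expect_equal(dim(emb), c(30, 2))
  expect_identical(emb, embed_2d(x, perplexity = 5, rng_seed = 2))
  d <- as.matrix(dist(emb))
  expect_lt(d[1, 2], quantile(d[upper.tri(d)], 0.01))
  expect_error(embed_2d(x, perplexity = 30), "perplexity")
  expect_error(embed_2d(x[1:2, ], perplexity = 1), "at least 3")
})

test_that("hit filtering applies every stated bound inclusively", {
  rec <- data.frame(
    id = c("hit", "prob_hi", "small", "lonely"),
    smiles = "CCO",
    probability = c(0.75, 0.95, 0.75, 0.75),
    neighbor_count = c(4L, 4L, 4L, 1L),
    logp = c(3, 3, 3, 3), hbd = c(2, 2, 2, 2), hba = c(5, 5, 5, 5),
    mw = c(400, 400, 250, 400), tpsa = 60, rot_bonds = 4, n_rings = 2,
    stringsAsFactors = FALSE)
  res <- filter_hits(rec, hit_criteria())
  expect_equal(res$hits$id, "hit")
  expect_equal(nrow(res$audit), 4)
  expect_false(res$audit$pass_prob[res$audit$id == "prob_hi"])  # above 0.9
  expect_false(res$audit$pass_mw[res$audit$id == "small"])      # below 300
  expect_false(res$audit$pass_neighbors[res$audit$id == "lonely"])
  # inclusive bounds
  rec$probability[1] <- 0.9
  rec$mw[1] <- 1000
  expect_equal(filter_hits(rec, hit_criteria())$hits$id, "hit")
})

test_that("missing probabilities are flagged, not dropped", {
  rec <- data.frame(id = c("a", "b"), smiles = "CCO",
                    probability = c(NA, 0.7), neighbor_count = c(5L, 5L),
                    logp = 3, hbd = 1, hba = 4, mw = 400, tpsa = 60,
                    rot_bonds = 3, n_rings = 2, stringsAsFactors = FALSE)
  res <- filter_hits(rec)
  expect_equal(nrow(res$audit), 2)
  expect_true(res$audit$missing_probability[res$audit$id == "a"])
  expect_false(res$audit$hit[res$audit$id == "a"])
})

test_that("tightening any single bound never increases the hit count", {
  set.seed(5)
  n <- 60
  rec <- data.frame(
    id = paste0("m", 1:n), smiles = "CCO",
    probability = runif(n), neighbor_count = rpois(n, 4),
    logp = runif(n, -1, 7), hbd = rpois(n, 2), hba = rpois(n, 5),
    mw = runif(n, 150, 1200), tpsa = runif(n, 10, 150),
    rot_bonds = rpois(n, 4), n_rings = rpois(n, 2),
    stringsAsFactors = FALSE)
  base <- hit_criteria()
  n0 <- nrow(filter_hits(rec, base)$hits)
  tighter <- list(
    hit_criteria(prob_min = 0.7), hit_criteria(prob_max = 0.8),
    hit_criteria(min_neighbors = 5), hit_criteria(hba_range = c(0, 6)),
    hit_criteria(hbd_range = c(0, 2)), hit_criteria(clogp_range = c(1, 4)),
    hit_criteria(mw_range = c(350, 800)))
  for (cr in tighter) {
    expect_lte(nrow(filter_hits(rec, cr)$hits), n0)
  }
})
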