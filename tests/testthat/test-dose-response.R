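test_that("normalization maps rates to percent of the negative control", {
  tab <- data.frame(
    compound = "c", form = "lactone",
    concentration_uM = c(1, 10, 0, 0),
    replicate = c(1, 1, 1, 2),
    rate = c(1.2, 0.6, 1.3, 1.1),   # control mean 1.2
    control_flag = c("treated", "treated", "negative", "negative"))
  norm <- normalize_activity(tab)
  expect_equal(norm$activity_pct, c(100, 50))   # identity and linearity
  # group means equal an independent aggregate
  agg <- tapply(norm$activity_pct, norm$concentration_uM, mean)
  expect_equal(unname(agg[["1"]]), 100)
  expect_error(normalize_activity(tab[tab$control_flag == "treated", ]),
               "negative control")
})

test_that("batch-wise normalization uses each batch's own control", {
  tab <- data.frame(
    compound = "c", form = "acid",
    concentration_uM = c(1, 0, 1, 0), replicate = 1,
    rate = c(1, 2, 2, 4), control_flag = rep(c("treated", "negative"), 2),
    batch = c("p1", "p1", "p2", "p2"))
  norm <- normalize_activity(tab)
  expect_equal(norm$activity_pct, c(50, 50))
})

test_that("noiseless 4PL data are recovered exactly", {
  truth <- fourpl_params(min_resp = 40, max_resp = 100, ic50 = 10, hill = 1)
  tab <- generate_dose_response(assay_config(truth, noise_sd = 0))
  fit <- fit_4pl(normalize_activity(tab))
  expect_true(fit$reliable)
  expect_equal(fit$params$min_resp, 40, tolerance = 1e-4)
  expect_equal(fit$params$max_resp, 100, tolerance = 1e-4)
  expect_equal(fit$ic50, 10, tolerance = 1e-4)
  expect_equal(fit$params$hill, 1, tolerance = 1e-4)
  expect_equal(fit$max_inhibition, 60, tolerance = 1e-3)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("the response at X = IC50 is the midpoint of the asymptotes", {
  p <- fourpl_params(25, 110, 3.7, 1.8)
  expect_equal(fourpl_response(p$ic50, p), (25 + 110) / 2)
})

test_that("flat data give a poor fit flagged unreliable and called inactive", {
  flat <- fourpl_params(99.5, 100, 50, 1)
  tab <- generate_dose_response(assay_config(flat, rng_seed = 3))
  fit <- fit_4pl(normalize_activity(tab))
  expect_lt(fit$r_squared, 0.18)
  expect_equal(classify_activity(fit), "inactive")
})

test_that("too few concentrations error", {
  norm <- data.frame(concentration_uM = c(1, 1, 10, 10),
                     activity_pct = c(90, 92, 60, 62))
  expect_error(fit_4pl(norm), "4 distinct")
})

test_that("activity calls honor the inclusive R-squared boundary", {
  mk_fit <- function(r2) structure(
    list(params = fourpl_params(40, 100, 10, 1), ic50 = 10,
         max_inhibition = 60, r_squared = r2,
         se = c(min_resp = 3, max_resp = 3, log10_ic50 = 0.1, hill = 0.2),
         reliable = TRUE, n_concentrations = 10),
    class = "dose_response_fit")
  expect_equal(classify_activity(mk_fit(0.18), r2_min = 0.18), "inhibitor")
  expect_equal(classify_activity(mk_fit(0.10), r2_min = 0.18), "inactive")
})

test_that("a strong synthetic inhibitor is called an inhibitor", {
  truth <- fourpl_params(30, 100, 5, 1)   # 70% max inhibition
  tab <- generate_dose_response(assay_config(truth, noise_sd = 2,
                                             rng_seed = 11))
  fit <- fit_4pl(normalize_activity(tab))
  expect_equal(classify_activity(fit), "inhibitor")
})

test_that("IC50 is scale-equivariant; asymptotes and slope are invariant", {
  truth <- fourpl_params(35, 100, 8, 1.2)
  tab <- generate_dose_response(assay_config(truth, noise_sd = 3,
                                             rng_seed = 5))
  norm <- normalize_activity(tab)
  f1 <- fit_4pl(norm)
  norm10 <- norm
  norm10$concentration_uM <- norm10$concentration_uM * 10
  f10 <- fit_4pl(norm10)
  expect_equal(f10$ic50, 10 * f1$ic50, tolerance = 1e-3)
  expect_equal(f10$params$min_resp, f1$params$min_resp, tolerance = 1e-3)
  expect_equal(f10$params$max_resp, f1$params$max_resp, tolerance = 1e-3)
  expect_equal(f10$params$hill, f1$params$hill, tolerance = 1e-3)
})

test_that("fits of decreasing data are monotone decreasing", {
  for (s in 1:5) {
    truth <- fourpl_params(45, 100, 12, 1)
    tab <- generate_dose_response(assay_config(truth, rng_seed = s))
    fit <- fit_4pl(normalize_activity(tab))
    expect_lte(fourpl_response(100, fit$params),
               fourpl_response(0.1, fit$params))
  }
})
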