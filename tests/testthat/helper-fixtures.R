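# Shared fixtures, built once per test session. The fragment library is
# the expensive one (~1 min); every test that needs one reuses this cache.

.fx <- new.env(parent = emptyenv())

fx_fragment_library <- function() {
  if (is.null(.fx$lib)) {
    ref <- reference_fragment_collection()
    .fx$lib <- build_fragment_library(ref, radius = 3)
  }
  .fx$lib
}

fx_seeds_small <- function() {
  if (is.null(.fx$seeds_small)) {
    .fx$seeds_small <- generate_sar_dataset(
      sar_config(n_active = 20, n_inactive = 14, rng_seed = 42))
  }
  .fx$seeds_small
}

# quiet wrapper for augmentation shortfall warnings in tests that do not
# assert on them
quiet_augment <- function(...) suppressWarnings(augment_dataset(...))

# brute-force Tanimoto of two 0/1 vectors (independent of tanimoto())
bf_tanimoto <- function(a, b) {
  inter <- sum(a == 1 & b == 1)
  uni <- sum(a == 1 | b == 1)
  if (uni == 0) 0 else inter / uni
}
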