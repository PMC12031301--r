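# Shared fixtures, built in code.

# Brute-force leave-one-out influence: the O(n^2) oracle for looInfluence.
brute_loo <- function(x, y, statistic = "r") {
  n <- length(x)
  r_all <- cor(x, y)
  vapply(seq_len(n), function(k) {
    r_k <- cor(x[-k], y[-k])
    if (statistic == "r2") r_k^2 - r_all^2 else r_k - r_all
  }, numeric(1L))
}

# A small split regression dataset for optimizer-level tests.
small_split_dataset <- function(n = 80, noiseSd = 0, seed = 42,
                                splitSeed = 7) {
  ds <- syntheticDataset(n = n, noiseSd = noiseSd, seed = seed)
  splitLabels(ds) <- randomSplit(length(ds), seed = splitSeed)
  ds
}

# Deterministic bag construction from explicit keys.
bag_of <- function(keys, mult = rep(1L, length(keys)),
                   family = rep("Sk", length(keys))) {
  structure(as.integer(mult), names = keys, family = family,
            class = "attrBag")
}

expect_cwqsar_error <- function(expr, class) {
  expect_error(expr, class = class)
}

# Seeded shuffle that leaves the session RNG untouched.
with_seed_shuffle <- function(x, seed) {
  old <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  sample(x)
}
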