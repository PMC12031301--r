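test_that("target functions reproduce hand arithmetic", {
  expect_equal(targetValue(0.8, 0.8, 0, 0, config = targetConfig("T1")),
               1.6)
  expect_equal(targetValue(0.8, 0.6, 0.5, 0.7, config = targetConfig("T1")),
               1.9, tolerance = 1e-12)
  expect_equal(targetValue(0.8, 0.6, 0.5, 0.7, cccp = 0.6,
                           config = targetConfig("T2")),
               2.08, tolerance = 1e-12)
  expect_cwqsar_error(
    targetValue(0.8, 0.6, 0.5, 0.7, cccp = NA_real_,
                config = targetConfig("T2")),
    "missing_criterion")
  # f3 = 0 reduces T2 to T1 even without a CCCP value
  expect_equal(targetValue(0.8, 0.6, 0.5, 0.7, cccp = NA_real_,
                           config = targetConfig("T2", f3 = 0)),
               1.9, tolerance = 1e-12)
  expect_cwqsar_error(targetConfig(f1 = -0.1), "config_error")
})

test_that("zero epochs returns the initialized state with empty trace", {
  ds <- small_split_dataset(n = 60, noiseSd = 0.3, seed = 19)
  run <- mcOptimize(ds, epochs = 0, seed = 4, threshold = 2, warmup = 0)
  expect_null(run$trace)
  w <- cwWeights(run$model)
  active <- setdiff(names(w), blockedKeys(run$model))
  # initialization = seeded jitter around init (default 0), untouched by
  # any epoch; the final slope normalization rescales all weights by one
  # common factor, so the stored weights are proportional to the jitter
  jitter <- local({ set.seed(4L); runif(length(active), -0.1, 0.1) })
  ratio <- unname(w[active]) / jitter
  expect_lt(diff(range(ratio)), 1e-9 * max(abs(ratio)))
  expect_true(all(w[blockedKeys(run$model)] == 0))
})

test_that("optimization is bit-reproducible for a fixed seed", {
  ds <- small_split_dataset(n = 60, noiseSd = 0.3, seed = 19)
  r1 <- mcOptimize(ds, epochs = 2, seed = 8, threshold = 2)
  r2 <- mcOptimize(ds, epochs = 2, seed = 8, threshold = 2)
  expect_identical(cwWeights(r1$model), cwWeights(r2$model))
  expect_identical(coef(r1$model), coef(r2$model))
  expect_identical(r1$trace, r2$trace)
  r3 <- mcOptimize(ds, epochs = 2, seed = 9, threshold = 2)
  expect_false(identical(cwWeights(r1$model), cwWeights(r3$model)))
})

test_that("per-epoch best target never decreases and ends above start", {
  ds <- small_split_dataset(n = 80, noiseSd = 0.3, seed = 23)
  run <- mcOptimize(ds, epochs = 6, seed = 2, threshold = 2)
  expect_true(all(diff(run$trace$target) >= 0))
})

test_that("validation endpoints are never read during training", {
  ds <- small_split_dataset(n = 80, noiseSd = 0.3, seed = 31)
  shuffled <- ds
  iV <- which(splitLabels(ds) == "V")
  ep <- endpoints(ds)
  ep[iV] <- with_seed_shuffle(ep[iV], 99)
  shuffled@endpoint <- ep
  r1 <- mcOptimize(ds, epochs = 2, seed = 3, threshold = 2)
  r2 <- mcOptimize(shuffled, epochs = 2, seed = 3, threshold = 2)
  expect_identical(cwWeights(r1$model), cwWeights(r2$model))
  expect_identical(coef(r1$model), coef(r2$model))
})

test_that("empty subsets and over-blocking raise typed errors", {
  ds <- syntheticDataset(n = 20, seed = 3, noiseSd = 0.3)
  expect_cwqsar_error(mcOptimize(ds, epochs = 1, seed = 1), "split_error")
  splitLabels(ds) <- randomSplit(length(ds), seed = 2)
  expect_cwqsar_error(mcOptimize(ds, epochs = 1, seed = 1,
                                 threshold = 10000L),
                      "degenerate_descriptor")
})

test_that("promoters are attributes positive in every run", {
  ds <- small_split_dataset(n = 80, noiseSd = 0.1, seed = 57)
  runs <- lapply(c(5, 6, 7), function(s) {
    mcOptimize(ds, epochs = 4, seed = s, threshold = 3)
  })
  prom <- extractPromoters(runs)
  expect_true(all(c("attribute", "cw_run1", "cw_run2", "cw_run3") %in%
                  names(prom)))
  cw <- as.matrix(prom[, -1])
  expect_true(all(cw > 0))
  # every attribute positive in all runs is present, none missed
  w <- vapply(runs, function(r) {
    wt <- cwWeights(r$model)
    wt[setdiff(names(wt), blockedKeys(r$model))]
  }, numeric(length(cwWeights(runs[[1]]$model)) -
             length(blockedKeys(runs[[1]]$model))))
  all_pos <- rownames(w)[rowSums(w > 0) == 3]
  expect_setequal(prom$attribute, all_pos)

  # mismatched configurations are not comparable
  other <- mcOptimize(ds, epochs = 3, seed = 8, threshold = 3)
  expect_cwqsar_error(extractPromoters(list(runs[[1]], other)),
                      "comparability_error")
  expect_cwqsar_error(extractPromoters(runs[1]), "invalid_input")
})

test_that("a true positive-effect token shows up as a promoter", {
  # aromatic carbon carries the largest positive generating weight
  ds <- small_split_dataset(n = 120, noiseSd = 0, seed = 71)
  runs <- lapply(c(11, 12, 13), function(s) {
    mcOptimize(ds, epochs = 12, seed = s, threshold = 5)
  })
  prom <- extractPromoters(runs)
  expect_true("S:c" %in% prom$attribute)
})
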