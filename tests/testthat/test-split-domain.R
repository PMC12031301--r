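test_that("random splits are seeded, contiguous-cut and size-correct", {
  s8 <- randomSplit(8, seed = 1)
  expect_equal(as.vector(table(s8)), rep(2L, 4))

  expect_identical(randomSplit(100, seed = 5), randomSplit(100, seed = 5))

  s394 <- randomSplit(394, seed = 2)
  # cumulative-rounding cut rule at equal quarters
  expect_equal(sort(as.vector(table(s394))), c(98, 98, 99, 99))
  expect_equal(sum(table(s394)), 394L)

  expect_cwqsar_error(randomSplit(5, seed = 1), "split_error")
  expect_cwqsar_error(randomSplit(100, fractions = c(0.5, 0.5, 0, 0),
                                  seed = 1), "split_error")
})

test_that("attribute defects follow the three-term probability contrast", {
  # equal probabilities across subsets -> zero defect
  expect_equal(attributeDefect(5, 5, 5, 10, 10, 10), 0)
  # attribute only in A -> strictly positive
  expect_gt(attributeDefect(5, 0, 0, 10, 10, 10), 0)
  expect_cwqsar_error(attributeDefect(0, 0, 0, 10, 10, 10),
                      "undefined_defect")

  # seeded random occurrence tables against direct arithmetic
  set.seed(31)
  for (i in 1:20) {
    nA <- sample(5:20, 1); nP <- sample(5:20, 1); nC <- sample(5:20, 1)
    cA <- sample(0:nA, 1); cP <- sample(0:nP, 1); cC <- sample(0:nC, 1)
    if (cA + cP + cC == 0) cA <- 1
    pA <- cA / nA; pP <- cP / nP; pC <- cC / nC
    oracle <- (if (cA + cP > 0) abs(pA - pP) / (cA + cP) else 0) +
      (if (cA + cC > 0) abs(pA - pC) / (cA + cC) else 0) +
      (if (cP + cC > 0) abs(pP - pC) / (cP + cC) else 0)
    expect_equal(attributeDefect(cA, cP, cC, nA, nP, nC), oracle,
                 tolerance = 1e-12)
  }
})

test_that("per-molecule defects sum non-blocked attribute defects", {
  d <- c("S:C" = 0.2, "S:N" = 0.1, "S:O" = 0)
  expect_equal(smilesDefect(bag_of(character()), d), 0)
  expect_equal(smilesDefect(bag_of("S:C"), d), 0.2)
  counts <- matrix(1L, 3, 3, dimnames = list(names(d), c("A", "P", "C")))
  wt <- new("WeightTable",
            weights = structure(rep(0, 3), names = names(d)),
            blocked = "S:N", counts = counts, threshold = 1L)
  expect_equal(smilesDefect(bag_of(c("S:C", "S:N")), d, wt), 0.2)
})

test_that("domain rule is Dj < 2*meanD with all-zero degenerate case", {
  expect_true(inDomain(0.5, 0.5))
  expect_false(inDomain(1.25, 0.5))
  expect_true(all(inDomain(c(0, 0, 0), 0)))
})

test_that("identically generated subsets give near-zero defects", {
  ds <- syntheticDataset(n = 160, seed = 77, noiseSd = 0.3)
  lab <- randomSplit(length(ds), seed = 11)
  bags <- extractAttributes(smilesStrings(ds))
  dt <- defectTable(bags, lab, threshold = 1L)
  # shared attributes have small defects; in-domain fraction is high
  expect_gte(mean(dt$inDomain), 0.9)
  # an attribute present in all three subsets with similar prevalence has a
  # lower defect than one confined to A
  onlyA <- names(which(rowSums(
    cwqsar:::build_weight_table(bags, lab, 1L)@counts[, c("P", "C")]) == 0))
  if (length(onlyA)) {
    expect_gt(min(dt$d[onlyA], na.rm = TRUE), 0)
  }
})

test_that("partition census counts subset incidence disjointly", {
  bags <- list(bag_of(c("S:C", "S:N")), bag_of(c("S:C", "S:O")),
               bag_of(c("S:C", "S:N")), bag_of("S:C"))
  lab <- factor(c("A", "P", "C", "A"), levels = c("A", "P", "C", "V"))
  cen <- partitionCensus(bags, lab, threshold = 1L)
  # S:C in A,P,C; S:N in A and C; S:O in P only (not counted in NAll)
  expect_equal(cen$N111, 1L)
  expect_equal(cen$N101, 1L)
  expect_equal(cen$N110, 0L)
  expect_equal(cen$N100, 0L)
  expect_equal(cen$NAll, 2L)
  expect_equal(cen$Wpct, 100L)
  expect_lte(cen$N111 + cen$N110 + cen$N101 + cen$N100, cen$NAll)
})

test_that("balanced subsets keep all actives plus matched inactives", {
  out <- balancedSubset(paste0("a", 1:5), paste0("i", 1:20), seed = 4)
  expect_length(out, 10L)
  expect_true(all(paste0("a", 1:5) %in% out))
  expect_identical(out, balancedSubset(paste0("a", 1:5),
                                       paste0("i", 1:20), seed = 4))
  eq <- balancedSubset(paste0("a", 1:3), paste0("i", 1:3), seed = 1)
  expect_length(eq, 6L)
  expect_cwqsar_error(balancedSubset(1:5, 1:3), "invalid_input")
})

test_that("Las Vegas trace is well-formed and returns the argmax split", {
  ds <- small_split_dataset(n = 80, noiseSd = 0.3, seed = 15)
  lv <- lasVegas(ds, nTests = 4, probeEpochs = 2, seed = 9)
  expect_equal(nrow(lv$trace), 4L)
  expect_true(all(diff(lv$trace$bestR2C) >= 0))
  expect_equal(lv$bestTest, which.max(lv$trace$R2C))
  expect_equal(lv$trace$bestR2C[4], max(lv$trace$R2C))
  # the returned split reproduces the winning probe's assignment
  expect_equal(as.vector(table(lv$split)), rep(20L, 4))
})
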