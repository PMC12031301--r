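test_that("incremental LOO influence matches the brute-force oracle", {
  set.seed(101)
  for (i in 1:40) {
    n <- sample(4:50, 1)
    x <- rnorm(n)
    y <- 0.7 * x + rnorm(n, sd = 0.5)
    d <- looInfluence(x, y)
    expect_lt(max(abs(d - brute_loo(x, y))), 1e-10)
    d2 <- looInfluence(x, y, statistic = "r2")
    expect_lt(max(abs(d2 - brute_loo(x, y, "r2"))), 1e-10)
  }
})

test_that("influence signs identify opponents and supporters", {
  # collinear data: every deletion leaves r = 1
  x <- c(1, 2, 3, 4)
  d <- looInfluence(x, 2 + 3 * x)
  expect_equal(d, rep(0, 4))

  # one gross outlier off a perfect line: removing it raises r
  x <- c(1:9, 10)
  y <- x; y[10] <- -20
  d <- looInfluence(x, y)
  expect_gt(d[10], 0)

  expect_cwqsar_error(looInfluence(1:3, c(2, 4, 6)), "invalid_input")
  expect_cwqsar_error(looInfluence(rep(1, 5), rnorm(5)), "degenerate_data")
})

test_that("CII and CCCP aggregate the influence vector correctly", {
  expect_equal(cii(c(-0.1, -0.05, 0)), 1.0)
  expect_equal(cii(c(0.1, -0.2, 0.05)), 0.85)
  expect_equal(cccp(c(-0.3, -0.2, 0)), 1.0)
  # opponent mass equal to supporter mass
  expect_equal(cccp(c(0.25, -0.25, 0)), 0.0)
  expect_equal(cccp(c(0.25, -0.25), form = "ratio"), 1.0)
  expect_cwqsar_error(cccp(c(0.1, 0.2, 0)), "undefined_cccp")

  # permutation invariance and oracle agreement on random series
  set.seed(7)
  for (i in 1:10) {
    x <- rnorm(12); y <- x + rnorm(12, sd = 0.4)
    d <- looInfluence(x, y)
    bf <- brute_loo(x, y)
    expect_equal(cii(d), 1 - sum(bf[bf > 0]), tolerance = 1e-10)
    expect_equal(cccp(d), 1 - sum(bf[bf > 0]) / sum(-bf[bf < 0]),
                 tolerance = 1e-10)
    p <- sample(12)
    expect_equal(cii(d[p]), cii(d))
    expect_equal(cccp(d[p]), cccp(d))
  }
})

test_that("IIC penalizes residual asymmetry", {
  # residuals {-2,-2,+1,+1}: MAE ratio 1/2, IIC = r/2
  x <- c(1, 2, 3, 4, 5, 6)
  y <- x + c(-2, -2, 1, 1, 1, -1)
  r <- cor(x, y)
  res <- x - y
  mn <- mean(abs(res[res < 0])); mp <- mean(res[res >= 0])
  expect_equal(iic(x, y), r * min(mn, mp) / max(mn, mp))

  # exact fit: equal-MAE rule gives IIC = r = 1
  expect_equal(iic(x, x), 1.0)
  # one-sided residuals are undefined
  expect_cwqsar_error(iic(x, x - 1), "undefined_iic")

  set.seed(9)
  for (i in 1:10) {
    a <- rnorm(15); b <- a + rnorm(15, sd = 0.5)
    res <- a - b
    if (!any(res < 0) || all(res < 0)) next
    mn <- mean(abs(res[res < 0])); mp <- mean(res[res >= 0])
    expect_equal(iic(a, b), cor(a, b) * min(mn, mp) / max(mn, mp),
                 tolerance = 1e-12)
  }
})

test_that("regression statistics match their closed forms", {
  # identity prediction
  x <- c(4.1, 5.3, 6.2, 7.9, 5.5)
  st <- regressionStats(x, x)
  expect_equal(st$r2, 1.0)
  expect_equal(st$ccc, 1.0)
  expect_equal(st$rmse, 0.0)
  expect_equal(st$mae, 0.0)
  expect_equal(st$q2, 1.0)
  expect_equal(st$iic, 1.0)
  expect_equal(st$cii, 1.0)
  expect_true(is.infinite(st$f))
  expect_true(is.na(st$cccp))  # no supporters on an exact line

  # constant shift: R2 stays 1, CCC drops
  st2 <- regressionStats(x, x + 1)
  expect_equal(st2$r2, 1.0)
  expect_lt(st2$ccc, 1.0)

  # seeded random data against formula-by-formula oracle
  set.seed(21)
  o <- rnorm(20, mean = 5)
  p <- o + rnorm(20, sd = 0.6)
  st3 <- regressionStats(o, p)
  n <- 20
  expect_equal(st3$r2, cor(o, p)^2, tolerance = 1e-12)
  mo <- mean(o); mp_ <- mean(p)
  ccc_oracle <- 2 * sum((o - mo) * (p - mp_)) / n /
    (sum((o - mo)^2) / n + sum((p - mp_)^2) / n + (mo - mp_)^2)
  expect_equal(st3$ccc, ccc_oracle, tolerance = 1e-12)
  expect_equal(st3$rmse, sqrt(mean((o - p)^2)), tolerance = 1e-12)
  expect_equal(st3$mae, mean(abs(o - p)), tolerance = 1e-12)
  expect_equal(st3$f, st3$r2 * (n - 2) / (1 - st3$r2), tolerance = 1e-12)
  # explicit leave-one-out PRESS oracle for Q2
  press <- sum(vapply(seq_len(n), function(k) {
    fit <- lm(o[-k] ~ p[-k])
    (o[k] - (coef(fit)[1] + coef(fit)[2] * p[k]))^2
  }, numeric(1)))
  expect_equal(st3$q2, 1 - press / sum((o - mean(o))^2), tolerance = 1e-10)
  d <- brute_loo(o, p)
  expect_equal(st3$cii, 1 - sum(d[d > 0]), tolerance = 1e-10)
  expect_equal(st3$cccp, 1 - sum(d[d > 0]) / sum(-d[d < 0]),
               tolerance = 1e-10)
})

test_that("classification statistics follow confusion-matrix definitions", {
  a <- c(1, 1, 1, 0, 0, 0)
  st <- classificationStats(a, a)
  expect_equal(st$sensitivity, 1.0)
  expect_equal(st$specificity, 1.0)
  expect_equal(st$accuracy, 1.0)
  expect_equal(st$mcc, 1.0)

  st2 <- classificationStats(a, rep(1, 6))
  expect_equal(st2$sensitivity, 1.0)
  expect_equal(st2$specificity, 0.0)
  expect_equal(st2$accuracy, 0.5)
  expect_equal(st2$mcc, 0.0)
  expect_true(attr(st2, "mcc_degenerate"))

  set.seed(3)
  act <- rbinom(50, 1, 0.5)
  if (length(unique(act)) == 1) act[1] <- 1 - act[1]
  prd <- ifelse(runif(50) < 0.8, act, 1 - act)
  st3 <- classificationStats(act, prd)
  tp <- sum(act & prd); tn <- sum(!act & !prd)
  fp <- sum(!act & prd); fn <- sum(act & !prd)
  expect_equal(st3$sensitivity, tp / (tp + fn))
  expect_equal(st3$specificity, tn / (tn + fp))
  expect_equal(st3$accuracy, (tp + tn) / 50)
  expect_equal(st3$mcc, (tp * tn - fp * fn) /
    sqrt((tp + fp)) / sqrt((tp + fn)) / sqrt((tn + fp)) / sqrt((tn + fn)))

  expect_cwqsar_error(classificationStats(rep(1, 5), rep(1, 5)),
                      "invalid_input")
})
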