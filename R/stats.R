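#' Leave-one-out influence of each observation on the correlation
#'
#' For a paired series (observed, predicted), computes for every observation
#' `k` the change in the Pearson correlation when that observation is
#' deleted: `delta[k] = r(without k) - r(all)`. Observations with positive
#' `delta` are *opponents* of the correlation (removing them improves it);
#' observations with negative `delta` are *supporters*. This influence
#' vector is the shared kernel behind the correlation intensity index
#' ([cii()]) and the coefficient of conformism of a correlative prediction
#' ([cccp()]).
#'
#' The deletion correlations are obtained from an O(n) downdate of the five
#' sufficient sums, not by refitting n times; the brute-force recomputation
#' is used as the oracle in the test suite.
#'
#' @param observed,predicted numeric vectors of equal length `n >= 4`.
#' @param statistic influence on Pearson `"r"` (default) or on its square
#'   `"r2"`.
#' @return Numeric vector `delta` of length `n`.
#' @examples
#' set.seed(1)
#' x <- rnorm(10); y <- x + rnorm(10, sd = 0.3)
#' d <- looInfluence(x, y)
#' sum(d > 0)  # number of opponents
#' @export
looInfluence <- function(observed, predicted, statistic = c("r", "r2")) {
  statistic <- match.arg(statistic)
  x <- as.numeric(observed); y <- as.numeric(predicted)
  n <- length(x)
  if (length(y) != n) stop_typed("invalid_input", "unequal series lengths")
  if (n < 4L) stop_typed("invalid_input",
                         "need n >= 4 so every deletion leaves >= 3 points")
  Sx <- sum(x); Sy <- sum(y)
  Sxx <- sum(x * x); Syy <- sum(y * y); Sxy <- sum(x * y)
  dx_all <- n * Sxx - Sx^2
  dy_all <- n * Syy - Sy^2
  eps <- .Machine$double.eps
  if (dx_all <= eps * n * (Sxx + 1) || dy_all <= eps * n * (Syy + 1)) {
    stop_typed("degenerate_data", "zero variance in the full series")
  }
  r_all <- (n * Sxy - Sx * Sy) / sqrt(dx_all * dy_all)
  m <- n - 1L
  sx <- Sx - x; sy <- Sy - y
  sxx <- Sxx - x * x; syy <- Syy - y * y; sxy <- Sxy - x * y
  dx <- m * sxx - sx^2
  dy <- m * syy - sy^2
  bad <- (dx <= eps * m * (sxx + 1)) | (dy <= eps * m * (syy + 1))
  if (any(bad)) {
    stop_typed("degenerate_data",
               "zero variance after deleting observation %d", which(bad)[1L])
  }
  r_minus <- (m * sxy - sx * sy) / sqrt(dx * dy)
  if (statistic == "r2") r_minus^2 - r_all^2 else r_minus - r_all
}

#' Correlation intensity index (CII)
#'
#' Aggregates the opponents of a correlation: `CII = 1 - sum of positive
#' leave-one-out deltas`. It equals 1 when no observation opposes the
#' correlation and decreases as opponent influence accumulates, so larger
#' is better.
#'
#' @param delta influence vector from [looInfluence()].
#' @return A number in `(-Inf, 1]`.
#' @export
cii <- function(delta) {
  1 - sum(delta[delta > 0])
}

#' Coefficient of conformism of a correlative prediction (CCCP)
#'
#' Contrasts the total influence of the opponents of a correlation with the
#' total influence of its supporters. In the default `"conformism"` form,
#' `CCCP = 1 - (sum of opponent deltas) / (sum of |supporter deltas|)`:
#' it equals 1 when there are no opponents, 0 when opponent and supporter
#' mass balance, and is negative when opponents dominate. The literal
#' opponent/supporter `"ratio"` is available as an alternative form.
#'
#' @param delta influence vector from [looInfluence()].
#' @param form `"conformism"` (default) or `"ratio"`.
#' @return A number; `<= 1` in the conformism form.
#' @export
cccp <- function(delta, form = c("conformism", "ratio")) {
  form <- match.arg(form)
  opp <- sum(delta[delta > 0])
  sup <- sum(-delta[delta < 0])
  if (sup <= 0) {
    stop_typed("undefined_cccp",
               "CCCP undefined: the series has no supporters of correlation")
  }
  if (form == "ratio") opp / sup else 1 - opp / sup
}

#' Index of ideality of correlation (IIC)
#'
#' Splits the observations by the sign of the residual
#' `observed - predicted` and penalizes the Pearson correlation by the
#' asymmetry of the two mean absolute errors:
#' `IIC = r * min(MAE-, MAE+) / max(MAE-, MAE+)`, where `MAE-` is taken over
#' negative residuals and `MAE+` over non-negative ones. When all residuals
#' are exactly zero the two MAEs agree trivially and `IIC = r`.
#'
#' @param observed,predicted numeric vectors of equal length.
#' @return A number with `|IIC| <= |r|`.
#' @export
iic <- function(observed, predicted) {
  x <- as.numeric(observed); y <- as.numeric(predicted)
  if (length(x) != length(y)) stop_typed("invalid_input", "unequal lengths")
  r <- stats::cor(x, y)
  res <- x - y
  # a numerically zero residual vector is an exact fit: both MAEs vanish
  # and the equal-MAE rule gives IIC = r
  if (max(abs(res)) <= 1e-9 * max(1, stats::sd(x))) return(r)
  neg <- res < 0
  if (!any(neg) || all(neg)) {
    stop_typed("undefined_iic",
               "IIC undefined: residuals are one-sided")
  }
  mae_neg <- mean(abs(res[neg]))
  mae_pos <- mean(res[!neg])
  if (mae_neg == 0 && mae_pos == 0) return(r)
  r * min(mae_neg, mae_pos) / max(mae_neg, mae_pos)
}

# Lin's concordance correlation coefficient (population-moment form).
lin_ccc <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxy <- sum((x - mx) * (y - my)) / n
  sx2 <- sum((x - mx)^2) / n
  sy2 <- sum((y - my)^2) / n
  2 * sxy / (sx2 + sy2 + (mx - my)^2)
}

# Leave-one-out Q2 (1 - PRESS/SS_tot) for the univariate regression of
# observed on predicted, via the hat-value shortcut.
loo_q2 <- function(observed, predicted) {
  x <- predicted; y <- observed
  n <- length(y)
  mx <- mean(x)
  sxx <- sum((x - mx)^2)
  if (sxx <= 0) stop_typed("degenerate_data", "constant predictions")
  b <- sum((x - mx) * (y - mean(y))) / sxx
  a <- mean(y) - b * mx
  e <- y - (a + b * x)
  h <- 1 / n + (x - mx)^2 / sxx
  press <- sum((e / (1 - h))^2)
  1 - press / sum((y - mean(y))^2)
}

#' All regression criteria for one paired series
#'
#' Computes every statistic reported for a regression model subset:
#' determination coefficient R2, Lin's concordance correlation coefficient
#' (CCC), [iic()], [cii()], leave-one-out Q2, [cccp()], RMSE, MAE and the
#' Fisher statistic `F = R2 (n - 2) / (1 - R2)`.
#'
#' CCCP is reported as `NA` when the series has no supporters of
#' correlation (e.g. an exact line, where every deletion leaves r = 1);
#' IIC is `NA` when the residuals are one-sided. A perfect fit reports
#' `F = Inf`.
#'
#' @param observed,predicted numeric vectors, `n >= 4`.
#' @return A list of class `regressionStats` with fields `n, r2, ccc, iic,
#'   cii, q2, cccp, rmse, mae, f`.
#' @examples
#' set.seed(7)
#' x <- rnorm(20); y <- x + rnorm(20, sd = 0.2)
#' unlist(regressionStats(x, y))
#' @export
regressionStats <- function(observed, predicted) {
  x <- as.numeric(observed); y <- as.numeric(predicted)
  n <- length(x)
  if (length(y) != n) stop_typed("invalid_input", "unequal series lengths")
  if (n < 4L) stop_typed("invalid_input", "need n >= 4")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_typed("degenerate_data", "zero variance series")
  }
  r <- stats::cor(x, y)
  r2 <- r^2
  delta <- looInfluence(x, y)
  cccp_val <- tryCatch(cccp(delta), cwqsar_error = function(e) NA_real_)
  iic_val <- tryCatch(iic(x, y), cwqsar_error = function(e) NA_real_)
  f <- if (1 - r2 <= .Machine$double.eps) Inf else r2 * (n - 2) / (1 - r2)
  structure(list(
    n = n,
    r2 = r2,
    ccc = lin_ccc(x, y),
    iic = iic_val,
    cii = cii(delta),
    q2 = loo_q2(x, y),
    cccp = cccp_val,
    rmse = sqrt(mean((x - y)^2)),
    mae = mean(abs(x - y)),
    f = f
  ), class = "regressionStats")
}

#' Confusion-matrix criteria for a binary classifier
#'
#' Sensitivity, specificity, accuracy and the Matthews correlation
#' coefficient from 0/1 actual and predicted labels. When the MCC
#' denominator is zero (a degenerate margin), MCC is reported as 0 with
#' attribute `mcc_degenerate = TRUE`.
#'
#' @param actual,predicted 0/1 vectors of equal length; `actual` must
#'   contain both classes.
#' @return A list of class `classificationStats` with fields `n,
#'   sensitivity, specificity, accuracy, mcc`.
#' @export
classificationStats <- function(actual, predicted) {
  a <- as.integer(actual); p <- as.integer(predicted)
  if (length(a) != length(p)) stop_typed("invalid_input", "unequal lengths")
  if (!all(a %in% c(0L, 1L)) || !all(p %in% c(0L, 1L))) {
    stop_typed("invalid_input", "labels must be 0/1")
  }
  if (length(unique(a)) < 2L) {
    stop_typed("invalid_input", "actual labels contain a single class")
  }
  tp <- sum(a == 1L & p == 1L); tn <- sum(a == 0L & p == 0L)
  fp <- sum(a == 0L & p == 1L); fn <- sum(a == 1L & p == 0L)
  den <- sqrt(as.double(tp + fp)) * sqrt(as.double(tp + fn)) *
    sqrt(as.double(tn + fp)) * sqrt(as.double(tn + fn))
  degenerate <- den == 0
  mcc <- if (degenerate) 0 else
    (as.double(tp) * tn - as.double(fp) * fn) / den
  out <- structure(list(
    n = length(a),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    accuracy = (tp + tn) / length(a),
    mcc = mcc
  ), class = "classificationStats")
  attr(out, "mcc_degenerate") <- degenerate
  out
}

#' Per-subset statistics table for a fitted model
#'
#' Applies the model to each non-empty subset of the structured split
#' (`A`, `P`, `C`, `V`) and tabulates the criteria, one row per subset, in
#' the column layout of the standard report (regression: `R2 CCC IIC CII Q2
#' CCCP RMSE MAE F`; classification: `Sensitivity Specificity Accuracy
#' MCC`).
#'
#' @param dataset a [SmilesSet-class] with split labels assigned.
#' @param model a fitted [CwModel-class].
#' @param config the [attrConfig()] used for training (defaults to the one
#'   stored in the model).
#' @return A data.frame, one row per subset.
#' @export
subsetStats <- function(dataset, model, config = NULL) {
  if (is.null(config)) config <- model_attr_config(model)
  bags <- extractAttributes(smilesStrings(dataset), config)
  pred <- vapply(bags, function(b) {
    model@c0 + model@c1 * dcw(b, model@weightTable)
  }, numeric(1L))
  y <- endpoints(dataset)
  lab <- splitLabels(dataset)
  rows <- lapply(c("A", "P", "C", "V"), function(s) {
    idx <- which(lab == s)
    if (!length(idx)) return(NULL)
    if (model@task == "regression") {
      st <- regressionStats(y[idx], pred[idx])
      data.frame(set = s, n = st$n, R2 = st$r2, CCC = st$ccc, IIC = st$iic,
                 CII = st$cii, Q2 = st$q2, CCCP = st$cccp, RMSE = st$rmse,
                 MAE = st$mae, F = st$f)
    } else {
      cl <- as.integer(pred[idx] >= 0.5)
      st <- classificationStats(y[idx], cl)
      data.frame(set = s, n = st$n, Sensitivity = st$sensitivity,
                 Specificity = st$specificity, Accuracy = st$accuracy,
                 MCC = st$mcc)
    }
  })
  do.call(rbind, rows)
}

#' @describeIn subsetStats write the table as UTF-8 TSV.
#' @param stats data.frame from `subsetStats`.
#' @param path output file.
#' @export
writeStatsReport <- function(stats, path) {
  utils::write.table(stats, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
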