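#' Random structured split into A/P/C/V subsets
#'
#' Draws a seeded random permutation of the records and cuts it into four
#' contiguous blocks: active training (`A`), passive training (`P`),
#' calibration (`C`) and validation (`V`). Block sizes come from rounding
#' the cumulative fractions, so the sizes differ by at most one from the
#' exact proportions.
#'
#' @param ids character vector of record identifiers, or a single integer
#'   `n` (identifiers `1..n`).
#' @param fractions four non-negative fractions for `A, P, C, V`, summing
#'   to 1 (default equal quarters).
#' @param seed integer RNG seed.
#' @return Factor of labels `A/P/C/V` aligned with (and named by) the ids.
#' @examples
#' table(randomSplit(394, seed = 1))
#' @export
randomSplit <- function(ids, fractions = c(0.25, 0.25, 0.25, 0.25),
                        seed = 1L) {
  if (length(ids) == 1L && is.numeric(ids)) ids <- as.character(seq_len(ids))
  n <- length(ids)
  if (n < 8L) stop_typed("split_error", "need at least 8 records to split")
  if (length(fractions) != 4L || any(fractions < 0) ||
      abs(sum(fractions) - 1) > 1e-9) {
    stop_typed("split_error", "fractions must be four values summing to 1")
  }
  bounds <- round(cumsum(fractions) * n)
  bounds[4L] <- n
  sizes <- diff(c(0, bounds))
  if (any(sizes < 1)) stop_typed("split_error", "a subset would be empty")
  perm <- with_seed(seed, sample.int(n))
  lab <- character(n)
  lab[perm] <- rep(c("A", "P", "C", "V"), times = sizes)
  structure(factor(lab, levels = c("A", "P", "C", "V")), names = ids)
}

#' Statistical defect of one SMILES attribute
#'
#' Measures how unevenly an attribute is represented across the active
#' training, passive training and calibration sets:
#' \deqn{d_k = \frac{|P - P'|}{N + N'} + \frac{|P - P''|}{N + N''} +
#'       \frac{|P' - P''|}{N' + N''}}
#' where `P, P', P''` are the fractions of molecules containing the
#' attribute in `A`, `P`, `C` and `N, N', N''` the corresponding molecule
#' counts. A term with both counts zero contributes nothing. The defect is
#' zero when the three probabilities agree.
#'
#' @param countA,countP,countC number of molecules containing the attribute
#'   in each subset.
#' @param sizeA,sizeP,sizeC subset sizes.
#' @return The non-negative defect `d_k`.
#' @export
attributeDefect <- function(countA, countP, countC, sizeA, sizeP, sizeC) {
  if (countA + countP + countC == 0) {
    stop_typed("undefined_defect",
               "attribute absent from all of A, P and C")
  }
  pA <- countA / sizeA; pP <- countP / sizeP; pC <- countC / sizeC
  term <- function(p1, p2, n1, n2) {
    if (n1 + n2 == 0) 0 else abs(p1 - p2) / (n1 + n2)
  }
  term(pA, pP, countA, countP) + term(pA, pC, countA, countC) +
    term(pP, pC, countP, countC)
}

#' Statistical defects of a split and per-molecule domain membership
#'
#' Computes the attribute defects `d_k` for every attribute seen in the
#' structured training set, the per-molecule defect `D_j` (sum of `d_k`
#' over the molecule's distinct non-blocked attributes), and the mean
#' defect over the `A`, `P` and `C` molecules that anchors the
#' applicability domain.
#'
#' @param bags list of attribute bags, one per molecule (e.g. from
#'   [extractAttributes()]).
#' @param split factor of `A/P/C/V` labels aligned with `bags`.
#' @param threshold blocking threshold used to exclude rare attributes from
#'   `D_j` (an attribute is blocked when fewer than `threshold` active
#'   training molecules contain it).
#' @return A list of class `defectTable`: `d` (named attribute defects),
#'   `D` (per-molecule defects), `meanD` (mean `D_j` over `A`, `P`, `C`),
#'   `inDomain` (logical per molecule, `D_j < 2 * meanD`; all `TRUE` when
#'   every defect is zero).
#' @export
defectTable <- function(bags, split, threshold = 1L) {
  wt <- build_weight_table(bags, split, threshold)
  cnt <- wt@counts
  sizeA <- sum(split == "A", na.rm = TRUE)
  sizeP <- sum(split == "P", na.rm = TRUE)
  sizeC <- sum(split == "C", na.rm = TRUE)
  if (sizeA == 0 || sizeP == 0 || sizeC == 0) {
    stop_typed("split_error", "A, P and C must be non-empty")
  }
  seen <- rowSums(cnt) > 0
  d <- structure(rep(NA_real_, nrow(cnt)), names = rownames(cnt))
  for (k in which(seen)) {
    d[k] <- attributeDefect(cnt[k, "A"], cnt[k, "P"], cnt[k, "C"],
                            sizeA, sizeP, sizeC)
  }
  D <- vapply(bags, smilesDefect, numeric(1L), defects = d, table = wt)
  train <- which(split %in% c("A", "P", "C"))
  meanD <- mean(D[train])
  in_dom <- if (meanD == 0) rep(TRUE, length(D)) else D < 2 * meanD
  structure(list(d = d, D = D, meanD = meanD, inDomain = in_dom,
                 threshold = as.integer(threshold)),
            class = "defectTable")
}

#' Per-molecule statistical defect
#'
#' Sums the attribute defects of a molecule's distinct non-blocked
#' attributes. Attributes with no defined defect (absent from the
#' structured training set) contribute nothing; with the default blocking
#' threshold such attributes are blocked anyway.
#'
#' @param bag an `attrBag`.
#' @param defects named numeric vector of attribute defects `d_k`.
#' @param table optional [WeightTable-class] supplying the blocked set.
#' @return The non-negative defect `D_j`.
#' @export
smilesDefect <- function(bag, defects, table = NULL) {
  keys <- names(bag)
  if (!length(keys)) return(0)
  if (!is.null(table) && length(table@blocked)) {
    keys <- setdiff(keys, table@blocked)
  }
  vals <- defects[keys]
  sum(vals[!is.na(vals)])
}

#' Applicability-domain test
#'
#' A molecule falls inside the applicability domain when its statistical
#' defect is less than twice the mean defect of the structured training
#' set: `D_j < 2 * meanD`. When every defect is zero (identically
#' distributed subsets) the strict inequality would exclude everything, so
#' that degenerate case is defined as all-in-domain.
#'
#' @param Dj per-molecule defect(s).
#' @param meanD mean defect of the A/P/C molecules.
#' @return Logical vector.
#' @export
inDomain <- function(Dj, meanD) {
  if (meanD == 0) rep(TRUE, length(Dj)) else Dj < 2 * meanD
}

#' Attribute-partition census of a split
#'
#' Counts how the distinct attributes of the active training set distribute
#' over the three structured subsets: `N111` present in `A`, `P` and `C`;
#' `N110` in `A` and `P` only; `N101` in `A` and `C` only; `N100` in `A`
#' only; `NAll` distinct attributes in `A`; and `W%`, the rounded
#' percentage of those attributes that are non-blocked (take part in the
#' optimization).
#'
#' @param bags list of attribute bags.
#' @param split factor of `A/P/C/V` labels.
#' @param threshold blocking threshold.
#' @return Named list `Wpct, N111, N110, N101, N100, NAll`.
#' @export
partitionCensus <- function(bags, split, threshold = 1L) {
  wt <- build_weight_table(bags, split, threshold)
  cnt <- wt@counts
  inA <- cnt[, "A"] > 0; inP <- cnt[, "P"] > 0; inC <- cnt[, "C"] > 0
  nAll <- sum(inA)
  nonblocked <- sum(cnt[, "A"] >= threshold)
  list(
    Wpct = if (nAll == 0) 0 else as.integer(round(100 * nonblocked / nAll)),
    N111 = sum(inA & inP & inC),
    N110 = sum(inA & inP & !inC),
    N101 = sum(inA & !inP & inC),
    N100 = sum(inA & !inP & !inC),
    NAll = nAll
  )
}

#' Las Vegas search for a favourable split
#'
#' Repeatedly draws a random structured split, runs a short Monte Carlo
#' probe optimization on it, and keeps the split whose probe reaches the
#' largest calibration determination coefficient. Each probe contributes
#' one trace row with the attribute-partition census, the probe's CCCP on
#' the calibration set, the subset determination coefficients, and the
#' running best. A probe that fails (degenerate split or optimization
#' error) is recorded with `R2C = 0` and does not abort the search.
#'
#' @param dataset a [SmilesSet-class]; existing split labels are ignored.
#' @param nTests number of splits to probe (`>= 1`).
#' @param probeEpochs epochs per probe (short by design).
#' @param target a [targetConfig()].
#' @param fractions split fractions passed to [randomSplit()].
#' @param threshold blocking threshold.
#' @param seed master seed; per-test seeds are derived from it.
#' @param attr an [attrConfig()].
#' @return A list with `split` (labels of the winning split), `bestTest`
#'   (its trace row index), and `trace` (data.frame with columns `test,
#'   Wpct, N111, N110, N101, N100, NAll, CCCP, R2A, R2P, R2C, bestR2C,
#'   bestTest`).
#' @export
lasVegas <- function(dataset, nTests = 10L, probeEpochs = 5L,
                     target = targetConfig(),
                     fractions = c(0.25, 0.25, 0.25, 0.25),
                     threshold = 1L, seed = 1L, attr = attrConfig()) {
  if (nTests < 1L) stop_typed("invalid_input", "nTests must be >= 1")
  y <- endpoints(dataset)
  bags <- extractAttributes(smilesStrings(dataset), attr)
  rows <- vector("list", nTests)
  best_r2c <- -Inf
  best_test <- NA_integer_
  best_split <- NULL
  for (i in seq_len(nTests)) {
    lab <- randomSplit(compoundIds(dataset), fractions,
                       seed = derive_seed(seed, i))
    probe <- tryCatch({
      ds <- dataset
      splitLabels(ds) <- lab
      run <- mcOptimize(ds, target = target, epochs = probeEpochs,
                        threshold = threshold,
                        seed = derive_seed(seed, i + 10000L), attr = attr)
      pred <- predict(run$model, ds)
      r2 <- function(s) {
        idx <- which(lab == s)
        suppressWarnings(stats::cor(y[idx], pred[idx]))^2
      }
      iC <- which(lab == "C")
      cc <- tryCatch(cccp(looInfluence(y[iC], pred[iC])),
                     cwqsar_error = function(e) NA_real_)
      list(r2a = r2("A"), r2p = r2("P"), r2c = r2("C"), cccp = cc)
    }, cwqsar_error = function(e) NULL, error = function(e) NULL)
    if (is.null(probe)) {
      probe <- list(r2a = NA_real_, r2p = NA_real_, r2c = 0,
                    cccp = NA_real_)
    }
    if (is.na(probe$r2c)) probe$r2c <- 0
    census <- partitionCensus(bags, lab, threshold)
    if (probe$r2c > best_r2c) {
      best_r2c <- probe$r2c
      best_test <- i
      best_split <- lab
    }
    rows[[i]] <- data.frame(
      test = i, Wpct = census$Wpct, N111 = census$N111, N110 = census$N110,
      N101 = census$N101, N100 = census$N100, NAll = census$NAll,
      CCCP = probe$cccp, R2A = probe$r2a, R2P = probe$r2p, R2C = probe$r2c,
      bestR2C = best_r2c, bestTest = best_test)
  }
  list(split = best_split, bestTest = best_test,
       trace = do.call(rbind, rows))
}

#' Class-balanced subset for classification modelling
#'
#' Keeps every active compound and a seeded random sample of inactives of
#' equal size.
#'
#' @param actives,inactives identifier vectors; `length(inactives) >=
#'   length(actives)`.
#' @param seed integer RNG seed.
#' @return Character vector of retained identifiers (actives first).
#' @export
balancedSubset <- function(actives, inactives, seed = 1L) {
  if (length(inactives) < length(actives)) {
    stop_typed("invalid_input", "fewer inactives than actives")
  }
  keep <- if (length(inactives) == length(actives)) inactives else
    with_seed(seed, sample(inactives, length(actives)))
  c(as.character(actives), as.character(keep))
}
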