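#' Descriptor of correlation weights (DCW)
#'
#' The optimal descriptor of a molecule is the sum, over its attribute
#' multiset, of multiplicity times correlation weight. Blocked attributes
#' (too rare in the active training set) and attributes unknown to the
#' weight table contribute exactly zero.
#'
#' @param bag an `attrBag` from [extractAttributes()].
#' @param table a [WeightTable-class].
#' @return A single number; 0 for an empty bag.
#' @export
dcw <- function(bag, table) {
  if (length(bag) == 0L) return(0)
  keys <- names(bag)
  w <- unname(table@weights[keys])
  w[is.na(w)] <- 0
  if (length(table@blocked)) w[keys %in% table@blocked] <- 0
  sum(as.numeric(bag) * w)
}

# Occurrence counts (molecules containing each key) per structured subset,
# and the blocking rule: active iff count in A >= threshold.
build_weight_table <- function(bags, split, threshold = 1L,
                               weights = NULL) {
  stopifnot(length(bags) == length(split))
  keys_by_mol <- lapply(bags, names)
  all_keys <- sort(unique(unlist(keys_by_mol)), method = "radix")
  counts <- matrix(0L, nrow = length(all_keys), ncol = 3L,
                   dimnames = list(all_keys, c("A", "P", "C")))
  for (s in c("A", "P", "C")) {
    ks <- unlist(keys_by_mol[which(split == s)])
    if (length(ks)) {
      tab <- table(factor(unlist(lapply(keys_by_mol[which(split == s)],
                                        unique)), levels = all_keys))
      counts[, s] <- as.integer(tab)
    }
  }
  blocked <- all_keys[counts[, "A"] < threshold]
  if (is.null(weights)) {
    weights <- structure(rep(0, length(all_keys)), names = all_keys)
  }
  new("WeightTable", weights = weights, blocked = blocked,
      counts = counts, threshold = as.integer(threshold))
}

#' Fit the one-descriptor regression
#'
#' Ordinary least squares for `endpoint = C0 + C1 * DCW`, the univariate
#' model applied to the descriptor values of the fit set.
#'
#' @param dcwValues numeric descriptor values (non-constant).
#' @param endpoints numeric endpoint values, same length, `n >= 3`.
#' @return Named numeric `c(c0, c1)`.
#' @export
fitRegression <- function(dcwValues, endpoints) {
  d <- as.numeric(dcwValues); y <- as.numeric(endpoints)
  n <- length(d)
  if (length(y) != n || n < 3L) {
    stop_typed("invalid_input", "need equal-length vectors with n >= 3")
  }
  md <- mean(d)
  sdd <- sum((d - md)^2)
  if (sdd <= .Machine$double.eps * n * (sum(d * d) + 1)) {
    stop_typed("degenerate_descriptor",
               "descriptor has zero variance (over-blocked weight table?)")
  }
  c1 <- sum((d - md) * (y - mean(y))) / sdd
  c0 <- mean(y) - c1 * md
  c(c0 = c0, c1 = c1)
}

model_attr_config <- function(model) {
  ac <- model@config$attr
  if (is.null(ac)) return(attrConfig())
  do.call(attrConfig, ac)
}

#' Predict endpoints with a fitted correlation-weight model
#'
#' Applies `C0 + C1 * DCW` to new data.
#'
#' @param object a fitted [CwModel-class].
#' @param newdata a [SmilesSet-class], a character vector of SMILES, a list
#'   of attribute bags, or a single `attrBag`.
#' @param ... ignored.
#' @return Numeric vector of predicted endpoint values.
#' @export
setMethod("predict", "CwModel", function(object, newdata, ...) {
  if (!isTRUE(object@fitted)) {
    stop_typed("model_state", "model has not been fitted")
  }
  bags <- as_bag_list(newdata, model_attr_config(object))
  d <- vapply(bags, dcw, numeric(1L), table = object@weightTable)
  unname(object@c0 + object@c1 * d)
})

as_bag_list <- function(newdata, config) {
  if (is(newdata, "SmilesSet")) {
    extractAttributes(smilesStrings(newdata), config)
  } else if (inherits(newdata, "attrBag")) {
    list(newdata)
  } else if (is.character(newdata)) {
    lapply(newdata, extractAttributes, config = config)
  } else if (is.list(newdata)) {
    newdata
  } else {
    stop_typed("invalid_input", "unsupported newdata type")
  }
}

#' @rdname classify
#' @export
setGeneric("classify", function(object, newdata, ...) {
  standardGeneric("classify")
})

#' Semi-correlation binary classification
#'
#' The semi-correlation scheme regresses the 0/1 endpoint on the descriptor
#' and thresholds the regression value: a molecule is classified active (1)
#' iff `y = C0 + C1 * DCW >= 0.5`, with the boundary inclusive.
#'
#' @param object a fitted classification-task [CwModel-class].
#' @param newdata as in [predict()][predict,CwModel-method].
#' @param ... ignored.
#' @return Integer vector of 0/1 labels.
#' @export
setMethod("classify", "CwModel", function(object, newdata, ...) {
  if (object@task != "classification") {
    stop_typed("task_mismatch",
               "classify() requires a classification-task model")
  }
  as.integer(predict(object, newdata) >= 0.5)
})

#' Write / read a model as JSON
#'
#' Serializes a [CwModel-class] (weights, blocked set, counts, regression
#' coefficients, task, configuration and seed) as a JSON file with stable
#' key ordering, at full double precision so that a round trip reproduces
#' predictions bit-identically.
#'
#' @param model a [CwModel-class].
#' @param path file path.
#' @return `writeModel` returns `path` invisibly; `readModel` returns the
#'   reconstructed [CwModel-class].
#' @export
writeModel <- function(model, path) {
  wt <- model@weightTable
  keys <- sort(names(wt@weights), method = "radix")
  payload <- list(
    format = "cwqsar-model",
    version = 1L,
    task = model@task,
    c0 = model@c0,
    c1 = model@c1,
    seed = model@seed,
    fitted = model@fitted,
    threshold = wt@threshold,
    config = model@config,
    blocked = sort(wt@blocked, method = "radix"),
    weights = as.list(wt@weights[keys]),
    counts = list(keys = keys,
                  A = unname(wt@counts[keys, "A"]),
                  P = unname(wt@counts[keys, "P"]),
                  C = unname(wt@counts[keys, "C"]))
  )
  # 17 significant digits: doubles survive the round trip bit-identically
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname writeModel
#' @export
readModel <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(p$format, "cwqsar-model")) {
    stop_typed("parse_error", "not a cwqsar model file: %s", path)
  }
  keys <- p$counts$keys
  counts <- cbind(A = as.integer(p$counts$A), P = as.integer(p$counts$P),
                  C = as.integer(p$counts$C))
  rownames(counts) <- keys
  weights <- unlist(p$weights)
  if (is.null(weights)) weights <- structure(numeric(), names = character())
  wt <- new("WeightTable", weights = weights[keys],
            blocked = as.character(p$blocked),
            counts = counts, threshold = as.integer(p$threshold))
  cfg <- p$config
  if (!is.null(cfg$attr)) cfg$attr <- lapply(cfg$attr, unlist)
  new("CwModel", weightTable = wt, c0 = as.numeric(p$c0),
      c1 = as.numeric(p$c1), task = p$task, config = cfg,
      seed = as.integer(p$seed), fitted = isTRUE(p$fitted))
}
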