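#' @import methods
NULL

#' SmilesSet: a set of compounds with SMILES and endpoint values
#'
#' Container for a QSAR dataset: one record per compound with an identifier,
#' a raw SMILES string, an endpoint value (continuous for regression, 0/1 for
#' classification) and an optional structured-split label. The split labels
#' follow the four-way scheme used throughout the package: active training
#' (`A`), passive training (`P`), calibration (`C`) and validation (`V`).
#'
#' @slot ids character vector of unique compound identifiers.
#' @slot smiles character vector of raw SMILES strings.
#' @slot endpoint numeric endpoint vector; all 0/1 when `task` is
#'   `"classification"`.
#' @slot split factor with levels `A`, `P`, `C`, `V` (may contain `NA` when
#'   no split has been assigned yet).
#' @slot task `"regression"` or `"classification"`.
#'
#' @seealso [SmilesSet()] for the constructor, [randomSplit()] to assign
#'   split labels, [mcOptimize()] to train a model.
#' @exportClass SmilesSet
setClass("SmilesSet",
  representation(
    ids = "character",
    smiles = "character",
    endpoint = "numeric",
    split = "factor",
    task = "character"
  )
)

setValidity("SmilesSet", function(object) {
  msg <- character()
  n <- length(object@ids)
  if (length(object@smiles) != n || length(object@endpoint) != n ||
      length(object@split) != n) {
    msg <- c(msg, "ids, smiles, endpoint and split must have equal length")
  }
  if (anyDuplicated(object@ids)) {
    msg <- c(msg, "compound identifiers must be unique")
  }
  if (!identical(levels(object@split), c("A", "P", "C", "V"))) {
    msg <- c(msg, "split levels must be exactly A, P, C, V")
  }
  if (!(length(object@task) == 1L &&
        object@task %in% c("regression", "classification"))) {
    msg <- c(msg, "task must be 'regression' or 'classification'")
  }
  if (length(object@task) == 1L && object@task == "classification" &&
      n > 0L && !all(object@endpoint %in% c(0, 1) | is.na(object@endpoint))) {
    msg <- c(msg, "classification endpoints must be 0 or 1")
  }
  if (length(msg)) msg else TRUE
})

#' WeightTable: correlation weights for SMILES attributes
#'
#' Maps every attribute key seen in the training data to a correlation
#' weight (CW). Attributes whose occurrence count in the active training set
#' falls below the blocking threshold `T` are *blocked*: they carry weight
#' zero in every descriptor sum and are excluded from optimization.
#'
#' @slot weights named numeric vector, attribute key -> CW.
#' @slot blocked character vector of blocked attribute keys.
#' @slot counts integer matrix (attribute keys x subsets `A`, `P`, `C`) of
#'   the number of molecules in each subset containing the attribute.
#' @slot threshold integer blocking threshold `T` (minimum active-training
#'   occurrence count for an attribute to stay active).
#'
#' @exportClass WeightTable
setClass("WeightTable",
  representation(
    weights = "numeric",
    blocked = "character",
    counts = "matrix",
    threshold = "integer"
  )
)

setValidity("WeightTable", function(object) {
  msg <- character()
  if (length(object@weights) && is.null(names(object@weights))) {
    msg <- c(msg, "weights must be named by attribute key")
  }
  if (!all(object@blocked %in% names(object@weights))) {
    msg <- c(msg, "blocked keys must be a subset of the weight keys")
  }
  if (length(object@weights) &&
      !identical(sort(rownames(object@counts)), sort(names(object@weights)))) {
    msg <- c(msg, "counts rows must match weight keys")
  }
  if (!identical(colnames(object@counts), c("A", "P", "C"))) {
    msg <- c(msg, "counts columns must be A, P, C")
  }
  if (length(msg)) msg else TRUE
})

#' CwModel: a trained correlation-weight QSAR model
#'
#' Serializable model state: the weight table together with the regression
#' coefficients of the one-descriptor model `endpoint = C0 + C1 * DCW`, the
#' task type, the configuration used for attribute extraction and
#' optimization, and the RNG seed, so that a run is fully replayable.
#'
#' @slot weightTable a [WeightTable-class].
#' @slot c0,c1 regression coefficients (intercept and slope).
#' @slot task `"regression"` or `"classification"`.
#' @slot config list snapshot of the attribute and optimizer configuration.
#' @slot seed integer RNG seed used for the optimization run.
#' @slot fitted logical; `FALSE` for a bare initialized state.
#'
#' @exportClass CwModel
setClass("CwModel",
  representation(
    weightTable = "WeightTable",
    c0 = "numeric",
    c1 = "numeric",
    task = "character",
    config = "list",
    seed = "integer",
    fitted = "logical"
  )
)

setValidity("CwModel", function(object) {
  msg <- character()
  if (!(object@task %in% c("regression", "classification"))) {
    msg <- c(msg, "task must be 'regression' or 'classification'")
  }
  if (isTRUE(object@fitted) && length(object@c1) == 1L &&
      !is.na(object@c1) && object@c1 == 0) {
    msg <- c(msg, "a fitted model requires c1 != 0")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a SmilesSet
#'
#' @param ids character identifiers (unique). Defaults to `M1..Mn`.
#' @param smiles character SMILES strings.
#' @param endpoint numeric endpoint values (0/1 for classification).
#' @param split optional character/factor of split labels in `A,P,C,V`;
#'   `NA` entries mean "not yet assigned".
#' @param task `"regression"` (default) or `"classification"`.
#' @return A [SmilesSet-class] object.
#' @examples
#' ss <- SmilesSet(smiles = c("CCO", "c1ccccc1", "ClCCl"),
#'                 endpoint = c(5.1, 6.2, 4.3))
#' length(ss)
#' @export
SmilesSet <- function(smiles, endpoint, ids = NULL, split = NULL,
                      task = c("regression", "classification")) {
  task <- match.arg(task)
  n <- length(smiles)
  if (is.null(ids)) ids <- paste0("M", seq_len(n))
  if (is.null(split)) split <- rep(NA_character_, n)
  new("SmilesSet",
      ids = as.character(ids),
      smiles = as.character(smiles),
      endpoint = as.numeric(endpoint),
      split = factor(as.character(split), levels = c("A", "P", "C", "V")),
      task = task)
}

setMethod("show", "SmilesSet", function(object) {
  cat("SmilesSet with", length(object@ids), "compounds (",
      object@task, ")\n", sep = " ")
  tab <- table(object@split, useNA = "ifany")
  cat("  split:", paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  if (length(object@ids)) {
    k <- min(3L, length(object@ids))
    cat("  head:", paste(object@smiles[seq_len(k)], collapse = "  "), "\n")
  }
})

setMethod("length", "SmilesSet", function(x) length(x@ids))

setMethod("[", "SmilesSet", function(x, i, j, ..., drop = TRUE) {
  new("SmilesSet", ids = x@ids[i], smiles = x@smiles[i],
      endpoint = x@endpoint[i], split = x@split[i], task = x@task)
})

setMethod("show", "WeightTable", function(object) {
  cat("WeightTable:", length(object@weights), "attributes,",
      length(object@blocked), "blocked (T =", object@threshold, ")\n")
})

setMethod("show", "CwModel", function(object) {
  cat("CwModel (", object@task, ")",
      if (object@fitted) "" else " [unfitted]", "\n", sep = "")
  if (object@fitted) {
    cat(sprintf("  endpoint = %.4g + %.4g * DCW\n", object@c0, object@c1))
  }
  cat("  attributes:", length(object@weightTable@weights),
      "(", length(object@weightTable@blocked), "blocked )\n")
})
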