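#' @rdname SmilesSet-accessors
#' @export
setGeneric("compoundIds", function(x) standardGeneric("compoundIds"))

#' @rdname SmilesSet-accessors
#' @export
setGeneric("smilesStrings", function(x) standardGeneric("smilesStrings"))

#' @rdname SmilesSet-accessors
#' @export
setGeneric("endpoints", function(x) standardGeneric("endpoints"))

#' @rdname SmilesSet-accessors
#' @export
setGeneric("splitLabels", function(x) standardGeneric("splitLabels"))

#' @rdname SmilesSet-accessors
#' @export
setGeneric("splitLabels<-", function(x, value) standardGeneric("splitLabels<-"))

#' @rdname SmilesSet-accessors
#' @export
setGeneric("taskType", function(x) standardGeneric("taskType"))

#' Accessors for SmilesSet objects
#'
#' `compoundIds`, `smilesStrings`, `endpoints`, `splitLabels` and `taskType`
#' read the corresponding record columns; `splitLabels<-` assigns a split
#' (a character/factor over `A, P, C, V`).
#'
#' @param x a [SmilesSet-class].
#' @param value replacement split labels.
#' @return The requested component, or the modified object for the setter.
#' @name SmilesSet-accessors
#' @aliases compoundIds smilesStrings endpoints splitLabels splitLabels<- taskType
NULL

setMethod("compoundIds", "SmilesSet", function(x) x@ids)
setMethod("smilesStrings", "SmilesSet", function(x) x@smiles)
setMethod("endpoints", "SmilesSet", function(x) x@endpoint)
setMethod("splitLabels", "SmilesSet", function(x) x@split)
setMethod("taskType", "SmilesSet", function(x) x@task)
setReplaceMethod("splitLabels", "SmilesSet", function(x, value) {
  x@split <- factor(as.character(value), levels = c("A", "P", "C", "V"))
  validObject(x)
  x
})

#' Accessors for WeightTable and CwModel objects
#'
#' @param x a [WeightTable-class] or [CwModel-class].
#' @return `cwWeights`: named numeric CW vector (blocked keys included, with
#'   their stored values; they contribute 0 to any descriptor). `blockedKeys`:
#'   character vector. `attributeCounts`: integer matrix keys x (A,P,C).
#'   `weightTable`: the model's [WeightTable-class].
#' @name WeightTable-accessors
#' @aliases cwWeights blockedKeys attributeCounts weightTable
NULL

#' @rdname WeightTable-accessors
#' @export
setGeneric("cwWeights", function(x) standardGeneric("cwWeights"))

#' @rdname WeightTable-accessors
#' @export
setGeneric("blockedKeys", function(x) standardGeneric("blockedKeys"))

#' @rdname WeightTable-accessors
#' @export
setGeneric("attributeCounts", function(x) standardGeneric("attributeCounts"))

#' @rdname WeightTable-accessors
#' @export
setGeneric("weightTable", function(x) standardGeneric("weightTable"))

setMethod("cwWeights", "WeightTable", function(x) x@weights)
setMethod("blockedKeys", "WeightTable", function(x) x@blocked)
setMethod("attributeCounts", "WeightTable", function(x) x@counts)
setMethod("cwWeights", "CwModel", function(x) x@weightTable@weights)
setMethod("blockedKeys", "CwModel", function(x) x@weightTable@blocked)
setMethod("weightTable", "CwModel", function(x) x@weightTable)

#' @describeIn WeightTable-accessors regression coefficients `c(c0, c1)`.
#' @param object a [CwModel-class].
#' @param ... ignored.
#' @export
setMethod("coef", "CwModel", function(object, ...) {
  c(c0 = object@c0, c1 = object@c1)
})
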