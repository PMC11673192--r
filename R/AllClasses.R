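#' @import methods
#' @importFrom stats median rnorm runif rexp sd setNames quantile wilcox.test cor
#' @importFrom utils read.delim write.table head
NULL

#' OmicsMatrix: one omics view
#'
#' A thin container for a single omics measurement layer: a numeric
#' samples-by-features matrix with unique sample and feature identifiers and
#' a label naming the omics (e.g. `"gene"` for gene expression RNA-seq,
#' `"mirna"` for miRNA-seq). Values may contain `NA` before imputation;
#' preprocessing removes them.
#'
#' @slot omicsName single character label for the omics layer.
#' @slot values numeric matrix, samples in rows (rownames = sample ids),
#'   features in columns (colnames = feature ids).
#'
#' @seealso [omicsMatrix()], [readExpressionMatrix()], [preprocessOmics()]
#' @export
setClass("OmicsMatrix",
  representation(omicsName = "character", values = "matrix"))

setValidity("OmicsMatrix", function(object) {
  msg <- character()
  if (length(object@omicsName) != 1L || is.na(object@omicsName) ||
      !nzchar(object@omicsName))
    msg <- c(msg, "'omicsName' must be a single non-empty string")
  v <- object@values
  if (!is.numeric(v))
    msg <- c(msg, "'values' must be a numeric matrix")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "'values' must have sample ids as rownames and feature ids as colnames")
  else {
    if (anyDuplicated(rownames(v)))
      msg <- c(msg, paste0("duplicated sample ids: ",
                           paste(unique(rownames(v)[duplicated(rownames(v))]), collapse = ", ")))
    if (anyDuplicated(colnames(v)))
      msg <- c(msg, paste0("duplicated feature ids: ",
                           paste(unique(colnames(v)[duplicated(colnames(v))]), collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OmicsMatrix
#'
#' @param values numeric matrix (samples x features) with dimnames, or a
#'   data.frame coercible to one.
#' @param omicsName label for the omics layer.
#' @return An [OmicsMatrix-class] object.
#' @examples
#' m <- matrix(rnorm(6), 3, 2, dimnames = list(paste0("s", 1:3), c("f1", "f2")))
#' omicsMatrix(m, "gene")
#' @export
omicsMatrix <- function(values, omicsName = "omics") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("OmicsMatrix", omicsName = omicsName, values = values)
}

#' MultiOmicsSurvData: aligned multi-omics views with survival outcomes
#'
#' Holds v omics views over an identical, identically ordered set of samples
#' together with right-censored survival outcomes: the observed time O
#' (min of the true survival time T and the censoring time C) and the event
#' indicator (1 = death observed, 0 = censored).
#'
#' @slot views named list of [OmicsMatrix-class] objects sharing the same
#'   sample order.
#' @slot time positive numeric vector of observed times, one per sample.
#' @slot event integer vector in \{0, 1\}, one per sample.
#'
#' @seealso [multiOmicsSurvData()], [alignSamples()]
#' @export
setClass("MultiOmicsSurvData",
  representation(views = "list", time = "numeric", event = "integer"))

setValidity("MultiOmicsSurvData", function(object) {
  msg <- character()
  if (length(object@views) < 1L)
    msg <- c(msg, "at least one omics view is required")
  if (is.null(names(object@views)) || anyDuplicated(names(object@views)))
    msg <- c(msg, "views must be uniquely named")
  if (!all(vapply(object@views, is, logical(1), "OmicsMatrix")))
    msg <- c(msg, "all views must be OmicsMatrix objects")
  else {
    ids <- lapply(object@views, function(v) rownames(v@values))
    if (!all(vapply(ids, identical, logical(1), ids[[1]])))
      msg <- c(msg, "all views must share an identical sample id order")
    n <- length(ids[[1]])
    if (length(object@time) != n || length(object@event) != n)
      msg <- c(msg, "survival outcomes must match the number of samples")
  }
  if (length(object@time) && any(!is.finite(object@time) | object@time <= 0))
    msg <- c(msg, "observed times must be positive and finite")
  if (length(object@event) && !all(object@event %in% c(0L, 1L)))
    msg <- c(msg, "event indicators must be 0 or 1")
  if (length(msg)) msg else TRUE
})

#' Construct a MultiOmicsSurvData object
#'
#' @param views named list of [OmicsMatrix-class] objects (or plain matrices),
#'   all with identical sample id order.
#' @param time positive observed times (days), one per sample.
#' @param event event indicators (1 = death observed, 0 = censored).
#' @return A [MultiOmicsSurvData-class] object.
#' @export
multiOmicsSurvData <- function(views, time, event) {
  if (is.null(names(views)))
    names(views) <- paste0("view", seq_along(views))
  views <- lapply(names(views), function(nm) {
    v <- views[[nm]]
    if (is(v, "OmicsMatrix")) v else omicsMatrix(v, nm)
  })
  names(views) <- vapply(views, function(v) v@omicsName, character(1))
  new("MultiOmicsSurvData", views = views, time = as.numeric(time),
      event = as.integer(event))
}

# ---- generics -------------------------------------------------------------

#' @rdname OmicsMatrix-class
#' @param x,object an object.
#' @export
setGeneric("omicsName", function(x) standardGeneric("omicsName"))

#' @rdname OmicsMatrix-class
#' @export
setGeneric("omicsValues", function(x) standardGeneric("omicsValues"))

#' @rdname OmicsMatrix-class
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))

#' @rdname OmicsMatrix-class
#' @export
setGeneric("featureIds", function(x) standardGeneric("featureIds"))

#' @rdname OmicsMatrix-class
#' @export
setGeneric("nSamples", function(x) standardGeneric("nSamples"))

#' @rdname MultiOmicsSurvData-class
#' @export
setGeneric("omicsViews", function(x) standardGeneric("omicsViews"))

#' @rdname MultiOmicsSurvData-class
#' @export
setGeneric("survTime", function(x) standardGeneric("survTime"))

#' @rdname MultiOmicsSurvData-class
#' @export
setGeneric("survEvent", function(x) standardGeneric("survEvent"))

#' @rdname MultiOmicsSurvData-class
#' @export
setGeneric("viewNames", function(x) standardGeneric("viewNames"))

# ---- OmicsMatrix methods --------------------------------------------------

#' @rdname OmicsMatrix-class
#' @export
setMethod("omicsName", "OmicsMatrix", function(x) x@omicsName)

#' @rdname OmicsMatrix-class
#' @export
setMethod("omicsValues", "OmicsMatrix", function(x) x@values)

#' @rdname OmicsMatrix-class
#' @export
setMethod("sampleIds", "OmicsMatrix", function(x) rownames(x@values))

#' @rdname OmicsMatrix-class
#' @export
setMethod("featureIds", "OmicsMatrix", function(x) colnames(x@values))

#' @rdname OmicsMatrix-class
#' @export
setMethod("nSamples", "OmicsMatrix", function(x) nrow(x@values))

#' @rdname OmicsMatrix-class
#' @param i,j,...,drop subsetting indices (samples, features).
#' @export
setMethod("[", "OmicsMatrix", function(x, i, j, ..., drop = FALSE) {
  v <- x@values
  if (!missing(i)) v <- v[i, , drop = FALSE]
  if (!missing(j)) v <- v[, j, drop = FALSE]
  omicsMatrix(v, x@omicsName)
})

setMethod("show", "OmicsMatrix", function(object) {
  cat("OmicsMatrix '", object@omicsName, "': ",
      nrow(object@values), " samples x ", ncol(object@values), " features",
      sep = "")
  nNA <- sum(is.na(object@values))
  if (nNA) cat(" (", nNA, " missing entries)", sep = "")
  cat("\n")
})

# ---- MultiOmicsSurvData methods -------------------------------------------

#' @rdname MultiOmicsSurvData-class
#' @export
setMethod("omicsViews", "MultiOmicsSurvData", function(x)
  lapply(x@views, omicsValues))

#' @rdname MultiOmicsSurvData-class
#' @export
setMethod("viewNames", "MultiOmicsSurvData", function(x) names(x@views))

#' @rdname MultiOmicsSurvData-class
#' @export
setMethod("survTime", "MultiOmicsSurvData", function(x) x@time)

#' @rdname MultiOmicsSurvData-class
#' @export
setMethod("survEvent", "MultiOmicsSurvData", function(x) x@event)

#' @rdname MultiOmicsSurvData-class
#' @export
setMethod("sampleIds", "MultiOmicsSurvData", function(x)
  rownames(x@views[[1]]@values))

#' @rdname MultiOmicsSurvData-class
#' @export
setMethod("nSamples", "MultiOmicsSurvData", function(x)
  nrow(x@views[[1]]@values))

#' @rdname MultiOmicsSurvData-class
#' @param i sample indices (integer, logical or sample ids).
#' @param j unused.
#' @export
setMethod("[", "MultiOmicsSurvData", function(x, i, j, ..., drop = FALSE) {
  if (is.character(i)) i <- match(i, sampleIds(x))
  views <- lapply(x@views, function(v) v[i, ])
  new("MultiOmicsSurvData", views = views, time = x@time[i],
      event = x@event[i])
})

setMethod("show", "MultiOmicsSurvData", function(object) {
  cat("MultiOmicsSurvData: ", nSamples(object), " samples, ",
      length(object@views), " views\n", sep = "")
  for (v in object@views)
    cat("  - ", v@omicsName, ": ", ncol(v@values), " features\n", sep = "")
  cat("  events: ", sum(object@event), " observed, ",
      sum(object@event == 0L), " censored\n", sep = "")
})

#' Restrict a multi-omics dataset to a subset of views
#'
#' @param x a [MultiOmicsSurvData-class] object.
#' @param keep character vector of view names to retain.
#' @return A [MultiOmicsSurvData-class] with only the requested views.
#' @export
subsetViews <- function(x, keep) {
  missing <- setdiff(keep, viewNames(x))
  if (length(missing))
    stop("unknown view(s): ", paste(missing, collapse = ", "))
  new("MultiOmicsSurvData", views = x@views[keep], time = x@time,
      event = x@event)
}

#' Concatenate multi-omics datasets sample-wise
#'
#' Used to form a union meta-training pool from several cohorts measured on
#' the same features.
#'
#' @param datasets list of [MultiOmicsSurvData-class] objects with identical
#'   views and feature sets.
#' @return A single [MultiOmicsSurvData-class].
#' @export
bindSamples <- function(datasets) {
  stopifnot(length(datasets) >= 1L)
  if (length(datasets) == 1L) return(datasets[[1]])
  vn <- viewNames(datasets[[1]])
  for (d in datasets[-1])
    if (!identical(viewNames(d), vn))
      stop("all datasets must have the same views to be pooled")
  views <- lapply(vn, function(nm) {
    mats <- lapply(datasets, function(d) omicsValues(d@views[[nm]]))
    feats <- colnames(mats[[1]])
    for (m in mats[-1])
      if (!identical(colnames(m), feats))
        stop("feature sets differ across datasets for view '", nm, "'")
    omicsMatrix(do.call(rbind, mats), nm)
  })
  names(views) <- vn
  new("MultiOmicsSurvData", views = views,
      time = unlist(lapply(datasets, survTime), use.names = FALSE),
      event = as.integer(unlist(lapply(datasets, survEvent), use.names = FALSE)))
}
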