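#' Drop features with too many missing values
#'
#' Retains exactly the features whose missing fraction is less than or equal
#' to `maxNAFraction` ("exceeding" the threshold is read strictly, so a
#' feature missing in exactly 10% of samples survives the default filter).
#'
#' @param x an [OmicsMatrix-class].
#' @param maxNAFraction maximum tolerated missing fraction, in `[0, 1)`.
#' @return An [OmicsMatrix-class] with the surviving features, order
#'   preserved.
#' @export
filterMissingFeatures <- function(x, maxNAFraction = 0.10) {
  stopifnot(maxNAFraction >= 0, maxNAFraction < 1)
  v <- omicsValues(x)
  frac <- colMeans(is.na(v))
  keep <- frac <= maxNAFraction
  if (!any(keep))
    stop("all features of view '", omicsName(x),
         "' exceed the missing-value threshold ", maxNAFraction)
  omicsMatrix(v[, keep, drop = FALSE], omicsName(x))
}

#' Impute missing entries with the per-feature median
#'
#' Each missing entry is replaced by the median of the observed values of
#' its feature.
#'
#' @param x an [OmicsMatrix-class]; every feature must have at least one
#'   observed value.
#' @return An [OmicsMatrix-class] with no missing entries.
#' @export
imputeMedian <- function(x) {
  v <- omicsValues(x)
  allNA <- colSums(!is.na(v)) == 0L
  if (any(allNA))
    stop("feature(s) fully missing (should have been filtered): ",
         paste(colnames(v)[allNA], collapse = ", "))
  nas <- is.na(v)
  if (any(nas)) {
    med <- apply(v, 2, median, na.rm = TRUE)
    idx <- which(nas, arr.ind = TRUE)
    v[idx] <- med[idx[, 2]]
  }
  omicsMatrix(v, omicsName(x))
}

#' Logarithm-transform expression values
#'
#' Replaces each value x by `log2(x + pseudocount)` (base and pseudocount
#' configurable). All values must be non-negative.
#'
#' @param x an [OmicsMatrix-class].
#' @param pseudocount added before taking the log; default 1 so zeros map
#'   to zero.
#' @param base logarithm base, default 2.
#' @return The transformed [OmicsMatrix-class].
#' @export
logTransform <- function(x, pseudocount = 1.0, base = 2) {
  v <- omicsValues(x)
  if (any(v < 0, na.rm = TRUE))
    stop("negative values cannot be log-transformed in view '",
         omicsName(x), "'")
  omicsMatrix(log(v + pseudocount, base = base), omicsName(x))
}

#' Remove near-constant features
#'
#' Drops features whose sample variance is below `minVariance` — features
#' whose values remain almost unchanged across samples carry no
#' discriminative signal and amplify normalization noise.
#'
#' @param x an imputed [OmicsMatrix-class] (no missing values).
#' @param minVariance variance threshold; features with variance strictly
#'   below it are removed. Default `1e-8`.
#' @return An [OmicsMatrix-class] with the surviving features.
#' @export
removeLowVariance <- function(x, minVariance = 1e-8) {
  v <- omicsValues(x)
  if (anyNA(v)) stop("impute missing values before variance filtering")
  vars <- apply(v, 2, stats::var)
  keep <- vars >= minVariance
  if (!any(keep))
    stop("all features of view '", omicsName(x),
         "' fall below the variance threshold ", minVariance)
  omicsMatrix(v[, keep, drop = FALSE], omicsName(x))
}

#' Per-feature standardization statistics
#'
#' Means and standard deviations used by [zscoreFeatures()]. Computing these
#' on the meta-training pool and reusing them on few-shot target data avoids
#' leaking 10-sample statistics into the normalization.
#'
#' @param x an [OmicsMatrix-class] (no missing values).
#' @param varianceType `"population"` (1/n, default) or `"sample"`
#'   (1/(n-1)).
#' @return list with numeric vectors `mean` and `sd` (named by feature).
#' @export
featureStats <- function(x, varianceType = c("population", "sample")) {
  varianceType <- match.arg(varianceType)
  v <- omicsValues(x)
  if (anyNA(v)) stop("impute missing values before standardization")
  mu <- colMeans(v)
  n <- nrow(v)
  ss <- colMeans(sweep(v, 2, mu)^2)
  if (varianceType == "sample") ss <- ss * n / max(n - 1, 1)
  list(mean = mu, sd = sqrt(ss))
}

#' Standardize features to zero mean and unit variance
#'
#' @param x an [OmicsMatrix-class] (no missing values).
#' @param stats optional precomputed [featureStats()] (e.g. from the
#'   meta-training pool); computed from `x` itself when `NULL`.
#' @param varianceType scaling convention when `stats` is computed here:
#'   `"population"` (1/n, default) or `"sample"` (1/(n-1)).
#' @return The standardized [OmicsMatrix-class].
#' @export
zscoreFeatures <- function(x, stats = NULL,
                           varianceType = c("population", "sample")) {
  varianceType <- match.arg(varianceType)
  if (is.null(stats)) stats <- featureStats(x, varianceType)
  v <- omicsValues(x)
  if (anyNA(v)) stop("impute missing values before standardization")
  sdv <- stats$sd[colnames(v)]
  mu <- stats$mean[colnames(v)]
  if (anyNA(sdv) || anyNA(mu))
    stop("standardization statistics missing for some features")
  zero <- sdv <= 0
  if (any(zero))
    stop("zero-variance feature(s): ",
         paste(colnames(v)[zero], collapse = ", "))
  omicsMatrix(sweep(sweep(v, 2, mu), 2, sdv, "/"), omicsName(x))
}

#' Align samples across omics views and survival outcomes
#'
#' Keeps the intersection of sample ids across all views and the outcome
#' table, in lexicographically sorted order, and reorders every view to
#' match — only patients with matched measurements in every omics layer are
#' retained.
#'
#' @param views list of [OmicsMatrix-class] objects.
#' @param outcomes data.frame as returned by [readSurvivalTable()].
#' @return A [MultiOmicsSurvData-class].
#' @export
alignSamples <- function(views, outcomes) {
  idSets <- c(lapply(views, sampleIds), list(outcomes$sample_id))
  common <- Reduce(intersect, idSets)
  if (length(common) == 0L)
    stop("no samples shared across all views and the survival table")
  common <- sort(common)
  views <- lapply(views, function(v) v[common, ])
  names(views) <- vapply(views, omicsName, character(1))
  idx <- match(common, outcomes$sample_id)
  multiOmicsSurvData(views, time = outcomes$time[idx],
                     event = outcomes$event[idx])
}

#' Full preprocessing pipeline for one omics view
#'
#' filter missing features -> median imputation -> log transform ->
#' low-variance filter -> z-score, with a per-stage report of dropped
#' features. The pipeline is deterministic: identical inputs give
#' bit-identical outputs.
#'
#' @param x an [OmicsMatrix-class].
#' @param maxNAFraction see [filterMissingFeatures()].
#' @param pseudocount,logBase see [logTransform()]; set
#'   `applyLog = FALSE` to skip (e.g. already-log data).
#' @param applyLog logical, apply the log transform stage.
#' @param minVariance see [removeLowVariance()].
#' @param zscoreStats optional pooled [featureStats()] to reuse.
#' @param varianceType standardization convention, see [zscoreFeatures()].
#' @return list with `matrix` (the preprocessed [OmicsMatrix-class]) and
#'   `report` (named list: features in/out per stage, dropped ids).
#' @export
preprocessOmics <- function(x, maxNAFraction = 0.10, pseudocount = 1.0,
                            logBase = 2, applyLog = TRUE,
                            minVariance = 1e-8, zscoreStats = NULL,
                            varianceType = c("population", "sample")) {
  varianceType <- match.arg(varianceType)
  report <- list(omics = omicsName(x), n_features_in = ncol(omicsValues(x)))
  x1 <- filterMissingFeatures(x, maxNAFraction)
  report$dropped_missing <- setdiff(featureIds(x), featureIds(x1))
  x2 <- imputeMedian(x1)
  x3 <- if (applyLog) logTransform(x2, pseudocount, logBase) else x2
  x4 <- removeLowVariance(x3, minVariance)
  report$dropped_low_variance <- setdiff(featureIds(x3), featureIds(x4))
  x5 <- zscoreFeatures(x4, stats = zscoreStats, varianceType = varianceType)
  report$n_features_out <- ncol(omicsValues(x5))
  list(matrix = x5, report = report)
}

#' Write a preprocessing report as JSON
#'
#' @param reports list of per-view reports from [preprocessOmics()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writePreprocessReport <- function(reports, path) {
  jsonlite::write_json(reports, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
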