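# Synthetic families of related multi-omics survival tasks with known
# ground truth: two omics views generated from shared latent patient
# factors, proportional-hazards survival times driven by those factors,
# right-censoring calibrated to a target proportion, and per-task
# perturbations of the risk coefficients so a family of "cancer types"
# shares transferable latent structure.

#' Synthetic multi-omics survival family configuration
#'
#' Each sample i has latent factors `u_i ~ N(0, I_r)`; view v is
#' `X_i^(v) = W_v u_i + noise` with loadings shared across the whole family;
#' the linear predictor is `eta_i = (w + task jitter) . u_i`; event times
#' are proportional-hazards Weibull (exponential by default,
#' `shape = 1`) with baseline rate `baselineRate`, and censoring times are
#' drawn from the same family with the rate calibrated so the expected
#' censored fraction matches `targetCensoring`.
#'
#' Defaults are sized for desk-scale experiments (r = 10 latent factors,
#' 500 + 100 features, 400 samples per task, 9 tasks) while keeping the
#' statistical structure of high-dimensional two-view omics cohorts with
#' censoring in the 0.14-0.86 range observed in real cohort collections.
#'
#' @param latentDim r, number of shared latent factors.
#' @param p1,p2 feature dimensions of the two views.
#' @param nPerTask samples per task.
#' @param nTasks number of tasks in the family (the last is the held-out
#'   target; the rest form the meta-training pool).
#' @param loadingScale magnitude of the loading matrices W1, W2 (entries
#'   `N(0, loadingScale^2 / r)`, giving per-feature signal variance
#'   `loadingScale^2`).
#' @param noiseSd per-feature Gaussian noise standard deviation.
#' @param riskCoef base risk coefficient vector w (length r), or `NULL` to
#'   draw it as `N(0, riskCoefScale^2 / r)` per coordinate (so
#'   `|w| ~ riskCoefScale` and the linear predictor has roughly unit
#'   variance at the default scale).
#' @param riskCoefScale scale used when drawing `riskCoef`.
#' @param taskPerturbationSd per-coordinate jitter of the per-task risk
#'   coefficients around w.
#' @param baselineRate baseline hazard rate lambda0.
#' @param targetCensoring target expected censored fraction, in (0, 1).
#' @param weibullShape Weibull shape of event and censoring times (1 =
#'   exponential).
#' @param viewLatentCoords optional list of two integer vectors selecting
#'   which latent coordinates each view loads on (loadings on the other
#'   coordinates are zero); `NULL` (default) loads both views on all
#'   coordinates. Disjoint coordinate sets make the views complementary.
#' @param viewNames names of the two views.
#' @param seed integer seed of the family.
#' @return A list of class `syntheticConfig`.
#' @export
syntheticConfig <- function(latentDim = 10L, p1 = 500L, p2 = 100L,
                            nPerTask = 400L, nTasks = 9L,
                            loadingScale = 1, noiseSd = 1,
                            riskCoef = NULL, riskCoefScale = 1,
                            taskPerturbationSd = 0.1,
                            baselineRate = 0.01, targetCensoring = 0.6,
                            weibullShape = 1, viewLatentCoords = NULL,
                            viewNames = c("gene", "mirna"), seed = 1L) {
  stopifnot(latentDim >= 1, p1 >= 1, p2 >= 1, nPerTask >= 2, nTasks >= 1,
            loadingScale > 0, noiseSd >= 0, baselineRate > 0,
            targetCensoring > 0, targetCensoring < 1, weibullShape > 0,
            length(viewNames) == 2)
  if (!is.null(riskCoef)) stopifnot(length(riskCoef) == latentDim)
  if (!is.null(viewLatentCoords)) {
    stopifnot(is.list(viewLatentCoords), length(viewLatentCoords) == 2,
              all(unlist(viewLatentCoords) %in% seq_len(latentDim)))
  }
  structure(list(latentDim = as.integer(latentDim), p1 = as.integer(p1),
                 p2 = as.integer(p2), nPerTask = as.integer(nPerTask),
                 nTasks = as.integer(nTasks), loadingScale = loadingScale,
                 noiseSd = noiseSd, riskCoef = riskCoef,
                 riskCoefScale = riskCoefScale,
                 taskPerturbationSd = taskPerturbationSd,
                 baselineRate = baselineRate,
                 targetCensoring = targetCensoring,
                 weibullShape = weibullShape,
                 viewLatentCoords = viewLatentCoords,
                 viewNames = viewNames, seed = as.integer(seed)),
            class = "syntheticConfig")
}

# family-level quantities (loadings, base risk coefficients), deterministic
# from the config seed
.familyLoadings <- function(config) {
  set.seed(fanSeed(config$seed, "family"))
  r <- config$latentDim
  mkW <- function(p, coords) {
    W <- matrix(rnorm(p * r, sd = config$loadingScale / sqrt(r)), r, p)
    if (!is.null(coords)) W[setdiff(seq_len(r), coords), ] <- 0
    W
  }
  W1 <- mkW(config$p1, config$viewLatentCoords[[1]])
  W2 <- mkW(config$p2, config$viewLatentCoords[[2]])
  w <- if (is.null(config$riskCoef))
    rnorm(r, sd = config$riskCoefScale / sqrt(r))
  else config$riskCoef
  list(W1 = W1, W2 = W2, w = w)
}

#' Calibrate the censoring rate to a target censored fraction
#'
#' Under proportional-hazards Weibull event times with rates
#' `lambda_i = lambda0 exp(eta_i)` and an independent same-shape Weibull
#' censoring time with rate c, the probability that sample i is censored is
#' `c / (c + lambda_i)`. The rate c is found by bisection on the mean
#' censoring probability over the sampled linear predictors.
#'
#' @param eta numeric vector of linear predictors.
#' @param baselineRate baseline hazard rate lambda0.
#' @param targetCensoring target expected censored fraction.
#' @return The calibrated censoring rate c.
#' @export
calibrateCensoringRate <- function(eta, baselineRate, targetCensoring) {
  lambda <- baselineRate * exp(eta)
  pCens <- function(logc) mean(exp(logc) / (exp(logc) + lambda)) -
    targetCensoring
  lo <- log(min(lambda)) - 40; hi <- log(max(lambda)) + 40
  if (pCens(lo) > 0 || pCens(hi) < 0)
    stop("censoring target ", targetCensoring, " unreachable")
  exp(stats::uniroot(pCens, c(lo, hi), tol = 1e-12)$root)
}

# draw proportional-hazards Weibull times: S(t) = exp(-rate * t^shape)
.rPHWeibull <- function(n, rate, shape) {
  (-log(runif(n)) / rate)^(1 / shape)
}

#' Generate one synthetic multi-omics survival task
#'
#' @param config a [syntheticConfig()].
#' @param taskIndex which task of the family (1-based); determines the
#'   task-specific RNG stream and risk-coefficient jitter.
#' @param loadings optional precomputed family loadings (internal reuse).
#' @return List of class `syntheticTask`: `dataset` (a
#'   [MultiOmicsSurvData-class]) and `truth` (data.frame with the latent
#'   factors `u.*`, the true linear predictor `eta`, the true event time
#'   `eventTime` and censoring time `censorTime` per sample; the observed
#'   time is their minimum and the event indicator is
#'   `eventTime <= censorTime`).
#' @export
generateSyntheticTask <- function(config, taskIndex = 1L, loadings = NULL) {
  if (is.null(loadings)) loadings <- .familyLoadings(config)
  set.seed(fanSeed(config$seed, "task", taskIndex))
  n <- config$nPerTask; r <- config$latentDim
  wTask <- loadings$w + rnorm(r, sd = config$taskPerturbationSd)
  U <- matrix(rnorm(n * r), n, r)
  X1 <- U %*% loadings$W1 +
    matrix(rnorm(n * config$p1, sd = config$noiseSd), n, config$p1)
  X2 <- U %*% loadings$W2 +
    matrix(rnorm(n * config$p2, sd = config$noiseSd), n, config$p2)
  eta <- drop(U %*% wTask)
  lambda <- config$baselineRate * exp(eta)
  eventTime <- .rPHWeibull(n, lambda, config$weibullShape)
  cRate <- calibrateCensoringRate(eta, config$baselineRate,
                                  config$targetCensoring)
  censorTime <- .rPHWeibull(n, cRate, config$weibullShape)
  obsTime <- pmin(eventTime, censorTime)
  event <- as.integer(eventTime <= censorTime)
  ids <- sprintf("t%02d_s%04d", taskIndex, seq_len(n))
  dimnames(X1) <- list(ids, sprintf("g%04d", seq_len(config$p1)))
  dimnames(X2) <- list(ids, sprintf("m%04d", seq_len(config$p2)))
  views <- list(omicsMatrix(X1, config$viewNames[1]),
                omicsMatrix(X2, config$viewNames[2]))
  names(views) <- config$viewNames
  truth <- data.frame(sample_id = ids, U, eta = eta,
                      eventTime = eventTime, censorTime = censorTime)
  colnames(truth)[1 + seq_len(r)] <- paste0("u", seq_len(r))
  structure(list(dataset = multiOmicsSurvData(views, obsTime, event),
                 truth = truth, taskIndex = taskIndex,
                 riskCoef = wTask, censorRate = cRate),
            class = "syntheticTask")
}

#' Generate a family of related tasks: meta-training pool plus target
#'
#' All tasks share the loading matrices and base risk coefficients of the
#' family; each task has independent samples and its own risk-coefficient
#' jitter. The target task never appears in the pool.
#'
#' @param config a [syntheticConfig()] with `nTasks >= 2`.
#' @return List with `pool` (list of `nTasks - 1` `syntheticTask`s),
#'   `target` (one `syntheticTask`) and `loadings` (the shared `W1`, `W2`,
#'   `w`).
#' @export
generateFamily <- function(config) {
  stopifnot(config$nTasks >= 2)
  loadings <- .familyLoadings(config)
  tasks <- lapply(seq_len(config$nTasks), generateSyntheticTask,
                  config = config, loadings = loadings)
  list(pool = tasks[-config$nTasks], target = tasks[[config$nTasks]],
       loadings = loadings)
}

#' Write a synthetic task to disk as plain-text files
#'
#' Standard TSV expression matrices (one per view), a survival table
#' (`sample_id`, `time`, `event`) and a ground-truth TSV (latent factors,
#' linear predictor, true event and censoring times) keyed by sample id.
#'
#' @param task a `syntheticTask` from [generateSyntheticTask()].
#' @param dir output directory (created if missing).
#' @param prefix file-name prefix, e.g. `"target"` or `"pool_1"`.
#' @return Character vector of the written file paths, invisibly.
#' @export
writeSyntheticTask <- function(task, dir, prefix) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  d <- task$dataset
  paths <- character()
  for (nm in viewNames(d)) {
    p <- file.path(dir, paste0(prefix, "_", nm, ".tsv"))
    writeExpressionMatrix(d@views[[nm]], p)
    paths <- c(paths, p)
  }
  sp <- file.path(dir, paste0(prefix, "_survival.tsv"))
  writeSurvivalTable(data.frame(sample_id = sampleIds(d),
                                time = survTime(d), event = survEvent(d)),
                     sp)
  tp <- file.path(dir, paste0(prefix, "_truth.tsv"))
  write.table(task$truth, tp, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(paths, sp, tp))
}
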