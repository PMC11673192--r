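# Survival-prediction metrics and the replicated few-shot benchmark
# protocol.

#' Harrell's concordance index
#'
#' A pair (i, j) is comparable iff `O_i < O_j` and subject i experienced
#' the event; it is concordant when the shorter-lived subject has the
#' higher risk score (`h_i > h_j`, credit 1), tied scores receive credit
#' 0.5. Returns concordant credit / comparable pairs: 0.5 is random, 1 is
#' perfect.
#'
#' @param scores risk scores (higher = higher predicted risk).
#' @param time observed times.
#' @param event event indicators in \{0, 1\}.
#' @return Concordance in `[0, 1]`.
#' @export
concordanceIndex <- function(scores, time, event) {
  n <- length(scores)
  stopifnot(length(time) == n, length(event) == n)
  comp <- outer(time, time, "<") & matrix(event == 1, n, n)
  nComp <- sum(comp)
  if (nComp == 0)
    stop("no comparable pairs (e.g. all subjects censored)")
  sg <- outer(scores, scores, ">")
  se <- outer(scores, scores, "==")
  (sum(sg & comp) + 0.5 * sum(se & comp)) / nComp
}

# Kaplan-Meier estimate of the censoring survival function G(t),
# evaluated with a left limit at jump points (G(t-)).
.censoringKM <- function(time, event) {
  fit <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  stats::stepfun(fit$time, c(1, fit$surv), right = TRUE)
}

#' IPCW time-dependent (cumulative/dynamic) AUC
#'
#' Discrimination between cases (event by the horizon) and controls
#' (observed beyond the horizon), with cases reweighted by the inverse
#' probability of remaining uncensored, estimated by a Kaplan-Meier fit to
#' the censoring distribution (Uno-style estimator). With no censoring this
#' reduces to the plain case/control pair rate.
#'
#' @param scores risk scores.
#' @param time observed times.
#' @param event event indicators in \{0, 1\}.
#' @param horizon evaluation time; defaults to the median observed time.
#' @return AUC at the horizon, in `[0, 1]`.
#' @export
timeDependentAUC <- function(scores, time, event, horizon = NULL) {
  n <- length(scores)
  stopifnot(length(time) == n, length(event) == n)
  if (is.null(horizon)) horizon <- median(time)
  cases <- which(time <= horizon & event == 1)
  controls <- which(time > horizon)
  if (length(cases) == 0) stop("no cases at the horizon ", horizon)
  if (length(controls) == 0) stop("no controls at the horizon ", horizon)
  G <- .censoringKM(time, event)
  w <- 1 / G(time[cases])
  if (any(!is.finite(w)))
    stop("degenerate censoring weights at the horizon ", horizon)
  conc <- outer(scores[cases], scores[controls], ">") +
          0.5 * outer(scores[cases], scores[controls], "==")
  sum(w * rowSums(conc)) / (sum(w) * length(controls))
}

# stratified (by censoring status) index split: returns list(train, test)
.stratifiedSplit <- function(event, testFraction) {
  idxE <- which(event == 1L); idxC <- which(event == 0L)
  nTestE <- .roundHalfUp(length(idxE) * testFraction)
  nTestC <- .roundHalfUp(length(idxC) * testFraction)
  testIdx <- c(if (length(idxE)) idxE[sample.int(length(idxE), nTestE)],
               if (length(idxC)) idxC[sample.int(length(idxC), nTestC)])
  list(train = sort(setdiff(seq_along(event), testIdx)),
       test = sort(testIdx))
}

# stratified few-shot draw of `shots` samples from `event`, proportional to
# the observed censoring composition, with at least one event
.stratifiedDraw <- function(event, shots) {
  idxE <- which(event == 1L); idxC <- which(event == 0L)
  nE <- .roundHalfUp(shots * length(idxE) / length(event))
  nE <- max(min(nE, length(idxE)), 1L)
  nC <- shots - nE
  if (nC > length(idxC))
    stop("not enough censored samples for a ", shots, "-shot draw")
  sort(c(idxE[sample.int(length(idxE), nE)],
         idxC[sample.int(length(idxC), nC)]))
}

#' Replicated few-shot benchmark
#'
#' For each target dataset: split train/test stratified by censoring
#' status, then for every repeat draw `shots` training samples (again
#' stratified) `nDraws` times; within a draw every scheme consumes the
#' identical few-shot training set and is scored on the fixed test split
#' (paired comparison). Pool-phase work (meta-training, pretraining) is
#' performed once per scheme per repeat and shared across draws.
#'
#' @param pool meta-training pool: a [MultiOmicsSurvData-class] or list of
#'   them, disjoint from the targets.
#' @param targets a [MultiOmicsSurvData-class] or (named) list of them.
#' @param schemes character vector of scheme names, see [schemeNames()].
#' @param modelConfig a [survModelConfig()].
#' @param metaConfig a [metaConfig()].
#' @param nDraws few-shot draws per repeat (the study protocol uses 50).
#' @param nRepeats protocol repetitions (the study protocol uses 20).
#' @param shots few-shot training-set size (10 or 20).
#' @param testFraction held-out test fraction of each target (0.2 common,
#'   0.5 for very small rare-cancer cohorts).
#' @param seed global seed; fans out to named per-component streams.
#' @param standardize standardize all views with meta-training-pool
#'   statistics before any training (default `TRUE`).
#' @return data.frame with one row per target x repeat x draw x scheme:
#'   `target`, `scheme`, `replicate`, `draw`, `c_index`, `auc`, `n_test`.
#' @export
runBenchmark <- function(pool, targets, schemes, modelConfig, metaConfig,
                         nDraws = 10L, nRepeats = 3L, shots = 10L,
                         testFraction = 0.2, seed = 1L,
                         standardize = TRUE) {
  if (is(targets, "MultiOmicsSurvData")) targets <- list(target = targets)
  if (is.null(names(targets)))
    names(targets) <- paste0("target", seq_along(targets))
  badSchemes <- setdiff(schemes, schemeNames())
  if (length(badSchemes))
    stop("unknown scheme(s): ", paste(badSchemes, collapse = ", "))
  poolData <- if (is(pool, "MultiOmicsSurvData")) pool else bindSamples(pool)
  if (standardize) {
    statsPerView <- lapply(poolData@views, featureStats)
    std <- function(d) {
      views <- lapply(viewNames(d), function(nm)
        zscoreFeatures(d@views[[nm]], stats = statsPerView[[nm]]))
      names(views) <- viewNames(d)
      multiOmicsSurvData(views, survTime(d), survEvent(d))
    }
    poolData <- std(poolData)
    targets <- lapply(targets, std)
  }
  rows <- list()
  for (tname in names(targets)) {
    target <- targets[[tname]]
    set.seed(fanSeed(seed, "split", tname))
    sp <- .stratifiedSplit(survEvent(target), testFraction)
    trainSet <- target[sp$train]
    testSet <- target[sp$test]
    for (rep in seq_len(nRepeats)) {
      poolPhases <- lapply(schemes, function(sc)
        schemePoolPhase(sc, poolData, modelConfig, metaConfig,
                        seed = fanSeed(seed, "pool", tname, rep, sc)))
      names(poolPhases) <- schemes
      for (draw in seq_len(nDraws)) {
        set.seed(fanSeed(seed, "draw", tname, rep, draw))
        drawIdx <- .stratifiedDraw(survEvent(trainSet), shots)
        fewShot <- trainSet[drawIdx]
        for (sc in schemes) {
          res <- runScheme(sc, poolData, fewShot, testSet, modelConfig,
                           metaConfig,
                           seed = fanSeed(seed, "fit", tname, rep, draw, sc),
                           poolPhase = poolPhases[[sc]])
          rows[[length(rows) + 1L]] <-
            data.frame(target = tname, scheme = sc, replicate = rep,
                       draw = draw, c_index = res$result$c_index,
                       auc = res$result$auc, n_test = res$result$n_test)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Summarize a benchmark run
#'
#' Per-scheme mean and standard deviation of each metric, per target and
#' overall, plus the average rank of each scheme across targets (ranks are
#' computed on the per-target mean C-index, rank 1 = best, ties get average
#' ranks; lower is better).
#'
#' @param results data.frame from [runBenchmark()].
#' @return List with `perTarget` (data.frame), `overall` (data.frame) and
#'   `avgRank` (named numeric).
#' @export
summarizeBenchmark <- function(results) {
  agg <- stats::aggregate(cbind(c_index, auc) ~ target + scheme,
                          data = results, FUN = mean)
  sds <- stats::aggregate(cbind(c_index, auc) ~ target + scheme,
                          data = results, FUN = sd)
  names(sds)[3:4] <- c("c_index_sd", "auc_sd")
  perTarget <- merge(agg, sds, by = c("target", "scheme"))
  overall <- stats::aggregate(cbind(c_index, auc) ~ scheme, data = results,
                              FUN = mean)
  ranks <- do.call(rbind, lapply(split(perTarget, perTarget$target),
    function(d) {
      d$rank <- rank(-d$c_index, ties.method = "average")
      d[c("scheme", "rank")]
    }))
  avgRank <- tapply(ranks$rank, ranks$scheme, mean)
  list(perTarget = perTarget, overall = overall,
       avgRank = avgRank[order(avgRank)])
}

#' Paired one-sided Wilcoxon test between two schemes
#'
#' Tests whether `scheme` improves on `baseline` in C-index, pairing rows
#' by target, replicate and draw.
#'
#' @param results data.frame from [runBenchmark()].
#' @param scheme,baseline scheme names to compare.
#' @param metric metric column (default `"c_index"`).
#' @return p-value of the one-sided paired Wilcoxon signed-rank test.
#' @export
pairedSchemeTest <- function(results, scheme, baseline,
                             metric = "c_index") {
  key <- c("target", "replicate", "draw")
  a <- results[results$scheme == scheme, c(key, metric)]
  b <- results[results$scheme == baseline, c(key, metric)]
  m <- merge(a, b, by = key, suffixes = c(".a", ".b"))
  if (!nrow(m)) stop("no paired rows between '", scheme, "' and '",
                     baseline, "'")
  suppressWarnings(
    wilcox.test(m[[paste0(metric, ".a")]], m[[paste0(metric, ".b")]],
                paired = TRUE, alternative = "greater")$p.value)
}
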