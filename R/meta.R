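# Reptile meta-training: inner-loop full-batch gradient descent per task,
# meta-loop update of the shared initialization from the aggregated
# parameter displacement, plus the final few-shot fine-tuning phase.

#' Meta-training configuration
#'
#' Hyper-parameter grids considered for the study are: inner learning rate
#' alpha in \{1e-1, 5e-2, 1e-2, 5e-3, 1e-3\}, meta learning rate gamma in
#' \{5e-3, 1e-3, 5e-4, 1e-4, 5e-5\}, inner steps k in \{5, 10, 20\}, tasks
#' per meta-iteration m in \{3, 5, 10\} and task batch size in \{50, 100,
#' 200, 400, 800\}.
#'
#' @param alpha inner-loop (batch gradient descent) learning rate.
#' @param gamma meta-loop learning rate.
#' @param k inner gradient steps per task.
#' @param m tasks per meta-iteration.
#' @param taskSize samples per task batch.
#' @param metaIterations meta-loop iteration budget.
#' @param uncensoredFraction stratification of task batches: fraction of
#'   uncensored (event) samples per task (default 0.25, i.e. 25%
#'   uncensored / 75% censored).
#' @param optimizer meta-loop optimizer: `"adam"` (default) or `"plain"`
#'   (the literal displacement update, used for algebraic identities).
#' @param finetuneEpochs full-batch epochs of the final learning phase
#'   (default 50).
#' @param finetuneLr learning rate of the final learning phase; defaults to
#'   `alpha`.
#' @param poolScheduling `"union"` (tasks drawn from the pooled cohorts,
#'   default) or `"round_robin"` (cycle over per-cohort pools).
#' @param seed integer seed for task sampling, parameter initialization and
#'   similarity-loss negative sampling.
#' @return A list of class `metaConfig`.
#' @export
metaConfig <- function(alpha = 1e-2, gamma = 1e-3, k = 5L, m = 3L,
                       taskSize = 100L, metaIterations = 100L,
                       uncensoredFraction = 0.25,
                       optimizer = c("adam", "plain"),
                       finetuneEpochs = 50L, finetuneLr = NULL,
                       poolScheduling = c("union", "round_robin"),
                       seed = 1L) {
  optimizer <- match.arg(optimizer)
  poolScheduling <- match.arg(poolScheduling)
  stopifnot(alpha > 0, gamma > 0, k >= 0, m >= 1, taskSize >= 2,
            metaIterations >= 0, uncensoredFraction > 0,
            uncensoredFraction < 1)
  structure(list(alpha = alpha, gamma = gamma, k = as.integer(k),
                 m = as.integer(m), taskSize = as.integer(taskSize),
                 metaIterations = as.integer(metaIterations),
                 uncensoredFraction = uncensoredFraction,
                 optimizer = optimizer,
                 finetuneEpochs = as.integer(finetuneEpochs),
                 finetuneLr = if (is.null(finetuneLr)) alpha else finetuneLr,
                 poolScheduling = poolScheduling,
                 seed = as.integer(seed)),
            class = "metaConfig")
}

.roundHalfUp <- function(x) floor(x + 0.5)

#' Sample a stratified task batch from a pool
#'
#' Draws `round(nTask * uncensoredFraction)` uncensored samples
#' (round-half-up) and fills the remainder with censored samples, without
#' replacement, using the ambient RNG stream.
#'
#' @param pool a [MultiOmicsSurvData-class].
#' @param nTask task batch size.
#' @param uncensoredFraction target fraction of uncensored (event) samples.
#' @return A [MultiOmicsSurvData-class] of `nTask` samples.
#' @export
sampleTask <- function(pool, nTask, uncensoredFraction = 0.25) {
  ev <- survEvent(pool)
  nUnc <- .roundHalfUp(nTask * uncensoredFraction)
  nCen <- nTask - nUnc
  uncIdx <- which(ev == 1L); cenIdx <- which(ev == 0L)
  if (length(uncIdx) < nUnc)
    stop("pool has only ", length(uncIdx),
         " uncensored samples; task needs ", nUnc)
  if (length(cenIdx) < nCen)
    stop("pool has only ", length(cenIdx),
         " censored samples; task needs ", nCen)
  idx <- c(uncIdx[sample.int(length(uncIdx), nUnc)],
           cenIdx[sample.int(length(cenIdx), nCen)])
  pool[sort(idx)]
}

#' Plain gradient descent over a parameter list
#'
#' The shared descent engine of the inner loop and the fine-tuning phase:
#' `theta <- theta - lr * gradFn(theta)` for `steps` iterations.
#'
#' @param theta parameter list.
#' @param gradFn function of `theta` returning a gradient list of the same
#'   shape.
#' @param lr learning rate.
#' @param steps number of steps.
#' @return The updated parameter list.
#' @export
gradientDescentSteps <- function(theta, gradFn, lr, steps) {
  for (s in seq_len(steps)) {
    g <- gradFn(theta)
    if (!all(vapply(g, function(x) all(is.finite(x)), logical(1))))
      stop("non-finite gradient at step ", s)
    theta <- .paramAxpy(theta, g, -lr)
  }
  theta
}

#' Inner-loop adaptation of one task
#'
#' `k` full-batch gradient-descent steps on the total model loss over the
#' task's support set, starting from (and not modifying) `theta`.
#' Similarity-loss negatives under the `"one_random"` policy are resampled
#' at every step from the ambient RNG stream.
#'
#' @param theta model parameters (the current meta initialization).
#' @param task a [MultiOmicsSurvData-class] support set.
#' @param alpha inner learning rate.
#' @param k number of steps.
#' @param config the [survModelConfig()].
#' @param lossGradFn optional override returning `list(loss=, grads=)`
#'   given parameters; by default the model total loss on `task`.
#' @return The adapted parameter list.
#' @export
innerAdapt <- function(theta, task, alpha, k, config, lossGradFn = NULL) {
  if (is.null(lossGradFn))
    lossGradFn <- function(p) modelLossGrad(p, config, task)
  gradientDescentSteps(theta, function(p) lossGradFn(p)$grads, alpha, k)
}

# ---- Adam on the flat parameter vector ------------------------------------

.adamInit <- function(nParams) {
  list(m = numeric(nParams), v = numeric(nParams), t = 0L,
       beta1 = 0.9, beta2 = 0.999, eps = 1e-8)
}

.adamStep <- function(state, grad, lr) {
  state$t <- state$t + 1L
  state$m <- state$beta1 * state$m + (1 - state$beta1) * grad
  state$v <- state$beta2 * state$v + (1 - state$beta2) * grad^2
  mhat <- state$m / (1 - state$beta1^state$t)
  vhat <- state$v / (1 - state$beta2^state$t)
  list(state = state, delta = -lr * mhat / (sqrt(vhat) + state$eps))
}

#' Reptile meta-update
#'
#' Moves the initialization toward the task-adapted parameters:
#' `theta <- theta + gamma * mean(adapted - theta)` in plain mode; in adam
#' mode the negated mean displacement is fed as the gradient to an Adam
#' optimizer with learning rate `gamma`.
#'
#' @param theta current initialization (parameter list).
#' @param adapted list of adapted parameter lists (one per task).
#' @param gamma meta learning rate.
#' @param optimizer `"plain"` or `"adam"`.
#' @param adamState optional Adam state (created on first use).
#' @return List with `theta` (updated parameters) and `adamState`.
#' @export
reptileMetaUpdate <- function(theta, adapted, gamma,
                              optimizer = c("plain", "adam"),
                              adamState = NULL) {
  optimizer <- match.arg(optimizer)
  stopifnot(length(adapted) >= 1)
  thetaVec <- paramsToVector(theta)
  dvs <- lapply(adapted, function(a) {
    av <- paramsToVector(a)
    if (length(av) != length(thetaVec))
      stop("adapted parameter shape does not match theta")
    av - thetaVec
  })
  # canonicalize the summation order coordinate-wise (elementwise sorting
  # network) so the update is exactly invariant to task permutation
  m <- length(dvs)
  if (m > 1) {
    for (i in seq_len(m - 1)) for (j in seq_len(m - i)) {
      lo <- pmin(dvs[[j]], dvs[[j + 1]])
      hi <- pmax(dvs[[j]], dvs[[j + 1]])
      dvs[[j]] <- lo; dvs[[j + 1]] <- hi
    }
  }
  disp <- Reduce(`+`, dvs) / m
  if (optimizer == "plain") {
    # gamma = 1 with a single task replaces theta by the adapted parameters;
    # doing so directly keeps the identity exact in floating point
    newVec <- if (gamma == 1 && m == 1L) paramsToVector(adapted[[1]])
              else thetaVec + gamma * disp
  } else {
    if (is.null(adamState)) adamState <- .adamInit(length(thetaVec))
    st <- .adamStep(adamState, -disp, gamma)
    adamState <- st$state
    newVec <- thetaVec + st$delta
  }
  list(theta = vectorToParams(newVec, theta), adamState = adamState)
}

# one meta-iteration body (shared by metaTrain and resume)
.metaIteration <- function(theta, pools, modelCfg, metaCfg, adamState, it) {
  m <- metaCfg$m
  adapted <- vector("list", m)
  preLoss <- postLoss <- numeric(m)
  for (j in seq_len(m)) {
    pool <- if (metaCfg$poolScheduling == "round_robin")
      pools[[((it - 1L) * m + j - 1L) %% length(pools) + 1L]]
    else pools[[1L]]
    task <- sampleTask(pool, metaCfg$taskSize, metaCfg$uncensoredFraction)
    preLoss[j] <- totalLoss(theta, modelCfg, task,
                            negatives = seq_len(nSamples(task)) %% nSamples(task) + 1L)$total
    adapted[[j]] <- innerAdapt(theta, task, metaCfg$alpha, metaCfg$k,
                               modelCfg)
    postLoss[j] <- totalLoss(adapted[[j]], modelCfg, task,
                             negatives = seq_len(nSamples(task)) %% nSamples(task) + 1L)$total
  }
  upd <- reptileMetaUpdate(theta, adapted, metaCfg$gamma,
                           metaCfg$optimizer, adamState)
  list(theta = upd$theta, adamState = upd$adamState,
       preLoss = mean(preLoss), postLoss = mean(postLoss))
}

#' Meta-train a parameter initialization with first-order Reptile
#'
#' Each meta-iteration samples `m` stratified task batches from the pool,
#' adapts each with `k` inner gradient steps starting from the same current
#' initialization, and applies one Reptile meta-update. Fully deterministic
#' given the seed.
#'
#' @param pool a [MultiOmicsSurvData-class] or a list of them (cohorts).
#'   With `poolScheduling = "union"` a list is pooled sample-wise.
#' @param modelConfig a [survModelConfig()].
#' @param metaConfig a [metaConfig()].
#' @param init optional initial parameters; drawn from
#'   [initModelParams()] under the config seed when `NULL`.
#' @param checkpointPath optional path; a checkpoint is written every
#'   `checkpointEvery` iterations and at the end.
#' @param checkpointEvery iteration interval between checkpoints.
#' @param logPath optional TSV path for the per-iteration progress log
#'   (iteration, mean inner loss before/after adaptation).
#' @param resumeFrom optional checkpoint path to continue from; training
#'   resumes bit-identically to the uninterrupted run.
#' @return List of class `metaFit`: `theta` (the learned initialization),
#'   `log` (data.frame iteration/preLoss/postLoss), `modelConfig`,
#'   `metaConfig`.
#' @export
metaTrain <- function(pool, modelConfig, metaConfig, init = NULL,
                      checkpointPath = NULL, checkpointEvery = 50L,
                      logPath = NULL, resumeFrom = NULL) {
  pools <- if (is(pool, "MultiOmicsSurvData")) list(pool) else pool
  if (metaConfig$poolScheduling == "union" && length(pools) > 1L)
    pools <- list(bindSamples(pools))
  if (!is.null(resumeFrom)) {
    ck <- readRDS(resumeFrom)
    theta <- ck$theta
    adamState <- ck$adamState
    startIter <- ck$iteration
    logRows <- ck$log
    assign(".Random.seed", ck$rngState, envir = globalenv())
  } else {
    set.seed(metaConfig$seed)
    theta <- if (is.null(init)) initModelParams(modelConfig) else init
    adamState <- NULL
    startIter <- 0L
    logRows <- data.frame(iteration = integer(), preLoss = numeric(),
                          postLoss = numeric())
  }
  iters <- seq_len(metaConfig$metaIterations)
  iters <- iters[iters > startIter]
  for (it in iters) {
    res <- .metaIteration(theta, pools, modelConfig, metaConfig, adamState, it)
    theta <- res$theta
    adamState <- res$adamState
    logRows <- rbind(logRows,
                     data.frame(iteration = it, preLoss = res$preLoss,
                                postLoss = res$postLoss))
    if (!is.null(checkpointPath) &&
        (it %% checkpointEvery == 0L || it == metaConfig$metaIterations)) {
      saveRDS(list(theta = theta, adamState = adamState, iteration = it,
                   rngState = get(".Random.seed", envir = globalenv()),
                   log = logRows, metaConfig = metaConfig,
                   modelConfig = modelConfig),
              checkpointPath)
    }
  }
  if (!is.null(logPath))
    write.table(logRows, logPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  structure(list(theta = theta, log = logRows, modelConfig = modelConfig,
                 metaConfig = metaConfig),
            class = "metaFit")
}

#' Fine-tune a model on a few-shot training set
#'
#' The final learning phase: full-batch gradient descent on the total loss
#' from the (meta-learned) initialization.
#'
#' @param theta initial parameters (e.g. the meta-learned initialization).
#' @param fewShot a [MultiOmicsSurvData-class] with at least 2 samples and
#'   at least one event.
#' @param config the [survModelConfig()].
#' @param epochs number of full-batch steps (default 50).
#' @param lr learning rate.
#' @return Adapted parameter list.
#' @export
finetune <- function(theta, fewShot, config, epochs = 50L, lr = 1e-2) {
  if (nSamples(fewShot) < 2)
    stop("fine-tuning needs at least 2 samples")
  if (sum(survEvent(fewShot)) == 0)
    stop("fine-tuning set has zero events: the Cox loss has no signal")
  innerAdapt(theta, fewShot, lr, epochs, config)
}

#' @export
print.metaFit <- function(x, ...) {
  cat("metaFit:", nrow(x$log), "meta-iterations")
  if (nrow(x$log)) {
    tail10 <- utils::tail(x$log, 10)
    cat(sprintf("; final mean inner loss %.4f -> %.4f (last 10 iterations)",
                mean(tail10$preLoss), mean(tail10$postLoss)))
  }
  cat("\n")
  invisible(x)
}
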