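# Comparison training schemes sharing the multi-omics survival model:
# direct learning, pretraining + fine-tune, multitask learning,
# single-omics meta-learning, the no-similarity ablation, and the full
# multi-omics meta-learning method.

#' Registry of training-scheme names
#'
#' @return Character vector of the closed scheme registry.
#' @export
schemeNames <- function() {
  c("direct", "pretrain", "multitask", "meta_single_gene",
    "meta_single_mirna", "meta_wo_similarity", "mmosurv")
}

# resolve the view a single-omics scheme uses: by conventional name when
# present, otherwise by position (gene = first view, mirna = second)
.singleOmicsView <- function(scheme, views) {
  want <- sub("meta_single_", "", scheme)
  if (want %in% views) return(want)
  if (want == "gene") views[1]
  else if (length(views) >= 2) views[2]
  else stop("scheme '", scheme, "' needs a second omics view")
}

# model config restricted to a subset of views / with the similarity loss
# switched off
.schemeModelConfig <- function(scheme, config) {
  switch(scheme,
    meta_single_gene = ,
    meta_single_mirna = {
      v <- .singleOmicsView(scheme, names(config$viewDims))
      cfg <- config
      cfg$viewDims <- config$viewDims[v]
      cfg$simWeight <- 0
      cfg
    },
    meta_wo_similarity = { cfg <- config; cfg$simWeight <- 0; cfg },
    config)
}

# Adam training on sampled pool task batches (pretraining)
.adamTrainOnBatches <- function(theta, pool, config, metaCfg, steps) {
  state <- NULL
  for (s in seq_len(steps)) {
    task <- sampleTask(pool, metaCfg$taskSize, metaCfg$uncensoredFraction)
    gv <- paramsToVector(modelLossGrad(theta, config, task)$grads)
    if (is.null(state)) state <- .adamInit(length(gv))
    st <- .adamStep(state, gv, metaCfg$gamma)
    state <- st$state
    theta <- vectorToParams(paramsToVector(theta) + st$delta, theta)
  }
  theta
}

# Multitask learning: shared parameters, alternating full batches (one pool
# task batch, one target batch per round), equal weights by default; the
# relative target weight is `weight` (gradients scaled 2*(1-w) / 2*w so
# w = 0.5 reduces to plain alternation).
.multitaskTrain <- function(theta, pool, target, config, metaCfg, rounds,
                            weight = 0.5) {
  state <- .adamInit(length(paramsToVector(theta)))
  for (it in seq_len(rounds)) {
    task <- sampleTask(pool, metaCfg$taskSize, metaCfg$uncensoredFraction)
    for (piece in list(list(d = task, w = 2 * (1 - weight)),
                       list(d = target, w = 2 * weight))) {
      gv <- piece$w * paramsToVector(modelLossGrad(theta, config, piece$d)$grads)
      st <- .adamStep(state, gv, metaCfg$gamma)
      state <- st$state
      theta <- vectorToParams(paramsToVector(theta) + st$delta, theta)
    }
  }
  theta
}

#' Pool-phase training for a scheme
#'
#' Performs the part of a scheme that depends only on the meta-training
#' pool, so it can be computed once and reused across few-shot draws:
#' Reptile meta-training for the meta schemes, Adam pretraining on pool
#' task batches for `pretrain` (budget: `metaIterations * m` batches, the
#' number of task batches meta-training consumes). Returns `NULL` for
#' `direct` and `multitask` (no shareable pool phase).
#'
#' @param scheme scheme name from [schemeNames()].
#' @param pool a [MultiOmicsSurvData-class].
#' @param modelConfig a [survModelConfig()] for the full model; restricted
#'   per scheme (single view, similarity off) automatically.
#' @param metaConfig a [metaConfig()].
#' @param seed integer seed.
#' @return Scheme-specific pool-phase object (model parameters) or `NULL`.
#' @export
schemePoolPhase <- function(scheme, pool, modelConfig, metaConfig,
                            seed = 1L) {
  if (!scheme %in% schemeNames())
    stop("unknown scheme name '", scheme, "'")
  cfg <- .schemeModelConfig(scheme, modelConfig)
  switch(scheme,
    direct = NULL,
    multitask = NULL,
    pretrain = {
      set.seed(seed)
      theta <- initModelParams(cfg)
      .adamTrainOnBatches(theta, pool, cfg, metaConfig,
                          steps = metaConfig$metaIterations * metaConfig$m)
    },
    {
      mc <- metaConfig
      mc$seed <- seed
      poolUse <- if (length(cfg$viewDims) < length(modelConfig$viewDims))
        subsetViews(pool, names(cfg$viewDims)) else pool
      metaTrain(poolUse, cfg, mc)$theta
    })
}

#' Run one training scheme on one few-shot draw
#'
#' Trains per the scheme's protocol and scores the fitted model on the test
#' split: `direct` trains on the few-shot set only from a fresh random
#' initialization; `pretrain` fine-tunes the pool-pretrained parameters;
#' `multitask` jointly optimizes alternating pool-task and target-task
#' full batches with shared parameters (equal weights); the `meta_*`
#' schemes fine-tune the Reptile meta-learned initialization
#' (`meta_single_*` with a single encoder and no similarity loss,
#' `meta_wo_similarity` with both encoders and no similarity loss,
#' `mmosurv` the full method).
#'
#' @param scheme scheme name from [schemeNames()].
#' @param pool a [MultiOmicsSurvData-class] (used by `multitask`, and by
#'   pool phases computed on the fly).
#' @param targetTrain the few-shot training draw
#'   ([MultiOmicsSurvData-class]).
#' @param targetTest the held-out test split.
#' @param modelConfig a [survModelConfig()].
#' @param metaConfig a [metaConfig()].
#' @param seed integer seed for this fit.
#' @param poolPhase optional precomputed [schemePoolPhase()] result.
#' @return List with `params` (fitted parameters), `config` (the
#'   scheme-restricted model config), `scores` (test risk scores) and
#'   `result` (one-row data.frame: `scheme`, `c_index`, `auc`, `n_test`).
#' @export
runScheme <- function(scheme, pool, targetTrain, targetTest, modelConfig,
                      metaConfig, seed = 1L, poolPhase = NULL) {
  if (!scheme %in% schemeNames())
    stop("unknown scheme name '", scheme, "'")
  cfg <- .schemeModelConfig(scheme, modelConfig)
  restrict <- function(d) if (length(cfg$viewDims) < length(modelConfig$viewDims))
    subsetViews(d, names(cfg$viewDims)) else d
  train <- restrict(targetTrain)
  test <- restrict(targetTest)
  set.seed(seed)
  params <- switch(scheme,
    direct = {
      theta <- initModelParams(cfg)
      finetune(theta, train, cfg, metaConfig$finetuneEpochs,
               metaConfig$finetuneLr)
    },
    pretrain = {
      if (is.null(poolPhase))
        poolPhase <- schemePoolPhase(scheme, pool, modelConfig, metaConfig,
                                     seed)
      set.seed(fanSeed(seed, "finetune"))
      finetune(poolPhase, train, cfg, metaConfig$finetuneEpochs,
               metaConfig$finetuneLr)
    },
    multitask = {
      theta <- initModelParams(cfg)
      .multitaskTrain(theta, restrict(pool), train, cfg, metaConfig,
                      rounds = metaConfig$metaIterations)
    },
    {
      if (is.null(poolPhase))
        poolPhase <- schemePoolPhase(scheme, pool, modelConfig, metaConfig,
                                     seed)
      set.seed(fanSeed(seed, "finetune"))
      finetune(poolPhase, train, cfg, metaConfig$finetuneEpochs,
               metaConfig$finetuneLr)
    })
  scores <- predictRisk(params, cfg, test)
  ci <- concordanceIndex(scores, survTime(test), survEvent(test))
  auc <- tryCatch(timeDependentAUC(scores, survTime(test), survEvent(test)),
                  error = function(e) NA_real_)
  list(params = params, config = cfg, scores = scores,
       result = data.frame(scheme = scheme, c_index = ci, auc = auc,
                           n_test = nSamples(test)))
}
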