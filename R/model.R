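# Deep multi-omics Cox model: forward passes, losses and analytic gradients.
# All heavy lifting is dense matrix algebra; gradients are hand-derived and
# verified against finite differences in the test suite.

.addRowVec <- function(M, b) M + matrix(b, nrow(M), length(b), byrow = TRUE)
.sigmoid <- function(x) 1 / (1 + exp(-x))

#' One highway layer
#'
#' `out = H(x) * T(x) + G(x) * (1 - T(x))` with transform
#' `H(x) = tanh(x Wh + bh)`, carry `G(x) = x Wg + bg` and gate
#' `T(x) = sigmoid(x Wt + bt)`, all elementwise: the gate mixes the
#' nonlinear transform with the (near-)identity carry path.
#'
#' @param x numeric vector or matrix (rows = samples).
#' @param layerParams list with matrices `Wh`, `Wt`, `Wg` and bias vectors
#'   `bh`, `bt`, `bg`.
#' @return Numeric matrix of the same shape as `x` (vectors are treated as
#'   one-row matrices and returned as vectors).
#' @export
highwayLayer <- function(x, layerParams) {
  vec <- is.null(dim(x))
  if (vec) x <- matrix(x, 1)
  H <- tanh(.addRowVec(x %*% layerParams$Wh, layerParams$bh))
  Tg <- .sigmoid(.addRowVec(x %*% layerParams$Wt, layerParams$bt))
  G <- .addRowVec(x %*% layerParams$Wg, layerParams$bg)
  out <- H * Tg + G * (1 - Tg)
  if (vec) drop(out) else out
}

# forward pass of one encoder with cache for backprop
.encodeForward <- function(X, params, view, nLayers) {
  pre <- paste0("enc.", view, ".")
  A <- .addRowVec(X %*% params[[paste0(pre, "W0")]], params[[paste0(pre, "b0")]])
  layers <- vector("list", nLayers)
  for (l in seq_len(nLayers)) {
    lp <- paste0(pre, "L", l, ".")
    H <- tanh(.addRowVec(A %*% params[[paste0(lp, "Wh")]], params[[paste0(lp, "bh")]]))
    Tg <- .sigmoid(.addRowVec(A %*% params[[paste0(lp, "Wt")]], params[[paste0(lp, "bt")]]))
    G <- .addRowVec(A %*% params[[paste0(lp, "Wg")]], params[[paste0(lp, "bg")]])
    layers[[l]] <- list(Ain = A, H = H, Tg = Tg, G = G)
    A <- H * Tg + G * (1 - Tg)
  }
  list(Z = A, layers = layers)
}

# backward pass of one encoder; accumulates into `grads` (an environment-free
# named list) and returns it
.encodeBackward <- function(dZ, X, cache, params, view, nLayers, grads) {
  pre <- paste0("enc.", view, ".")
  dA <- dZ
  for (l in rev(seq_len(nLayers))) {
    lp <- paste0(pre, "L", l, ".")
    cl <- cache$layers[[l]]
    dH <- dA * cl$Tg
    dT <- dA * (cl$H - cl$G)
    dG <- dA * (1 - cl$Tg)
    dPreH <- dH * (1 - cl$H^2)
    dPreT <- dT * cl$Tg * (1 - cl$Tg)
    grads[[paste0(lp, "Wh")]] <- grads[[paste0(lp, "Wh")]] + crossprod(cl$Ain, dPreH)
    grads[[paste0(lp, "bh")]] <- grads[[paste0(lp, "bh")]] + colSums(dPreH)
    grads[[paste0(lp, "Wt")]] <- grads[[paste0(lp, "Wt")]] + crossprod(cl$Ain, dPreT)
    grads[[paste0(lp, "bt")]] <- grads[[paste0(lp, "bt")]] + colSums(dPreT)
    grads[[paste0(lp, "Wg")]] <- grads[[paste0(lp, "Wg")]] + crossprod(cl$Ain, dG)
    grads[[paste0(lp, "bg")]] <- grads[[paste0(lp, "bg")]] + colSums(dG)
    dA <- tcrossprod(dPreH, params[[paste0(lp, "Wh")]]) +
          tcrossprod(dPreT, params[[paste0(lp, "Wt")]]) +
          tcrossprod(dG, params[[paste0(lp, "Wg")]])
  }
  grads[[paste0(pre, "W0")]] <- grads[[paste0(pre, "W0")]] + crossprod(X, dA)
  grads[[paste0(pre, "b0")]] <- grads[[paste0(pre, "b0")]] + colSums(dA)
  grads
}

#' Encode one omics view into the shared embedding space
#'
#' Deterministic given the parameters; each embedding row depends only on
#' its own sample (no batch coupling).
#'
#' @param X numeric matrix (samples x features) or [OmicsMatrix-class].
#' @param params model parameters from [initModelParams()].
#' @param view view name (must match a `viewDims` entry of the config the
#'   parameters were initialized from).
#' @param config the [survModelConfig()].
#' @return Numeric matrix, samples x `embedDim`.
#' @export
encodeView <- function(X, params, view, config) {
  if (is(X, "OmicsMatrix")) X <- omicsValues(X)
  if (!view %in% names(config$viewDims))
    stop("unknown view '", view, "'")
  if (ncol(X) != config$viewDims[[view]])
    stop("input has ", ncol(X), " features but encoder '", view,
         "' expects ", config$viewDims[[view]])
  .encodeForward(X, params, view, config$nLayers)$Z
}

#' Cosine similarity of two vectors
#'
#' Scale-invariant: `cosineSimilarity(c * a, b) == cosineSimilarity(a, b)`
#' for any c > 0. Errors on zero vectors (inside the training loss a
#' norm guard of 1e-12 is used instead).
#'
#' @param a,b numeric vectors of equal length.
#' @return Cosine similarity in `[-1, 1]`.
#' @export
cosineSimilarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vectors")
  sum(a * b) / (na * nb)
}

# guarded row normalization used inside the training loss:
# n_i = z_i / sqrt(|z_i|^2 + epsSq); gradient of g wrt z is (g - n (n.g))/r
.NORM_EPS_SQ <- 1e-24

.rowNormalize <- function(Z) {
  r <- sqrt(rowSums(Z^2) + .NORM_EPS_SQ)
  list(N = Z / r, r = r)
}

# resolve negative indices per anchor according to the policy; uses the
# ambient RNG stream for "one_random"
.chooseNegatives <- function(S, rule) {
  n <- nrow(S)
  if (n < 2) stop("similarity loss needs at least 2 samples")
  switch(rule,
    one_random = lapply(seq_len(n), function(i) {
      cand <- setdiff(seq_len(n), i)
      cand[sample.int(length(cand), 1L)]
    }),
    all_pairs = lapply(seq_len(n), function(i) setdiff(seq_len(n), i)),
    hardest = lapply(seq_len(n), function(i) {
      s <- S[i, ]; s[i] <- -Inf
      which.max(s)
    }),
    stop("unknown negative rule '", rule, "'"))
}

# core similarity loss + gradient on the two embedding matrices
# negatives: list of integer vectors (per anchor), already resolved
.simLossGradCore <- function(Z1, Z2, margin, negatives, symmetric = FALSE) {
  n <- nrow(Z1)
  n1 <- .rowNormalize(Z1); n2 <- .rowNormalize(Z2)
  S <- tcrossprod(n1$N, n2$N)            # S[i, j] = sim(z_i^1, z_j^2)
  directions <- if (symmetric) list(c(1, 2), c(2, 1)) else list(c(1, 2))
  loss <- 0
  D <- matrix(0, n, n)                    # dLoss/dS accumulation
  Dt <- matrix(0, n, n)                   # for the reversed direction: dLoss/d t(S)
  for (dir in directions) {
    Sd <- if (dir[1] == 1) S else t(S)
    acc <- 0
    Dd <- matrix(0, n, n)
    for (i in seq_len(n)) {
      js <- negatives[[i]]
      w <- 1 / (n * length(js) * length(directions))
      hinge <- margin - (Sd[i, i] - Sd[i, js])
      active <- hinge > 0
      acc <- acc + sum(pmax(hinge, 0)) * w
      if (any(active)) {
        Dd[i, js[active]] <- Dd[i, js[active]] + w
        Dd[i, i] <- Dd[i, i] - w * sum(active)
      }
    }
    loss <- loss + acc
    if (dir[1] == 1) D <- D + Dd else Dt <- Dt + Dd
  }
  Dfull <- D + t(Dt)                      # total dLoss/dS
  G1 <- Dfull %*% n2$N                    # dLoss/dN1
  G2 <- crossprod(Dfull, n1$N)            # dLoss/dN2
  dZ1 <- (G1 - n1$N * rowSums(G1 * n1$N)) / n1$r
  dZ2 <- (G2 - n2$N * rowSums(G2 * n2$N)) / n2$r
  list(loss = loss, dZ1 = dZ1, dZ2 = dZ2)
}

#' Cross-omics margin similarity loss
#'
#' Hinge loss `max(0, M - (sim(z_i^1, z_i^2) - sim(z_i^1, z_j^2)))`,
#' averaged over anchors i (and, per policy, negatives j): same-patient
#' embeddings from the two omics should be more similar than cross-patient
#' pairs by at least the margin M. Returns 0 when every same-patient
#' similarity exceeds every selected cross-patient similarity by at least M.
#'
#' @param Z1,Z2 embedding matrices (samples x embedDim), row-aligned by
#'   patient.
#' @param margin margin M (default 0.2).
#' @param negativeRule `"one_random"`, `"all_pairs"` or `"hardest"`; see
#'   [survModelConfig()].
#' @param negatives optional explicit list of negative indices per anchor
#'   (overrides `negativeRule`; used for deterministic gradient checks).
#' @param symmetric average both anchor directions.
#' @return Non-negative scalar loss.
#' @export
similarityLoss <- function(Z1, Z2, margin = 0.2,
                           negativeRule = c("one_random", "all_pairs",
                                            "hardest"),
                           negatives = NULL, symmetric = FALSE) {
  negativeRule <- match.arg(negativeRule)
  stopifnot(identical(dim(Z1), dim(Z2)))
  if (nrow(Z1) < 2) stop("similarity loss needs at least 2 samples")
  if (is.null(negatives)) {
    n1 <- .rowNormalize(Z1); n2 <- .rowNormalize(Z2)
    S <- tcrossprod(n1$N, n2$N)
    negatives <- .chooseNegatives(S, negativeRule)
  } else if (is.numeric(negatives)) {
    negatives <- as.list(as.integer(negatives))
  }
  .simLossGradCore(Z1, Z2, margin, negatives, symmetric)$loss
}

#' Fuse per-view embeddings
#'
#' Elementwise mean of the aligned per-view embeddings,
#' `z_i = (z_i^1 + z_i^2) / 2` for two views.
#'
#' @param ... embedding matrices or vectors of identical shape, or a single
#'   list of them.
#' @return The elementwise mean, same shape as the inputs.
#' @export
fuseEmbeddings <- function(...) {
  zs <- list(...)
  if (length(zs) == 1L && is.list(zs[[1]]) && !is.numeric(zs[[1]]))
    zs <- zs[[1]]
  stopifnot(length(zs) >= 1)
  Reduce(`+`, zs) / length(zs)
}

# risk head forward with cache
.headForward <- function(Z, params) {
  if (!is.null(params[["head.W1"]])) {
    U <- tanh(.addRowVec(Z %*% params[["head.W1"]], params[["head.b1"]]))
    h <- drop(U %*% params[["head.w"]]) + params[["head.b"]]
    list(h = h, U = U)
  } else {
    list(h = drop(Z %*% params[["head.w"]]) + params[["head.b"]], U = NULL)
  }
}

.headBackward <- function(dh, Z, cache, params, grads) {
  dh <- matrix(dh, ncol = 1)
  if (!is.null(params[["head.W1"]])) {
    U <- cache$U
    grads[["head.w"]] <- grads[["head.w"]] + crossprod(U, dh)
    grads[["head.b"]] <- grads[["head.b"]] + sum(dh)
    dUpre <- (dh %*% t(params[["head.w"]])) * (1 - U^2)
    grads[["head.W1"]] <- grads[["head.W1"]] + crossprod(Z, dUpre)
    grads[["head.b1"]] <- grads[["head.b1"]] + colSums(dUpre)
    dZ <- tcrossprod(dUpre, params[["head.W1"]])
  } else {
    grads[["head.w"]] <- grads[["head.w"]] + crossprod(Z, dh)
    grads[["head.b"]] <- grads[["head.b"]] + sum(dh)
    dZ <- dh %*% t(params[["head.w"]])
  }
  list(grads = grads, dZ = dZ)
}

#' Risk score of a fused embedding
#'
#' Scalar log-relative-hazard; higher means higher predicted risk.
#'
#' @param z fused embedding vector (or matrix of rows).
#' @param params model parameters (uses the `head.*` entries).
#' @return Numeric score(s).
#' @export
riskScore <- function(z, params) {
  if (is.null(dim(z))) z <- matrix(z, 1)
  .headForward(z, params)$h
}

#' Negative mean log Cox partial likelihood
#'
#' `-(1/n) sum_i delta_i (h_i - log sum_{j in R_i} exp(h_j))` with
#' Breslow-style risk sets. Under the default `"geq"` rule the risk set of
#' an event at time t is every subject with observed time >= t (self
#' included), so every event term is well defined; under `"gt"` only
#' strictly later observed times are at risk and an event with an empty risk
#' set is an error. The log-sum-exp is computed with max-subtraction.
#'
#' @param scores numeric vector of risk scores h.
#' @param time positive observed times.
#' @param event event indicators in \{0, 1\}.
#' @param riskSetRule `"geq"` (default) or `"gt"`.
#' @return Scalar loss; 0 with a warning when every subject is censored
#'   (no gradient signal).
#' @export
coxPartialLikelihood <- function(scores, time, event,
                                 riskSetRule = c("geq", "gt")) {
  .coxLossGrad(scores, time, event, match.arg(riskSetRule),
               computeGrad = FALSE)$loss
}

.coxLossGrad <- function(scores, time, event, riskSetRule = "geq",
                         computeGrad = TRUE) {
  n <- length(scores)
  stopifnot(length(time) == n, length(event) == n, all(time > 0))
  if (all(event == 0)) {
    warning("all subjects censored: Cox partial likelihood is 0 with no gradient signal")
    return(list(loss = 0, grad = numeric(n)))
  }
  ord <- order(time, decreasing = TRUE)
  hs <- scores[ord]; ts <- time[ord]; ev <- event[ord]
  M <- max(hs)
  e <- exp(hs - M)
  cume <- cumsum(e)
  # tie groups are contiguous in the sorted order
  first <- ave(seq_len(n), match(ts, unique(ts)), FUN = min)
  last <- ave(seq_len(n), match(ts, unique(ts)), FUN = max)
  if (riskSetRule == "geq") {
    S <- cume[last]
  } else {
    emptyIdx <- which(first == 1L & ev == 1L)
    if (length(emptyIdx))
      stop("empty risk set under the strict 'gt' rule for event(s) at the ",
           "latest observed time ", ts[1])
    S <- ifelse(first > 1L, cume[pmax(first - 1L, 1L)], NA_real_)
  }
  evIdx <- ev == 1L
  loss <- -mean(ifelse(evIdx, hs - (log(S) + M), 0))
  grad <- NULL
  if (computeGrad) {
    W <- ifelse(evIdx, 1 / S, 0)
    revcum <- rev(cumsum(rev(W)))              # revcum[j] = sum_{i >= j} W_i
    revcum <- c(revcum, 0)
    Tk <- if (riskSetRule == "geq") revcum[first] else revcum[last + 1L]
    gs <- -(ev - e * Tk) / n
    grad <- numeric(n)
    grad[ord] <- gs
  }
  list(loss = loss, grad = grad)
}

#' Total loss of the multi-omics survival model
#'
#' `total = cox + simWeight * sim`: the Cox partial-likelihood loss on the
#' fused embeddings plus the weighted cross-omics similarity loss.
#'
#' @param params model parameters.
#' @param config a [survModelConfig()].
#' @param views named list of preprocessed matrices (samples x features),
#'   in the order of `config$viewDims`, or a [MultiOmicsSurvData-class].
#' @param time,event survival outcomes (ignored when `views` is a
#'   [MultiOmicsSurvData-class]).
#' @param negatives optional explicit negative indices for the similarity
#'   loss (deterministic evaluation).
#' @return List of class `lossBreakdown` with elements `cox`, `sim`,
#'   `total` and `simWeight` (`total == cox + simWeight * sim`).
#' @export
totalLoss <- function(params, config, views, time = NULL, event = NULL,
                      negatives = NULL) {
  out <- modelLossGrad(params, config, views, time, event,
                       negatives = negatives, computeGrad = FALSE)
  out$loss
}

#' Loss and analytic gradient of the multi-omics survival model
#'
#' Backpropagates the total loss through the risk head, the embedding
#' fusion and every highway encoder. Gradient correctness is established
#' against central finite differences in the test suite.
#'
#' @inheritParams totalLoss
#' @param computeGrad set `FALSE` to skip the backward pass.
#' @return List with `loss` (a `lossBreakdown`) and `grads` (parameter list
#'   of the same shape as `params`, or `NULL`).
#' @export
modelLossGrad <- function(params, config, views, time = NULL, event = NULL,
                          negatives = NULL, computeGrad = TRUE) {
  if (is(views, "MultiOmicsSurvData")) {
    time <- survTime(views); event <- survEvent(views)
    views <- omicsViews(views)
  }
  vn <- names(config$viewDims)
  missingViews <- setdiff(vn, names(views))
  if (length(missingViews))
    stop("missing view(s): ", paste(missingViews, collapse = ", "))
  views <- views[vn]
  n <- nrow(views[[1]])
  if (n < 1) stop("empty batch")
  caches <- lapply(vn, function(v) {
    X <- views[[v]]
    if (ncol(X) != config$viewDims[[v]])
      stop("view '", v, "' has ", ncol(X), " features, expected ",
           config$viewDims[[v]])
    .encodeForward(X, params, v, config$nLayers)
  })
  names(caches) <- vn
  Zs <- lapply(caches, `[[`, "Z")
  fused <- Reduce(`+`, Zs) / length(Zs)
  headCache <- .headForward(fused, params)
  coxOut <- .coxLossGrad(headCache$h, time, event, config$riskSetRule,
                         computeGrad = computeGrad)
  useSim <- config$simWeight != 0 && length(Zs) >= 2
  simOut <- NULL
  if (useSim) {
    if (n < 2) stop("similarity loss needs at least 2 samples")
    if (is.null(negatives)) {
      n1 <- .rowNormalize(Zs[[1]]); n2 <- .rowNormalize(Zs[[2]])
      S <- tcrossprod(n1$N, n2$N)
      negatives <- .chooseNegatives(S, config$negativeRule)
    } else if (is.numeric(negatives)) {
      negatives <- as.list(as.integer(negatives))
    }
    simOut <- .simLossGradCore(Zs[[1]], Zs[[2]], config$margin, negatives,
                               config$symmetricSim)
  }
  simLoss <- if (useSim) simOut$loss else 0
  loss <- structure(list(cox = coxOut$loss, sim = simLoss,
                         simWeight = config$simWeight,
                         total = coxOut$loss + config$simWeight * simLoss),
                    class = "lossBreakdown")
  if (!computeGrad) return(list(loss = loss, grads = NULL))

  grads <- .paramZero(params)
  hb <- .headBackward(coxOut$grad, fused, headCache, params, grads)
  grads <- hb$grads
  dZs <- lapply(Zs, function(z) hb$dZ / length(Zs))
  if (useSim) {
    dZs[[1]] <- dZs[[1]] + config$simWeight * simOut$dZ1
    dZs[[2]] <- dZs[[2]] + config$simWeight * simOut$dZ2
  }
  for (v in vn)
    grads <- .encodeBackward(dZs[[v]], views[[v]], caches[[v]], params, v,
                             config$nLayers, grads)
  list(loss = loss, grads = grads)
}

#' Predict risk scores for a multi-omics dataset
#'
#' Encodes every view, fuses the embeddings and applies the risk head.
#'
#' @param params model parameters.
#' @param config a [survModelConfig()].
#' @param data a [MultiOmicsSurvData-class] or named list of matrices.
#' @return Numeric vector of log-relative-hazard scores (higher = higher
#'   risk), named by sample when available.
#' @export
predictRisk <- function(params, config, data) {
  views <- if (is(data, "MultiOmicsSurvData")) omicsViews(data) else data
  vn <- names(config$viewDims)
  Zs <- lapply(vn, function(v) encodeView(views[[v]], params, v, config))
  fused <- Reduce(`+`, Zs) / length(Zs)
  h <- .headForward(fused, params)$h
  names(h) <- rownames(views[[vn[1]]])
  h
}

#' @export
print.lossBreakdown <- function(x, ...) {
  cat(sprintf("loss: total = %.6g (cox = %.6g, sim = %.6g, simWeight = %g)\n",
              x$total, x$cox, x$sim, x$simWeight))
  invisible(x)
}
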