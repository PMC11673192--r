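#' Configuration of one highway encoder
#'
#' A highway encoder maps one raw omics profile to the shared embedding
#' space: an initial linear projection to `hiddenDim`, then `nLayers`
#' highway layers `out = H(x)*T(x) + G(x)*(1 - T(x))` where H is a tanh
#' transform, G an affine carry path (initialized at the identity) and T a
#' sigmoid transform gate. A negative `gateBiasInit` biases the gate toward
#' the carry path at initialization, so a freshly initialized deep encoder
#' behaves near-linearly and gradients flow.
#'
#' @param inputDim number of input features for the view.
#' @param nLayers number of highway layers (default 5).
#' @param embedDim embedding dimension (default 80).
#' @param hiddenDim width of the highway layers; defaults to `embedDim`.
#' @param gateBiasInit initial transform-gate bias (default -2,
#'   carry-biased).
#' @return A list of class `highwayConfig`.
#' @export
highwayConfig <- function(inputDim, nLayers = 5L, embedDim = 80L,
                          hiddenDim = embedDim, gateBiasInit = -2) {
  stopifnot(inputDim >= 1, nLayers >= 1, embedDim >= 1,
            hiddenDim == embedDim)
  structure(list(inputDim = as.integer(inputDim),
                 nLayers = as.integer(nLayers),
                 embedDim = as.integer(embedDim),
                 gateBiasInit = gateBiasInit),
            class = "highwayConfig")
}

#' Configuration of the multi-omics deep Cox survival model
#'
#' @param viewDims named integer vector of per-view input dimensions, e.g.
#'   `c(gene = 500, mirna = 100)`. One highway encoder is instantiated per
#'   view.
#' @param nLayers highway layers per encoder (default 5).
#' @param embedDim shared embedding dimension (default 80).
#' @param margin margin M of the cross-omics hinge similarity loss
#'   (default 0.2).
#' @param simWeight weight of the similarity loss in the total loss
#'   (default 1; the total loss is `cox + simWeight * sim`). Set to 0 for
#'   the no-similarity ablation; the similarity term is then skipped
#'   entirely.
#' @param negativeRule negative-pair policy of the similarity loss:
#'   `"one_random"` (one random j != i per anchor, resampled each step;
#'   default), `"all_pairs"` (mean over all j != i) or `"hardest"`
#'   (most similar cross-patient pair).
#' @param symmetricSim if `TRUE`, average the hinge over both anchor
#'   directions (view1 vs view2 and view2 vs view1); default `FALSE`
#'   (anchor view 1 only).
#' @param riskSetRule Cox risk-set convention: `"geq"` (default; risk set
#'   of an event at time t is every subject with observed time >= t,
#'   Breslow-style, always well defined) or `"gt"` (strictly later times
#'   only; errors when an event has an empty risk set).
#' @param headHidden width of an optional hidden layer in the risk head;
#'   `NULL` (default) for a single linear layer on the fused embedding.
#' @param gateBiasInit transform-gate bias initialization (default -2).
#' @return A list of class `survModelConfig`.
#' @export
survModelConfig <- function(viewDims, nLayers = 5L, embedDim = 80L,
                            margin = 0.2, simWeight = 1,
                            negativeRule = c("one_random", "all_pairs",
                                             "hardest"),
                            symmetricSim = FALSE,
                            riskSetRule = c("geq", "gt"),
                            headHidden = NULL, gateBiasInit = -2) {
  negativeRule <- match.arg(negativeRule)
  riskSetRule <- match.arg(riskSetRule)
  stopifnot(length(viewDims) >= 1, !is.null(names(viewDims)),
            all(nzchar(names(viewDims))), all(viewDims >= 1),
            nLayers >= 1, embedDim >= 1, margin >= 0, simWeight >= 0)
  structure(list(viewDims = vapply(viewDims, as.integer, integer(1)),
                 nLayers = as.integer(nLayers),
                 embedDim = as.integer(embedDim),
                 margin = margin, simWeight = simWeight,
                 negativeRule = negativeRule, symmetricSim = symmetricSim,
                 riskSetRule = riskSetRule,
                 headHidden = if (is.null(headHidden)) NULL
                              else as.integer(headHidden),
                 gateBiasInit = gateBiasInit),
            class = "survModelConfig")
}

#' Initialize model parameters
#'
#' Parameters theta = \{phi, beta\} are a flat named list of numeric arrays:
#' encoder (phi) weights per view (`enc.<view>.*`) and risk-head (beta)
#' weights (`head.*`). Encoder projections use Glorot-style scaling, the
#' carry path G starts at the identity and the transform gates start
#' carry-biased, so the initial network is close to a random linear
#' projection.
#'
#' @param config a [survModelConfig()].
#' @param seed optional integer seed; when `NULL` the ambient RNG stream is
#'   used.
#' @return Named list of parameter arrays (class `modelParams`).
#' @export
initModelParams <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  d <- config$embedDim
  params <- list()
  for (v in names(config$viewDims)) {
    p <- config$viewDims[[v]]
    params[[paste0("enc.", v, ".W0")]] <-
      matrix(rnorm(p * d, sd = sqrt(2 / (p + d))), p, d)
    params[[paste0("enc.", v, ".b0")]] <- numeric(d)
    for (l in seq_len(config$nLayers)) {
      pre <- paste0("enc.", v, ".L", l, ".")
      params[[paste0(pre, "Wh")]] <- matrix(rnorm(d * d, sd = sqrt(1 / d)), d, d)
      params[[paste0(pre, "bh")]] <- numeric(d)
      params[[paste0(pre, "Wt")]] <- matrix(rnorm(d * d, sd = sqrt(1 / d)), d, d)
      params[[paste0(pre, "bt")]] <- rep(config$gateBiasInit, d)
      params[[paste0(pre, "Wg")]] <- diag(d)
      params[[paste0(pre, "bg")]] <- numeric(d)
    }
  }
  if (is.null(config$headHidden)) {
    params[["head.w"]] <- matrix(rnorm(d, sd = 0.1 / sqrt(d)), d, 1)
    params[["head.b"]] <- 0
  } else {
    hd <- config$headHidden
    params[["head.W1"]] <- matrix(rnorm(d * hd, sd = sqrt(2 / (d + hd))), d, hd)
    params[["head.b1"]] <- numeric(hd)
    params[["head.w"]] <- matrix(rnorm(hd, sd = 0.1 / sqrt(hd)), hd, 1)
    params[["head.b"]] <- 0
  }
  structure(params, class = "modelParams")
}

#' Flatten model parameters to a single numeric vector
#'
#' Parameters are restorable losslessly with [vectorToParams()]; this is
#' the representation the Reptile displacement arithmetic and the Adam
#' meta-optimizer operate on.
#'
#' @param params a parameter list from [initModelParams()].
#' @return Numeric vector of all parameter entries.
#' @export
paramsToVector <- function(params) {
  unlist(params, use.names = FALSE)
}

#' Restore model parameters from a flat vector
#'
#' @param vec numeric vector as produced by [paramsToVector()].
#' @param skeleton a parameter list providing names and shapes.
#' @return Parameter list with the values of `vec`.
#' @export
vectorToParams <- function(vec, skeleton) {
  out <- skeleton
  pos <- 0L
  for (nm in names(skeleton)) {
    k <- length(skeleton[[nm]])
    piece <- vec[(pos + 1L):(pos + k)]
    attributes(piece) <- attributes(skeleton[[nm]])
    out[[nm]] <- piece
    pos <- pos + k
  }
  if (pos != length(vec))
    stop("parameter vector length ", length(vec),
         " does not match skeleton size ", pos)
  out
}

# elementwise theta <- a + s * b over two parameter lists
.paramAxpy <- function(a, b, s) {
  out <- a
  for (nm in names(a)) out[[nm]] <- a[[nm]] + s * b[[nm]]
  out
}

.paramZero <- function(skeleton) {
  lapply(skeleton, function(p) { p[] <- 0; p })
}

#' @export
print.modelParams <- function(x, ...) {
  cat("modelParams:", length(x), "arrays,",
      length(paramsToVector(x)), "parameters\n")
  invisible(x)
}
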