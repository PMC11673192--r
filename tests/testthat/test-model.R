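# The multi-omics survival model: highway layers, encoders, similarity and
# Cox losses, and analytic gradients.

test_that("highway layer interpolates between carry and transform paths", {
  d <- 3
  lp <- list(Wh = matrix(0.5, d, d), bh = rep(0.1, d),
             Wt = matrix(0, d, d), bt = rep(-1e4, d),   # T ~ 0
             Wg = diag(d), bg = numeric(d))
  x <- c(0.3, -0.2, 1.1)
  expect_equal(highwayLayer(x, lp), x, tolerance = 1e-12)  # carry path
  lp$bt <- rep(1e4, d)                                     # T ~ 1
  expect_equal(highwayLayer(x, lp),
               drop(tanh(x %*% lp$Wh + lp$bh)), tolerance = 1e-12)
  # hand-computed 2-dim gate mixture
  lp2 <- list(Wh = matrix(c(1, 0, 0, 1), 2), bh = c(0, 0),
              Wt = matrix(0, 2, 2), bt = c(0, 0),        # T = 0.5
              Wg = 2 * diag(2), bg = c(1, 1))
  x2 <- c(0.4, -0.6)
  expect_equal(highwayLayer(x2, lp2),
               tanh(x2) * 0.5 + (2 * x2 + 1) * 0.5, tolerance = 1e-12)
})

test_that("encoding is per-sample, permutation-equivariant and shape-checked", {
  cfg <- tinyModelConfig()
  params <- initModelParams(cfg, seed = 3)
  X <- matrix(rnorm(8 * 6), 8, 6)
  Z <- encodeView(X, params, "gene", cfg)
  expect_identical(dim(Z), c(8L, 5L))
  # identical rows embed identically
  Xdup <- X[c(1, 1, 2), ]
  Zdup <- encodeView(Xdup, params, "gene", cfg)
  expect_equal(Zdup[1, ], Zdup[2, ])
  # permutation equivariance
  perm <- c(5, 2, 8, 1, 3, 7, 4, 6)
  expect_equal(encodeView(X[perm, ], params, "gene", cfg), Z[perm, ])
  # no batch coupling: single sample equals its in-batch row
  expect_equal(drop(encodeView(X[3, , drop = FALSE], params, "gene", cfg)),
               Z[3, ])
  expect_error(encodeView(X[, 1:4], params, "gene", cfg), "features")
})

test_that("cosine similarity is exact, scale-invariant and guarded", {
  a <- c(1, 2, -1)
  expect_equal(cosineSimilarity(a, a), 1)
  expect_equal(cosineSimilarity(c(1, 0), c(0, 1)), 0)
  expect_equal(cosineSimilarity(c(1, 0), c(1, 1)), 1 / sqrt(2),
               tolerance = 1e-12)
  expect_equal(cosineSimilarity(3.7 * a, a), 1, tolerance = 1e-12)
  expect_error(cosineSimilarity(c(0, 0), a), "zero")
})

test_that("similarity loss honours the margin and matches hand-computed hinges", {
  # perfectly aligned same-patient pairs, orthogonal cross pairs
  Z1 <- diag(3); Z2 <- diag(3)
  expect_equal(similarityLoss(Z1, Z2, margin = 0.2,
                              negativeRule = "all_pairs"), 0)
  # identical similarities everywhere -> hinge = margin
  Zc <- matrix(1, 4, 3)
  expect_equal(similarityLoss(Zc, Zc, margin = 0.2,
                              negativeRule = "all_pairs"), 0.2)
  # n = 2 hand case, all-pairs: one negative per anchor
  Z1 <- rbind(c(1, 0), c(0, 1))
  Z2 <- rbind(c(1, 1) / sqrt(2), c(0, 1))
  M <- 0.5
  s11 <- 1 / sqrt(2); s12 <- 0       # anchor 1: pos s11, neg s12
  s22 <- 1;           s21 <- 1 / sqrt(2)
  expected <- mean(c(max(0, M - (s11 - s12)), max(0, M - (s22 - s21))))
  expect_equal(similarityLoss(Z1, Z2, margin = M,
                              negativeRule = "all_pairs"),
               expected, tolerance = 1e-9)
  expect_error(similarityLoss(Z1[1, , drop = FALSE], Z2[1, , drop = FALSE]),
               "at least 2")
})

test_that("similarity loss is bounded by margin + 2 for all policies", {
  set.seed(9)
  for (rule in c("one_random", "all_pairs", "hardest")) {
    for (rep in 1:20) {
      n <- sample(2:8, 1)
      Z1 <- matrix(rnorm(n * 4), n, 4)
      Z2 <- matrix(rnorm(n * 4), n, 4)
      M <- runif(1, 0, 1)
      l <- similarityLoss(Z1, Z2, margin = M, negativeRule = rule)
      expect_gte(l, 0)
      expect_lte(l, M + 2 + 1e-12)
    }
  }
})

test_that("embedding fusion is the elementwise mean", {
  expect_equal(fuseEmbeddings(c(1, 3), c(3, 1)), c(2, 2))
  z <- rnorm(5)
  expect_equal(fuseEmbeddings(z, z), z)
  expect_equal(fuseEmbeddings(z, -z), rep(0, 5))
})

test_that("the linear risk head is a dot product plus bias", {
  cfg <- tinyModelConfig()
  params <- initModelParams(cfg, seed = 1)
  params[["head.w"]] <- matrix(c(1, -1, 0, 0, 0), 5, 1)
  params[["head.b"]] <- 0
  expect_equal(riskScore(c(2, 0.5, 0, 0, 0), params), 1.5)
  params[["head.w"]][] <- 0
  expect_equal(riskScore(rnorm(5), params), 0)
})

test_that("Cox loss matches the brute-force risk-set enumerator on random instances", {
  set.seed(17)
  for (rep in 1:200) {
    n <- sample(2:20, 1)
    h <- rnorm(n)
    time <- round(rexp(n) + 0.05, 2)  # rounding creates ties
    event <- rbinom(n, 1, 0.6)
    if (all(event == 0)) event[sample(n, 1)] <- 1L
    expect_equal(coxPartialLikelihood(h, time, event, "geq"),
                 bruteCoxLoss(h, time, event, "geq"), tolerance = 1e-10)
    lastEventAtMax <- any(event == 1 & time == max(time))
    if (!lastEventAtMax) {
      expect_equal(coxPartialLikelihood(h, time, event, "gt"),
                   bruteCoxLoss(h, time, event, "gt"), tolerance = 1e-10)
    } else {
      expect_error(coxPartialLikelihood(h, time, event, "gt"),
                   "empty risk set")
    }
  }
})

test_that("Cox loss trivial cases and shift invariance hold", {
  expect_warning(l <- coxPartialLikelihood(c(1, 2), c(1, 2), c(0, 0)),
                 "censored")
  expect_equal(l, 0)
  # n = 1 event with self-only risk set
  expect_equal(coxPartialLikelihood(0.7, 3, 1, "geq"), 0)
  # worked 3-sample example against the oracle
  h <- c(0.5, -0.2, 0.1); time <- c(1, 2, 3); event <- c(1, 0, 1)
  expect_equal(coxPartialLikelihood(h, time, event, "geq"),
               bruteCoxLoss(h, time, event, "geq"), tolerance = 1e-12)
  # shift invariance
  set.seed(4)
  for (rep in 1:20) {
    n <- sample(3:15, 1)
    h <- rnorm(n); time <- rexp(n) + 0.1; event <- rbinom(n, 1, 0.5)
    if (all(event == 0)) event[1] <- 1L
    c0 <- rnorm(1, sd = 5)
    expect_equal(coxPartialLikelihood(h + c0, time, event),
                 coxPartialLikelihood(h, time, event), tolerance = 1e-10)
  }
})

test_that("tied event times share the full batch as risk set under geq", {
  h <- c(0.2, -0.4, 1.1, 0)
  time <- rep(5, 4)
  event <- c(1L, 1L, 1L, 1L)
  lse <- log(sum(exp(h)))
  expect_equal(coxPartialLikelihood(h, time, event, "geq"),
               -mean(h - lse), tolerance = 1e-12)
  expect_error(coxPartialLikelihood(h, time, event, "gt"), "empty risk set")
})

test_that("the loss breakdown invariant total = cox + w * sim holds", {
  d <- makeTinyData(7, seed = 5)
  cfg <- tinyModelConfig(simWeight = 0.7, negativeRule = "all_pairs")
  params <- initModelParams(cfg, seed = 6)
  lb <- totalLoss(params, cfg, d)
  expect_equal(lb$total, lb$cox + 0.7 * lb$sim, tolerance = 1e-12)
  cfg0 <- tinyModelConfig(simWeight = 0)
  lb0 <- totalLoss(params, cfg0, d)
  expect_equal(lb0$total, lb0$cox)
  expect_equal(lb0$sim, 0)
})

test_that("backpropagated gradients match finite differences across configurations", {
  set.seed(31)
  configs <- list(
    tinyModelConfig(negativeRule = "all_pairs"),
    tinyModelConfig(negativeRule = "all_pairs", symmetricSim = TRUE),
    tinyModelConfig(riskSetRule = "gt"),
    tinyModelConfig(headHidden = 4L),
    tinyModelConfig(simWeight = 0)
  )
  for (cfg in configs) {
    d <- makeTinyData(6, seed = sample(1e4, 1))
    # keep the strict rule well defined: latest time censored, earliest an event
    d@event[which.max(d@time)] <- 0L
    d@event[which.min(d@time)] <- 1L
    params <- initModelParams(cfg, seed = sample(1e4, 1))
    negs <- sapply(seq_len(6), function(i) (i %% 6) + 1)
    out <- modelLossGrad(params, cfg, d, negatives = negs)
    f <- function(vec) totalLoss(vectorToParams(vec, params), cfg, d,
                                 negatives = negs)$total
    gNum <- numericGradient(f, paramsToVector(params))
    expect_lt(relativeError(paramsToVector(out$grads), gNum), 1e-4)
  }
})

test_that("risk prediction is deterministic and named by sample", {
  d <- makeTinyData(5, seed = 8)
  cfg <- tinyModelConfig()
  params <- initModelParams(cfg, seed = 9)
  h1 <- predictRisk(params, cfg, d)
  h2 <- predictRisk(params, cfg, d)
  expect_identical(h1, h2)
  expect_identical(names(h1), sampleIds(d))
})
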