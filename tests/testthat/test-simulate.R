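# The synthetic task-family generator: ground-truth structure, censoring
# calibration, independence of event and censoring times, determinism.

test_that("noiseless identity loadings reproduce the latent factors", {
  cfg <- syntheticConfig(latentDim = 3L, p1 = 3L, p2 = 3L, nPerTask = 20L,
                         nTasks = 2L, noiseSd = 0, seed = 5L)
  task <- generateSyntheticTask(cfg, 1L,
                                loadings = list(W1 = diag(3), W2 = diag(3),
                                                w = rep(0.5, 3)))
  U <- as.matrix(task$truth[, c("u1", "u2", "u3")])
  expect_equal(unname(omicsViews(task$dataset)$gene), unname(U),
               tolerance = 1e-12)
})

test_that("the generated survival data respect the observed-time identity", {
  cfg <- syntheticConfig(nPerTask = 300L, nTasks = 2L, seed = 6L)
  task <- generateSyntheticTask(cfg, 1L)
  tr <- task$truth
  d <- task$dataset
  expect_equal(survTime(d), pmin(tr$eventTime, tr$censorTime))
  expect_identical(survEvent(d), as.integer(tr$eventTime <= tr$censorTime))
  expect_true(all(survTime(d) > 0))
})

test_that("censoring-rate calibration hits the target censored fraction", {
  cfg <- syntheticConfig(nPerTask = 5000L, nTasks = 2L,
                         targetCensoring = 0.75, seed = 7L)
  task <- generateSyntheticTask(cfg, 1L)
  expect_lt(abs(mean(1 - survEvent(task$dataset)) - 0.75), 0.03)
  # the calibrated rate solves the analytic censoring probability
  eta <- task$truth$eta
  lam <- cfg$baselineRate * exp(eta)
  expect_equal(mean(task$censorRate / (task$censorRate + lam)), 0.75,
               tolerance = 1e-8)
  expect_error(calibrateCensoringRate(c(0, 0), 1, 1 + 1e-9), "unreachable")
})

test_that("a null risk coefficient gives chance-level concordance", {
  cfg <- syntheticConfig(nPerTask = 2000L, nTasks = 2L,
                         riskCoef = rep(0, 10), taskPerturbationSd = 0,
                         seed = 8L)
  task <- generateSyntheticTask(cfg, 1L)
  set.seed(9)
  randomScores <- rnorm(2000)
  ci <- concordanceIndex(randomScores, survTime(task$dataset),
                         survEvent(task$dataset))
  expect_lt(abs(ci - 0.5), 0.05)
})

test_that("event and censoring times are empirically independent", {
  cfg <- syntheticConfig(nPerTask = 10000L, nTasks = 2L,
                         riskCoef = rep(0, 10), taskPerturbationSd = 0,
                         seed = 10L)
  task <- generateSyntheticTask(cfg, 1L)
  expect_lt(abs(cor(task$truth$eventTime, task$truth$censorTime)), 0.03)
})

test_that("top-decile risk samples die sooner than bottom-decile ones", {
  cfg <- syntheticConfig(nPerTask = 2000L, nTasks = 2L, seed = 11L)
  task <- generateSyntheticTask(cfg, 1L)
  tr <- task$truth
  hi <- tr$eta >= quantile(tr$eta, 0.9)
  lo <- tr$eta <= quantile(tr$eta, 0.1)
  expect_lt(mean(tr$eventTime[hi]), mean(tr$eventTime[lo]))
})

test_that("the true linear predictor is near-optimal (oracle dominance)", {
  cfg <- syntheticConfig(nPerTask = 2000L, nTasks = 2L, seed = 12L)
  fam <- generateFamily(cfg)
  d <- fam$target$dataset
  etaCI <- concordanceIndex(fam$target$truth$eta, survTime(d), survEvent(d))
  # an independently simulated instance of the same family gives the same
  # oracle concordance up to Monte-Carlo error
  cfg2 <- cfg; cfg2$seed <- 131L
  fam2 <- generateFamily(cfg2)
  d2 <- fam2$target$dataset
  etaCI2 <- concordanceIndex(fam2$target$truth$eta, survTime(d2),
                             survEvent(d2))
  expect_lt(abs(etaCI - etaCI2), 0.05)
  # any fitted model is at most marginally better than the truth
  gene <- omicsViews(d)$gene
  fit <- survival::coxph(survival::Surv(survTime(d), survEvent(d)) ~ .,
                         data = as.data.frame(gene[, 1:20]))
  fitted <- drop(as.matrix(as.data.frame(gene[, 1:20])) %*% coef(fit))
  fittedCI <- concordanceIndex(fitted, survTime(d), survEvent(d))
  expect_gte(etaCI, fittedCI - 0.02)
})

test_that("families are deterministic, share loadings and keep the target out of the pool", {
  cfg <- syntheticConfig(latentDim = 4L, p1 = 10L, p2 = 6L, nPerTask = 50L,
                         nTasks = 3L, seed = 13L)
  famA <- generateFamily(cfg)
  famB <- generateFamily(cfg)
  expect_identical(famA$loadings, famB$loadings)
  expect_identical(omicsViews(famA$target$dataset),
                   omicsViews(famB$target$dataset))
  expect_identical(length(famA$pool), 2L)
  poolIds <- unlist(lapply(famA$pool, function(t) sampleIds(t$dataset)))
  expect_length(intersect(poolIds, sampleIds(famA$target$dataset)), 0)
  # zero task perturbation -> identical risk coefficients across tasks
  cfg0 <- syntheticConfig(latentDim = 4L, p1 = 10L, p2 = 6L, nPerTask = 50L,
                          nTasks = 3L, taskPerturbationSd = 0, seed = 13L)
  fam0 <- generateFamily(cfg0)
  expect_identical(fam0$pool[[1]]$riskCoef, fam0$target$riskCoef)
})

test_that("complementary view loadings occupy disjoint latent coordinates", {
  cfg <- syntheticConfig(latentDim = 6L, p1 = 10L, p2 = 8L, nPerTask = 30L,
                         nTasks = 2L, viewLatentCoords = list(1:3, 4:6),
                         seed = 14L)
  fam <- generateFamily(cfg)
  expect_identical(unname(rowSums(abs(fam$loadings$W1)) > 0),
                   c(rep(TRUE, 3), rep(FALSE, 3)))
  expect_identical(unname(rowSums(abs(fam$loadings$W2)) > 0),
                   c(rep(FALSE, 3), rep(TRUE, 3)))
})

test_that("synthetic tasks round-trip through the plain-text file layout", {
  cfg <- syntheticConfig(latentDim = 3L, p1 = 6L, p2 = 4L, nPerTask = 25L,
                         nTasks = 2L, seed = 15L)
  task <- generateSyntheticTask(cfg, 1L)
  dir <- tempfile()
  writeSyntheticTask(task, dir, "target")
  gene <- readExpressionMatrix(file.path(dir, "target_gene.tsv"),
                               omicsName = "gene")
  surv <- readSurvivalTable(file.path(dir, "target_survival.tsv"))
  expect_equal(omicsValues(gene), omicsViews(task$dataset)$gene,
               tolerance = 1e-10)
  expect_equal(surv$time, survTime(task$dataset), tolerance = 1e-10)
  expect_identical(surv$event, survEvent(task$dataset))
  truth <- read.delim(file.path(dir, "target_truth.tsv"))
  expect_identical(truth$sample_id, sampleIds(task$dataset))
})
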