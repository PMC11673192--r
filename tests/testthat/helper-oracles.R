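# Independent brute-force oracles and small fixture builders. The oracles
# deliberately use naive enumeration so they share no code path with the
# package implementations they check.

# negative mean log Cox partial likelihood by explicit risk-set enumeration
bruteCoxLoss <- function(h, time, event, rule = c("geq", "gt")) {
  rule <- match.arg(rule)
  n <- length(h)
  total <- 0
  for (i in seq_len(n)) {
    if (event[i] != 1) next
    riskSet <- if (rule == "geq") which(time >= time[i])
               else which(time > time[i])
    if (length(riskSet) == 0)
      stop("empty risk set in oracle")
    total <- total + (h[i] - log(sum(exp(h[riskSet]))))
  }
  -total / n
}

# Harrell concordance by explicit pair enumeration
bruteCIndex <- function(h, time, event) {
  num <- 0; den <- 0
  n <- length(h)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    if (time[i] < time[j] && event[i] == 1) {
      den <- den + 1
      if (h[i] > h[j]) num <- num + 1
      else if (h[i] == h[j]) num <- num + 0.5
    }
  }
  if (den == 0) stop("no comparable pairs in oracle")
  num / den
}

# case/control pair rate at a horizon, valid when censoring is absent
bruteAUCNoCensoring <- function(h, time, horizon) {
  cases <- which(time <= horizon)
  controls <- which(time > horizon)
  num <- 0
  for (i in cases) for (j in controls) {
    if (h[i] > h[j]) num <- num + 1
    else if (h[i] == h[j]) num <- num + 0.5
  }
  num / (length(cases) * length(controls))
}

# central finite differences on a flat parameter vector
numericGradient <- function(f, vec, eps = 1e-5) {
  g <- numeric(length(vec))
  for (i in seq_along(vec)) {
    vp <- vec; vp[i] <- vp[i] + eps
    vm <- vec; vm[i] <- vm[i] - eps
    g[i] <- (f(vp) - f(vm)) / (2 * eps)
  }
  g
}

relativeError <- function(a, b) {
  sqrt(sum((a - b)^2)) / (sqrt(sum(a^2)) + sqrt(sum(b^2)) + 1e-300)
}

# small random multi-omics dataset with valid survival outcomes
makeTinyData <- function(n = 8, pGene = 6, pMirna = 4, seed = 1,
                         pEvent = 0.6) {
  set.seed(seed)
  ids <- sprintf("s%02d", seq_len(n))
  gene <- matrix(rnorm(n * pGene), n, pGene,
                 dimnames = list(ids, paste0("g", seq_len(pGene))))
  mirna <- matrix(rnorm(n * pMirna), n, pMirna,
                  dimnames = list(ids, paste0("m", seq_len(pMirna))))
  event <- rbinom(n, 1, pEvent)
  if (all(event == 0)) event[1] <- 1L
  multiOmicsSurvData(list(gene = gene, mirna = mirna),
                     time = rexp(n) + 0.1, event = event)
}

tinyModelConfig <- function(pGene = 6, pMirna = 4, ...) {
  survModelConfig(c(gene = pGene, mirna = pMirna), nLayers = 2L,
                  embedDim = 5L, ...)
}
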