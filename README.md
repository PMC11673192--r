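# momsurv

Few-shot multi-omics survival prediction via meta-learned deep Cox models.

## The problem

Predicting patient survival for a rare cancer means fitting a model from
10–20 patients, each described by high-dimensional multi-omics profiles
(gene expression and miRNA expression). Direct fitting overfits; `momsurv`
instead meta-learns a parameter initialization for a deep Cox model across
tasks sampled from abundant *related* cohorts, then adapts it to the
target cohort with a few gradient steps.

## The model

Per-omics 5-layer highway encoders map each view into a shared
80-dimensional embedding space. Training minimizes

```
l(phi, beta) = l_cox(beta) + w * l_sim(phi)
```

where `l_cox` is the negative mean log Cox partial likelihood of the fused
embedding `z_i = (z_i^1 + z_i^2)/2` scored by a risk head `h_beta`
(Breslow-style risk sets, log-sum-exp stabilized), and `l_sim` is a
margin-based hinge on cosine similarities demanding that same-patient
cross-omics embedding pairs be more similar than cross-patient pairs by a
margin `M`. The initialization is learned with first-order Reptile: per
meta-iteration, `m` censoring-stratified task batches are adapted with `k`
full-batch gradient steps each, and the initialization moves along the
mean parameter displacement (Adam on the pseudo-gradient). Fine-tuning on
the few-shot draw is plain full-batch gradient descent.

The package also implements the standard comparison schemes over the same
model (direct learning, pretraining + fine-tune, multitask learning,
single-omics meta-learning, a no-similarity ablation), Harrell's C-index
and IPCW time-dependent AUC, a replicated paired few-shot benchmark
protocol, TCGA-style expression-matrix preprocessing, and a synthetic
generator for families of related multi-omics survival tasks with known
ground truth, so everything is testable without external downloads.

## Worked example

```r
library(momsurv)

# a synthetic family: 3 related pool cohorts + 1 held-out target,
# two omics views driven by shared latent factors, 60% censoring
syn <- syntheticConfig(nTasks = 4L, nPerTask = 200L, seed = 42L)
fam <- generateFamily(syn)
pool <- lapply(fam$pool, `[[`, "dataset")
target <- fam$target$dataset
target
#> MultiOmicsSurvData: 200 samples, 2 views
#>   - gene: 500 features
#>   - mirna: 100 features
#>   events: 84 observed, 116 censored

mcfg <- survModelConfig(c(gene = 500L, mirna = 100L))
metaCfg <- metaConfig(metaIterations = 40L, taskSize = 50L)
res <- runBenchmark(pool, target, c("direct", "mmosurv"), mcfg, metaCfg,
                    nDraws = 3L, nRepeats = 1L, shots = 10L, seed = 1L)
summarizeBenchmark(res)$overall
#>    scheme   c_index       auc
#> 1  direct 0.6253165 0.6437190
#> 2 mmosurv 0.8118143 0.8674205
```

Both schemes see the *same* three 10-patient training draws and are scored
on the same held-out 20% test split. Direct learning from a random
initialization reaches C-index 0.63; meta-learning the initialization from
the three related cohorts first, then fine-tuning on the same 10 patients,
reaches 0.81 (1.0 = perfect ranking of survival times, 0.5 = random).

File-based data enter through `readExpressionMatrix()` (either
orientation), `readSurvivalTable()` and `preprocessOmics()` (missing-value
filter, median imputation, log2, variance filter, z-scoring with pooled
statistics). A thin command-line dispatcher with `simulate`, `meta-train`,
`benchmark` and `preprocess` subcommands lives at `inst/scripts/momsurv`;
each command echoes its YAML configuration and seed into the output
directory and reproduces its outputs byte-identically from that echo.

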