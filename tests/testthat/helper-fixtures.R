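## Shared fixtures, built in code. The trained model is expensive (~2-3 min)
## and is computed once per test run on first use.

.fixtureCache <- new.env(parent = emptyenv())

## Standard synthetic fixture: 6 categories x 2 phenotypes x 2 datasets x
## 50 cells, N = 500 genes, planted markers (generator defaults).
standardFixture <- function() {
  if (is.null(.fixtureCache$sim))
    .fixtureCache$sim <- generatePotencyDataset(simulationConfig(seed = 11))
  .fixtureCache$sim
}

## Single model trained on dataset ds1 of the standard fixture with the
## default hyperparameters, validated on the held-out dataset ds2.
trainedFixture <- function() {
  if (is.null(.fixtureCache$fit)) {
    sim <- standardFixture()
    X <- exprValues(sim$expression)
    tr <- sim$labels$dataset == "ds1"
    Htr <- dualRepresentation(X[, tr])
    Hval <- dualRepresentation(X[, !tr])
    model <- trainModel(Htr, sim$labels[tr, ], Hval, sim$labels[!tr, ],
                        hp = gsbnHyperparameters(), seed = 5)
    .fixtureCache$fit <- list(model = model, Htr = Htr, Hval = Hval,
                              trainLabels = sim$labels[tr, ],
                              valLabels = sim$labels[!tr, ], sim = sim)
  }
  .fixtureCache$fit
}

## Small deterministic harmonized input for forward-pass tests.
tinyHarmonized <- function(N = 40, C = 12, seed = 7) {
  withr::with_seed(seed, {
    X <- matrix(rpois(N * C, 30), N, C,
                dimnames = list(sprintf("g%03d", seq_len(N)),
                                sprintf("c%03d", seq_len(C))))
    dualRepresentation(X)
  })
}

## Hand-built fitted model on a tiny feature space (no training involved):
## module p gets a positive enrichment weight on gene set 1 whose genes are
## the p-th block of features, so predictions are analytically controlled.
tinyModel <- function(N = 40, M = 2, seed = 3) {
  withr::with_seed(seed, {
    bg <- buildBackgroundMap(rnorm(N), nBins = 4, nSample = 3, seed = 1)
    modules <- lapply(seq_len(6), function(p) {
      W <- matrix(-1, N, M, dimnames = list(sprintf("g%03d", seq_len(N)),
                                            NULL))
      block <- ((p - 1) * 5 + 1):(p * 5)
      W[block, 1] <- 1
      W[sample.int(N, 4), 2] <- 1
      GSBNModule(W = W, tauM = -0.5, V = c(1, 0.1, 1, 0.1),
                 bias = 0, normMean = rep(0, 2 * M),
                 normVar = rep(1, 2 * M), fitted = TRUE)
    })
    CoreModel(modules, bg, sprintf("g%03d", seq_len(N)))
  })
}

## Independent scalar-loop oracle for the rank-based enrichment score.
ucellOracle <- function(ranks, setIdx, tau) {
  S <- length(setIdx)
  tsum <- sum(pmin(ranks[setIdx], tau))
  1 + (S * (S + 1) - 2 * tsum) / (2 * tau * S)
}

## O(n^2) pair-count oracle for weighted Kendall tau-b.
kendallOracle <- function(x, y, w) {
  num <- 0; dx <- 0; dy <- 0
  n <- length(x)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    wij <- w[i] * w[j]
    sx <- sign(x[i] - x[j]); sy <- sign(y[i] - y[j])
    num <- num + wij * sx * sy
    if (sx != 0) dx <- dx + wij
    if (sy != 0) dy <- dy + wij
  }
  num / sqrt(dx * dy)
}

## Confusion-matrix oracle for mean multiclass F1 and per-category MAE.
f1Oracle <- function(pred, truth) {
  cats <- unique(truth)
  mean(vapply(cats, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 1))
}

maeOracle <- function(predIdx, truthIdx) {
  mean(vapply(unique(truthIdx), function(t)
    mean(abs(predIdx[truthIdx == t] - t)), 1))
}

## minimal permutation generator used by the enumeration oracle
combinat_perms <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- combinat_perms(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}
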