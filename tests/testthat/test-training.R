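test_that("hierarchical loss weights balance the label hierarchy", {
  lab <- data.frame(cell_id = paste0("c", 1:4),
                    broad_category = rep(c("Differentiated", "Pluripotent"),
                                         each = 2),
                    phenotype = rep(c("f1", "f2"), each = 2),
                    dataset = "d1")
  expect_equal(hierarchicalLossWeights(lab), rep(0.25, 4))

  ## category A: 2 phenotypes, category B: 1 -> B's phenotype carries 0.5
  lab2 <- data.frame(cell_id = paste0("c", 1:6),
                     broad_category = c(rep("Unipotent", 4),
                                        rep("Totipotent", 2)),
                     phenotype = c("a1", "a1", "a2", "a2", "b1", "b1"),
                     dataset = "d1")
  w <- hierarchicalLossWeights(lab2)
  expect_equal(sum(w[5:6]), 0.5)
  expect_equal(sum(w[1:2]), 0.25)
  expect_equal(sum(w[3:4]), 0.25)

  ## unit sum for random hierarchies
  withr::local_seed(8)
  for (rep in 1:10) {
    n <- 50
    lab3 <- data.frame(cell_id = seq_len(n),
                       broad_category = sample(potencyCategories(), n, TRUE),
                       phenotype = sample(letters[1:5], n, TRUE),
                       dataset = sample(c("d1", "d2", "d3"), n, TRUE))
    expect_equal(sum(hierarchicalLossWeights(lab3)), 1)
  }
})

test_that("prediction loss follows the weighted cross-entropy form", {
  ## near-one-hot logits drive the loss to zero
  Q <- matrix(-50, 4, 6)
  y <- c(1, 3, 5, 6)
  Q[cbind(1:4, y)] <- 50
  v <- rep(0.25, 4)
  expect_lt(predictionLoss(Q, y, v), 1e-8)

  ## uniform likelihoods with unit-sum weights give ln 6
  expect_equal(predictionLoss(matrix(0, 3, 6), c(2, 4, 6), rep(1 / 3, 3)),
               log(6))
  ## linearity in the weights
  Q2 <- matrix(rnorm(18), 3)
  expect_equal(predictionLoss(Q2, c(1, 2, 3), 2 * rep(1 / 3, 3)),
               2 * predictionLoss(Q2, c(1, 2, 3), rep(1 / 3, 3)))
  expect_error(predictionLoss(Q2, c(1, 2, 9), rep(1, 3)), "1..6")
})

test_that("gene-set size penalty matches the scaled Frobenius form", {
  ## single module, one set of 10 genes among 100, lambda 0.01:
  ## a = sqrt(12), diagonal entry S/N = 0.1 -> J_S = sqrt(12) * 0.01 * 0.1
  WB <- matrix(0, 100, 1); WB[1:10, 1] <- 1
  expect_equal(geneSetSizePenalty(list(WB), 0.01, M = 1, N = 100),
               sqrt(12) * 0.01 * 0.1)
  expect_equal(geneSetSizePenalty(list(WB), 0.01, M = 1, N = 100),
               0.0034641, tolerance = 1e-5)

  expect_equal(geneSetSizePenalty(list(matrix(0, 50, 3)), 0.1, 3, 50), 0)

  ## the sqrt(12)/sqrt(M) factor makes equal-sized sets M-invariant
  js <- vapply(c(1, 12, 24), function(M) {
    WBm <- matrix(0, 120, M); WBm[1:8, ] <- 1
    geneSetSizePenalty(list(WBm), 0.01, M, 120)
  }, 1)
  expect_equal(js[1], js[2])
  expect_equal(js[2], js[3])
})

test_that("initialization is sparse, scaled and reproducible", {
  hp <- gsbnHyperparameters()
  ## positive fraction matches the Gaussian tail at the default mean/sd
  W <- initializeSelectionWeights(20000, 3, hp, seed = 2)
  pPos <- pnorm(0, hp$init_mean, hp$init_sd, lower.tail = FALSE)
  expect_equal(mean(colSums(W > 0)) / 20000, pPos, tolerance = 0.05)

  ## degenerate limit: sd -> 0 with negative mean selects nothing
  W0 <- initializeSelectionWeights(500, 2,
                                   gsbnHyperparameters(init_sd = 1e-12),
                                   seed = 1)
  expect_true(all(binarizeWeights(W0) == 0))

  expect_identical(initializeSelectionWeights(100, 4, hp, seed = 9),
                   initializeSelectionWeights(100, 4, hp, seed = 9))

  withr::local_seed(3)
  bg <- buildBackgroundMap(rnorm(60), nBins = 3, nSample = 5, seed = 1)
  m1 <- initializeModel(gsbnHyperparameters(M = 4), 60, 7, bg)
  m2 <- initializeModel(gsbnHyperparameters(M = 4), 60, 7, bg)
  expect_identical(m1@modules[[3]]@W, m2@modules[[3]]@W)
  expect_true(all(vapply(m1@modules, function(m)
    m@tauM >= 0 && m@tauM <= 1, TRUE)))
})

test_that("straight-through estimator masks outside the hardtanh region", {
  W <- matrix(c(0.5, 1.5, -0.2, -1.01), 2)
  g <- matrix(c(1, 2, 3, 4), 2)
  expect_equal(steBackward(g, W), matrix(c(1, 0, 3, 0), 2))
  expect_equal(steBackward(g * 0, W), matrix(0, 2, 2))
})

test_that("module gradients match central finite differences", {
  ## continuous relaxation of the binary weights; smooth unrounded tau
  mfr <- scPotency:::moduleForwardRaw
  mbw <- scPotency:::moduleBackward
  rsm <- scPotency:::rowSoftmax
  withr::local_seed(42)
  N <- 24; cc <- 6; M <- 2
  L <- matrix(abs(rnorm(N * cc, 2, 1)), N, cc)
  R <- apply(matrix(rnorm(N * cc), N, cc), 2,
             function(x) rank(-x, ties.method = "first"))
  bg <- buildBackgroundMap(rnorm(N), nBins = 3, nSample = 3, seed = 7)
  WB <- matrix(runif(N * M, 0.2, 0.9), N, M)
  V <- rnorm(2 * M, 0, 0.3); bias <- 0.1; tauM <- 0.0123
  y <- sample(1:6, cc, TRUE); vb <- runif(cc); vb <- vb / sum(vb)
  lambda <- 0.01

  lossFun <- function(WB, tauM, V, bias) {
    S <- colSums(WB)
    tau <- 10 + max(S) + 1000 * max(0, tauM)
    fw <- mfr(WB, tau, V, bias, L, pmin(R, tau), NULL, mode = "train",
              bg = bg)
    Q <- matrix(0, cc, 6); Q[, 1] <- fw$q
    P <- rsm(Q)
    sum(vb * -log(P[cbind(1:cc, y)])) +
      lambda * sqrt(12) / sqrt(M) * sqrt(sum((S / N)^2))
  }
  S <- colSums(WB); tau <- 10 + max(S) + 1000 * max(0, tauM)
  fw <- mfr(WB, tau, V, bias, L, pmin(R, tau), NULL, mode = "train",
            bg = bg)
  Q <- matrix(0, cc, 6); Q[, 1] <- fw$q
  P <- rsm(Q)
  dQ <- P * vb; dQ[cbind(1:cc, y)] <- dQ[cbind(1:cc, y)] - vb
  gr <- mbw(fw, dQ[, 1], WB, WB * 0, tauM, V, L, pmin(R, tau), R, bg,
            lambda)

  fd <- function(f, h = 1e-6) (f(h) - f(-h)) / (2 * h)
  for (probe in list(c(1, 1), c(5, 2), c(24, 1), c(13, 2))) {
    i <- probe[1]; j <- probe[2]
    num <- fd(function(e) {
      W2 <- WB; W2[i, j] <- W2[i, j] + e; lossFun(W2, tauM, V, bias)
    })
    expect_equal(gr$dWB[i, j], num, tolerance = 1e-6)
  }
  expect_equal(gr$dtauM,
               fd(function(e) lossFun(WB, tauM + e, V, bias)),
               tolerance = 1e-6)
  for (s in 1:(2 * M))
    expect_equal(gr$dV[s], fd(function(e) {
      V2 <- V; V2[s] <- V2[s] + e; lossFun(WB, tauM, V2, bias)
    }), tolerance = 1e-6)
  expect_equal(gr$dbias,
               fd(function(e) lossFun(WB, tauM, V, bias + e)),
               tolerance = 1e-6)
})

test_that("the balanced sampler equalizes phenotype representation", {
  lab <- data.frame(cell_id = seq_len(1000),
                    broad_category = "Unipotent",
                    phenotype = rep(c("rare", "common"), c(10, 990)),
                    dataset = "d1")
  nxt <- makeSampler(lab, batchSize = 600, seed = 3)
  idx <- c(nxt(), nxt(), nxt())
  frac <- mean(lab$phenotype[idx] == "rare")
  expect_gt(frac, 0.4); expect_lt(frac, 0.6)

  ## single phenotype: uniform over cells; fixed seed reproduces batches
  lab2 <- data.frame(cell_id = 1:50, broad_category = "Totipotent",
                     phenotype = "p", dataset = "d")
  a <- makeSampler(lab2, 20, seed = 5)
  b <- makeSampler(lab2, 20, seed = 5)
  expect_identical(a(), b())
  expect_identical(a(), b())
})

test_that("weighted accuracy aggregates F1 across the hierarchy", {
  lab <- data.frame(cell_id = 1:10,
                    broad_category = "Multipotent",
                    phenotype = rep(c("f1", "f2"), c(3, 7)),
                    dataset = "d1")
  ## F1 = 0.8 needs 2/3 recalled; F1 = 0.6 needs 3/7
  pred <- c(rep("Multipotent", 2), "Unipotent",
            rep("Multipotent", 3), rep("Oligopotent", 4))
  expect_equal(weightedAccuracy(pred, lab), 0.7)
  expect_equal(weightedAccuracy(rep("Multipotent", 10), lab), 1)
  expect_equal(weightedAccuracy(rep("Totipotent", 10), lab), 0)
})

test_that("training behaves as a null op at zero learning rate", {
  sim <- generatePotencyDataset(
    simulationConfig(n_genes = 200, phenotypes_per_category = 1,
                     cells_per_phenotype = 10, seed = 2))
  X <- exprValues(sim$expression)
  tr <- sim$labels$dataset == "ds1"
  Htr <- dualRepresentation(X[, tr]); Hval <- dualRepresentation(X[, !tr])
  hp <- gsbnHyperparameters(M = 4, lr = 0, max_epochs = 2,
                            min_epochs_before_stop = 1, rho = 0)
  fit <- trainModel(Htr, sim$labels[tr, ], Hval, sim$labels[!tr, ],
                    hp = hp, seed = 4)
  init <- initializeModel(hp, 200, scPotency:::deriveSeed(4, 1L),
                          fit@background, featureNames = rownames(Htr))
  expect_identical(fit@modules[[2]]@W, init@modules[[2]]@W)
  expect_identical(fit@modules[[5]]@V, init@modules[[5]]@V)
})

test_that("training is seed-deterministic and reduces the loss", {
  sim <- generatePotencyDataset(
    simulationConfig(n_genes = 200, phenotypes_per_category = 1,
                     cells_per_phenotype = 15, seed = 6))
  X <- exprValues(sim$expression)
  tr <- sim$labels$dataset == "ds1"
  Htr <- dualRepresentation(X[, tr]); Hval <- dualRepresentation(X[, !tr])
  hp <- gsbnHyperparameters(M = 4, max_epochs = 20,
                            min_epochs_before_stop = 5)
  f1 <- trainModel(Htr, sim$labels[tr, ], Hval, sim$labels[!tr, ],
                   hp = hp, seed = 12)
  f2 <- trainModel(Htr, sim$labels[tr, ], Hval, sim$labels[!tr, ],
                   hp = hp, seed = 12)
  for (p in 1:6)
    expect_identical(f1@modules[[p]]@W, f2@modules[[p]]@W)
  expect_identical(attr(f1, "history"), attr(f2, "history"))

  h <- attr(f1, "history")$loss
  expect_lt(mean(utils::tail(h, 5)), mean(utils::head(h, 5)))
})

test_that("ensembling averages likelihoods entrywise", {
  H <- tinyHarmonized()
  m <- tinyModel()
  single <- ensemblePredict(EnsembleModel(list(m)), H)
  direct <- coreForward(m, H, mode = "infer")$prediction
  expect_identical(single@P, direct@P)
  expect_identical(single@yHat, direct@yHat)

  m2 <- tinyModel(seed = 8)
  ens <- ensemblePredict(list(m, m2), H)
  p2 <- coreForward(m2, H, mode = "infer")$prediction
  expect_equal(ens@P, (direct@P + p2@P) / 2)
  expect_equal(unname(rowSums(ens@P)), rep(1, ncol(H)), tolerance = 1e-9)

  ## two one-hot rows average to 0.5/0.5 with RPS 0.1
  Pa <- matrix(0, 1, 6); Pa[1, 1] <- 1
  Pb <- matrix(0, 1, 6); Pb[1, 2] <- 1
  expect_equal(rawPotencyScore((Pa + Pb) / 2), 0.1)
})
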