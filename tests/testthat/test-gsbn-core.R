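test_that("rank trimming and binarization follow their piecewise rules", {
  expect_equal(trimRanks(matrix(c(7, 3), 1), 5), matrix(c(5, 3), 1))
  R <- matrix(1:6, 2)
  expect_equal(trimRanks(R, 10), R)               # tau >= N is identity

  expect_equal(binarizeWeights(c(-0.1, 0, 0.2)), c(0, 0, 1))
  W <- matrix(-abs(rnorm(12)), 4)
  expect_true(all(binarizeWeights(W) == 0))       # all-negative column
  B <- binarizeWeights(matrix(rnorm(20), 4))
  expect_identical(binarizeWeights(B), B)         # idempotent on {0,1}
})

test_that("tau is computed from the learnable parameter and set sizes", {
  expect_identical(computeTau(-0.3, c(500, 40)), 510L)
  expect_identical(computeTau(0.5, c(500, 40)), 1010L)
  expect_identical(computeTau(0, numeric(0)), 10L)
  expect_identical(computeTau(0, c(0, 0)), 10L)
})

test_that("rank-based score matches its closed forms", {
  N <- 10
  ## set occupying the top S ranks scores exactly 1
  R <- matrix(1:N, N)
  WB <- matrix(0, N, 1); WB[1:3, 1] <- 1
  tau <- computeTau(-1, colSums(WB))
  expect_equal(as.vector(ucellScore(trimRanks(R, tau), WB, tau)), 1)

  ## printed worked example: S = 2, tau = 5, trimmed ranks {3, 5}
  T <- matrix(c(3, 5, 1, 2, 4, rep(5, 5)), N)
  WB2 <- matrix(0, N, 1); WB2[1:2, 1] <- 1
  expect_equal(as.vector(ucellScore(T, WB2, 5)), 0.5)

  ## all set genes trimmed at tau attains the minimum (S + 1) / (2 tau)
  S <- 3; tau <- 7
  Tmin <- matrix(tau, N)
  WB3 <- matrix(0, N, 1); WB3[c(2, 5, 9), 1] <- 1
  expect_equal(as.vector(ucellScore(Tmin, WB3, tau)), (S + 1) / (2 * tau))

  expect_error(ucellScore(T, matrix(0, N, 1), 5), "empty")
})

test_that("rank-based score agrees with brute-force enumeration", {
  ## all rank assignments (permutations) at small N, all sets of size <= 3,
  ## against the independent scalar-loop oracle, including trimming
  for (N in c(4, 5)) {
    perms <- combinat_perms(N)
    sets <- unlist(lapply(1:3, function(S)
      utils::combn(N, S, simplify = FALSE)), recursive = FALSE)
    for (tau in c(3, N + 10)) {
      for (si in sets) {
        WB <- matrix(0, N, 1); WB[si, 1] <- 1
        S <- length(si)
        lo <- (S + 1) / (2 * tau)
        for (k in seq_len(nrow(perms))) {
          r <- perms[k, ]
          got <- ucellScore(trimRanks(matrix(r, N), tau), WB, tau)[1, 1]
          expect_equal(got, ucellOracle(r, si, tau), tolerance = 1e-12)
          if (tau > N) expect_true(got >= lo - 1e-12 && got <= 1 + 1e-12)
        }
      }
    }
  }
})

test_that("lowering a set gene's trimmed rank strictly increases the score", {
  withr::local_seed(4)
  N <- 12; tau <- 8
  for (rep in 1:20) {
    r <- sample(N)
    si <- sample(N, 3)
    WB <- matrix(0, N, 1); WB[si, 1] <- 1
    T <- trimRanks(matrix(r, N), tau)
    g <- si[which(T[si, 1] > 1)[1]]
    if (is.na(g)) next
    T2 <- T; T2[g, 1] <- T2[g, 1] - 1
    expect_gt(ucellScore(T2, WB, tau)[1, 1], ucellScore(T, WB, tau)[1, 1])
  }
})

test_that("background-subtracted score has its analytic fixed points", {
  withr::local_seed(9)
  N <- 30
  bg <- buildBackgroundMap(rnorm(N), nBins = 3, nSample = 4, seed = 2)
  WB <- matrix(0, N, 2); WB[1:4, 1] <- 1; WB[5:10, 2] <- 1

  ## constant expression across genes cancels exactly
  L <- matrix(3, N, 5)
  expect_equal(amsScore(L, WB, bg), matrix(0, 5, 2), ignore_attr = TRUE)

  ## set genes at 2 and all their background genes at 1 score exactly 1:
  ## one set gene per expression bin, so backgrounds never hit set genes
  bgSeq <- buildBackgroundMap(seq_len(N), nBins = 3, nSample = 4, seed = 2)
  set <- c(1, 11, 21)
  WBd <- matrix(0, N, 1); WBd[set, 1] <- 1
  bgGenes <- which(Matrix::colSums(bgSeq@B[set, , drop = FALSE]) > 0)
  expect_length(intersect(set, bgGenes), 0)
  L2 <- matrix(0, N, 1); L2[bgGenes, 1] <- 1; L2[set, 1] <- 2
  expect_equal(as.vector(amsScore(L2, WBd, bgSeq)), 1)

  ## homogeneity and per-cell shift invariance
  L3 <- matrix(abs(rnorm(N * 4, 2)), N, 4)
  expect_equal(amsScore(2 * L3, WB, bg), 2 * amsScore(L3, WB, bg))
  expect_equal(amsScore(L3 + 5, WB, bg), amsScore(L3, WB, bg))
})

test_that("background genes share their gene's expression bin", {
  withr::local_seed(13)
  N <- 240
  mu <- rnorm(N)
  bg <- buildBackgroundMap(mu, nBins = 6, nSample = 10, seed = 5)
  ord <- order(mu, seq_len(N))
  bin <- integer(N); bin[ord] <- rep(1:6, each = N / 6)
  Bm <- as.matrix(bg@B)
  for (i in sample(N, 40)) {
    js <- which(Bm[i, ] > 0)
    expect_true(all(bin[js] == bin[i]))
    expect_false(i %in% js)            # self excluded
  }
  ## mean background count concentrates near nSample
  expect_lt(abs(mean(Matrix::rowSums(bg@B)) - 10), 2)
  ## deterministic given seed
  bg2 <- buildBackgroundMap(mu, nBins = 6, nSample = 10, seed = 5)
  expect_identical(as.matrix(bg@B), as.matrix(bg2@B))

  expect_error(buildBackgroundMap(rnorm(6), nBins = 6, nSample = 2), "genes")
  expect_error(buildBackgroundMap(rnorm(40), nBins = 4, nSample = 50),
               "smaller nSample")
})

test_that("score standardization distinguishes train and inference modes", {
  withr::local_seed(5)
  K <- matrix(rnorm(60, 4, 3), 20, 3)
  tr <- normalizeScores(K, mode = "train")
  expect_equal(unname(colMeans(tr$scores)), rep(0, 3), tolerance = 1e-10)
  expect_equal(unname(apply(tr$scores, 2, function(x) mean(x^2))),
               rep(1, 3), tolerance = 1e-2)   # biased variance + eps guard

  st <- list(mean = c(2, 0, 0), var = c(4, 1, 1), fitted = TRUE)
  inf <- normalizeScores(matrix(4, 1, 3), stats = st, mode = "infer",
                         eps = 0)
  expect_equal(inf$scores[1, 1], 1)            # (4 - 2) / 2
  expect_identical(inf$stats, st)              # no update at inference

  cst <- normalizeScores(matrix(7, 5, 1), mode = "train")
  expect_true(all(is.finite(cst$scores)))      # constant column guarded
  expect_error(normalizeScores(K, mode = "infer"), "fitted")
})

test_that("forward pass yields stochastic likelihoods and anchored scores", {
  H <- tinyHarmonized()
  model <- tinyModel()
  out <- coreForward(model, H, mode = "infer")
  expect_equal(unname(rowSums(out$prediction@P)), rep(1, ncol(H)),
               tolerance = 1e-9)
  expect_true(all(out$prediction@RPS >= 0 & out$prediction@RPS <= 1))
  expect_identical(as.character(out$prediction@yHat),
                   potencyCategories()[max.col(out$prediction@P)])

  ## inference is bitwise deterministic
  out2 <- coreForward(model, H, mode = "infer")
  expect_identical(out$prediction@P, out2$prediction@P)

  ## raw potency score anchors
  oneHot <- function(j) { P <- matrix(0, 1, 6); P[1, j] <- 1; P }
  expect_equal(rawPotencyScore(oneHot(6)), 1.0)
  expect_equal(rawPotencyScore(oneHot(1)), 0.0)
  expect_equal(rawPotencyScore(matrix(1 / 6, 1, 6)), 0.5)
})

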