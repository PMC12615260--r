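test_that("the generator produces a balanced, reproducible hierarchy", {
  cfg <- simulationConfig(n_genes = 200, phenotypes_per_category = 1,
                          datasets_per_phenotype = 1,
                          cells_per_phenotype = 100, seed = 4)
  sim <- generatePotencyDataset(cfg)
  expect_equal(ncol(exprValues(sim$expression)), 600L)
  expect_equal(unname(table(sim$labels$broad_category)), rep(100L, 6),
               ignore_attr = TRUE)
  expect_true(all(exprValues(sim$expression) >= 0))
  expect_equal(length(unique(unlist(sim$markers))),
               6 * cfg$markers_per_category)   # disjoint marker programs

  sim2 <- generatePotencyDataset(cfg)
  expect_identical(exprValues(sim$expression), exprValues(sim2$expression))
  expect_identical(sim$labels, sim2$labels)
})

test_that("planted markers are overexpressed in their own category", {
  sim <- generatePotencyDataset(simulationConfig(seed = 9))
  X <- exprValues(sim$expression)
  cpm <- sweep(X, 2, colSums(X), "/") * 1e6
  for (p in c(1, 4, 6)) {
    mk <- sim$markers[[p]]
    own <- sim$labels$broad_category == potencyCategories()[p]
    expect_gt(mean(cpm[mk, own]), 2 * mean(cpm[mk, !own]))
  }
})

test_that("transition matrices follow the Gaussian rank-distance kernel", {
  ## near-zero sigma approaches the identity
  expect_equal(buildTransitionMatrix(1e-3)@P, diag(6), tolerance = 1e-12,
               ignore_attr = TRUE)
  ## sigma = 1, first row diagonal from direct kernel evaluation
  tm <- buildTransitionMatrix(1)
  expect_equal(unname(tm@P[1, 1]),
               1 / sum(exp(-(0:5)^2 / 2)), tolerance = 1e-12)
  expect_equal(unname(tm@P[1, 1]), 0.5703, tolerance = 1e-4)
  ## large sigma approaches the uniform kernel
  expect_equal(buildTransitionMatrix(1e6)@P,
               matrix(1 / 6, 6, 6), tolerance = 1e-9, ignore_attr = TRUE)
  ## row-stochastic and symmetric in rank distance
  for (s in c(0.3, 0.7, 1.5, 4)) {
    P <- buildTransitionMatrix(s)@P
    expect_equal(unname(rowSums(P)), rep(1, 6), tolerance = 1e-12)
    K <- P * rep(rowSums(exp(-outer(1:6, 1:6, "-")^2 / (2 * s^2))),
                 times = 6)  # unnormalized kernel is symmetric
    expect_equal(unname(K), unname(t(K)), tolerance = 1e-9)
  }
  expect_error(buildTransitionMatrix(0), "positive")
})

test_that("sigma calibration hits the requested perturbation level", {
  ## expected perturbed fraction is monotone in sigma
  f <- function(s) 1 - mean(diag(buildTransitionMatrix(s)@P))
  grid <- vapply(seq(0.1, 5, by = 0.1), f, 1)
  expect_true(all(diff(grid) > 0))

  for (target in c(0.05, 0.2, 0.5)) {
    sig <- calibrateSigma(target)
    expect_equal(f(sig), target, tolerance = 1e-4)
  }
  expect_error(calibrateSigma(0.9), "5/6")
  expect_error(calibrateSigma(0), "5/6")
})

test_that("label perturbation respects mode and calibration", {
  withr::local_seed(43)
  phenCats <- sample(potencyCategories(), 60, TRUE)
  labels <- data.frame(cell_id = seq_len(6000),
                       broad_category = rep(phenCats, each = 100),
                       phenotype = rep(sprintf("ph%02d", 1:60), each = 100),
                       dataset = "d1")

  ## near-identity matrix leaves labels unchanged
  tmId <- buildTransitionMatrix(1e-3)
  same <- perturbLabels(labels, tmId, "cell", seed = 2)
  expect_identical(as.character(same$broad_category),
                   as.character(labels$broad_category))

  ## cell mode at the calibrated 20% level
  tm <- buildTransitionMatrix(calibrateSigma(0.2))
  pert <- perturbLabels(labels, tm, "cell", seed = 3)
  frac <- mean(pert$broad_category != labels$broad_category)
  expect_lt(abs(frac - 0.2), 0.03)

  ## phenotype mode: all cells of a phenotype share one draw
  pertPh <- perturbLabels(labels, tm, "phenotype", seed = 4)
  perPh <- tapply(as.character(pertPh$broad_category), labels$phenotype,
                  function(x) length(unique(x)))
  expect_true(all(perPh == 1))
})

test_that("gene-count downsampling keeps the top expressed genes", {
  X <- matrix(c(5, 3, 3, 1), 4, 1,
              dimnames = list(paste0("g", 1:4), "c1"))
  out <- exprValues(downsampleGeneCounts(X, 2, seed = 1))
  expect_equal(sum(out > 0), 2)
  expect_equal(out["g1", 1], 5)          # top gene always kept
  expect_true(out["g2", 1] == 3 || out["g3", 1] == 3)  # seeded tie pick
  expect_identical(exprValues(downsampleGeneCounts(X, 2, seed = 8)),
                   exprValues(downsampleGeneCounts(X, 2, seed = 8)))

  ## g at or above the expressed count is a no-op
  expect_equal(exprValues(downsampleGeneCounts(X, 4)), X)

  withr::local_seed(41)
  Xr <- matrix(rpois(300, 3), 30, 10,
               dimnames = list(sprintf("g%02d", 1:30), sprintf("c%d", 1:10)))
  out2 <- exprValues(downsampleGeneCounts(Xr, 5, seed = 2))
  expect_true(all(colSums(out2 > 0) <= 5))
})

test_that("UMI downsampling conserves totals and expectations", {
  X <- matrix(c(10, 30, 60, 2, 1, 0), 3, 2,
              dimnames = list(paste0("g", 1:3), c("big", "small")))
  out <- exprValues(downsampleUmis(X, 50, seed = 1))
  expect_equal(unname(colSums(out)), c(50, 3))   # min(u, total)
  expect_equal(out[, "small"], X[, "small"])     # below threshold untouched

  ## multinomial expectation: mean count of gene i approaches u * x_i / sum
  reps <- vapply(1:400, function(s)
    exprValues(downsampleUmis(X[, 1, drop = FALSE], 50, seed = s))[, 1],
    numeric(3))
  expect_equal(rowMeans(reps), 50 * X[, 1] / 100, tolerance = 0.05)

  expect_error(downsampleUmis(matrix(0.5, 1, 1,
                                     dimnames = list("g", "c")), 10),
               "integer")
})

test_that("rarity titration subsamples only the chosen phenotype", {
  sim <- generatePotencyDataset(
    simulationConfig(n_genes = 200, phenotypes_per_category = 1,
                     datasets_per_phenotype = 1, cells_per_phenotype = 30,
                     seed = 5))
  lab <- sim$labels
  ph <- lab$phenotype[1]
  out <- titrateRarity(sim$expression, lab, ph, 5, seed = 2)
  expect_equal(sum(out$labels$phenotype == ph), 5L)
  expect_equal(nrow(out$labels), 180L - 25L)
  expect_equal(ncol(exprValues(out$expression)), 155L)

  idemp <- titrateRarity(sim$expression, lab, ph, 30, seed = 2)
  expect_identical(as.matrix(exprValues(idemp$expression)),
                   as.matrix(exprValues(sim$expression)))
  expect_error(titrateRarity(sim$expression, lab, ph, 31), "exceeds")
})
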