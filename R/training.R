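#' Training hyperparameters
#'
#' Defaults follow the tuned configuration: M = 24 gene sets per potency
#' category, dropout rho = 0.5, gene-set-size penalty lambda = 0.01,
#' learning rate 0.001, batch size 1024, up to 100 epochs with early
#' stopping allowed from epoch 15, and sparse Gaussian initialization of
#' the gene-selection weights (mean -0.1, s.d. 0.055).
#'
#' @param M,rho,lambda,lr,batch_size,max_epochs,min_epochs_before_stop
#'   see Description.
#' @param min_batches_per_epoch floor on optimizer steps per epoch. When
#'   the training set is smaller than a few batches, an epoch of
#'   ceiling(C / batch_size) steps would leave the optimizer with far too
#'   few updates to converge; the floor keeps the step count meaningful at
#'   small scale while changing nothing when the data span many batches.
#' @param init_mean,init_sd Gaussian initialization of the continuous
#'   gene-selection weights.
#' @return named list of hyperparameters.
#' @export
gsbnHyperparameters <- function(M = 24, rho = 0.5, lambda = 0.01,
                                lr = 0.001, batch_size = 1024,
                                max_epochs = 100,
                                min_epochs_before_stop = 15,
                                min_batches_per_epoch = 5,
                                init_mean = -0.1, init_sd = 0.055) {
  stopIfNot(rho >= 0 && rho < 1, "rho must lie in [0, 1)")
  stopIfNot(M >= 1 && lr >= 0 && batch_size >= 1 && max_epochs >= 1,
            "hyperparameters must be positive")
  list(M = as.integer(M), rho = rho, lambda = lambda, lr = lr,
       batch_size = as.integer(batch_size),
       max_epochs = as.integer(max_epochs),
       min_epochs_before_stop = as.integer(min_epochs_before_stop),
       min_batches_per_epoch = as.integer(min_batches_per_epoch),
       init_mean = init_mean, init_sd = init_sd)
}

#' Hierarchy-balanced loss weights
#'
#' Assigns each cell the weight 1 / (nCategories x nPhenotypesInCategory x
#' nDatasetsForPhenotype x nCellsInPhenotypeDataset), so every broad
#' potency category carries equal total mass, split equally across its
#' phenotypes and, within a phenotype, across contributing datasets. The
#' vector sums to 1.
#'
#' @param labels label data.frame (see \code{\link{readLabels}}).
#' @return length-C non-negative numeric vector summing to 1.
#' @export
hierarchicalLossWeights <- function(labels) {
  cat <- as.character(labels$broad_category)
  phe <- paste(cat, labels$phenotype, sep = "\r")
  ds <- paste(phe, labels$dataset, sep = "\r")
  nCat <- length(unique(cat))
  phenPerCat <- vapply(split(phe, cat), function(x) length(unique(x)), 1)
  dsPerPhen <- vapply(split(ds, phe), function(x) length(unique(x)), 1)
  cellsPerDs <- table(ds)
  w <- 1 / (nCat * phenPerCat[cat] * dsPerPhen[phe] *
              as.numeric(cellsPerDs[ds]))
  unname(w)
}

#' Weighted cross-entropy prediction loss
#'
#' Sum over cells of v_w * CE(Q_w, y_w), with cross-entropy computed from
#' logits via the log-sum-exp form.
#'
#' @param Q C x 6 logit matrix.
#' @param y true broad categories (factor/character/integer 1..6).
#' @param v per-cell loss weights.
#' @return scalar loss.
#' @export
predictionLoss <- function(Q, y, v) {
  yi <- asCategoryIndex(y)
  stopIfNot(length(yi) == nrow(Q) && length(v) == nrow(Q),
            "Q, y and v must agree in length")
  m <- apply(Q, 1, max)
  lse <- m + log(rowSums(exp(Q - m)))
  ce <- lse - Q[cbind(seq_len(nrow(Q)), yi)]
  sum(v * ce)
}

asCategoryIndex <- function(y) {
  if (is.numeric(y)) {
    stopIfNot(all(y %in% 1:6), "category codes must lie in 1..6")
    return(as.integer(y))
  }
  yi <- match(as.character(y), potencyCategories())
  if (anyNA(yi))
    stop("labels outside the six potency categories: ",
         paste(unique(as.character(y)[is.na(yi)]), collapse = ", "),
         call. = FALSE)
  yi
}

#' Gene-set size penalty
#'
#' J_S = a * lambda * sum_p || (1/N) (W_p^B)' W_p^B elementwise I ||_F with
#' a = sqrt(12)/sqrt(M); the diagonal entries equal S_j / N, so each
#' module contributes sqrt(sum_j (S_j/N)^2).
#'
#' @param WBList list of binary N x M matrices, one per category module.
#' @param lambda penalty weight.
#' @param M gene sets per module.
#' @param N number of features.
#' @return scalar penalty.
#' @export
geneSetSizePenalty <- function(WBList, lambda, M, N) {
  a <- sqrt(12) / sqrt(M)
  total <- sum(vapply(WBList, function(WB) {
    S <- colSums(WB)
    sqrt(sum((S / N)^2))
  }, 1))
  a * lambda * total
}

#' Initialize continuous gene-selection weights
#'
#' Entries are i.i.d. Normal(init_mean, init_sd^2); with the default
#' mean -0.1 and s.d. 0.055 roughly 3.45\% of genes start strictly
#' positive, i.e. about 500 of 14,271 features per gene-set column.
#'
#' @param N number of features.
#' @param M number of gene sets.
#' @param hp hyperparameters (uses \code{init_mean}, \code{init_sd}).
#' @param seed integer seed (optional; caller RNG used when NULL).
#' @return N x M matrix.
#' @export
initializeSelectionWeights <- function(N, M, hp = gsbnHyperparameters(),
                                       seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  matrix(rnorm(N * M, hp$init_mean, hp$init_sd), N, M)
}

#' Initialize a core model
#'
#' Gene-selection weights from the sparse Gaussian scheme, rank-cutoff
#' parameters tauM uniform on [0, 1] per module, enrichment-layer weights
#' from the standard uniform fan-in scheme, biases at zero. Fully
#' reproducible given the seed.
#'
#' @param hp hyperparameters from \code{\link{gsbnHyperparameters}}.
#' @param N number of features.
#' @param seed integer seed.
#' @param background a \linkS4class{BackgroundMap} over the N features.
#' @param featureNames optional feature symbols (generated when NULL).
#' @return An untrained \linkS4class{CoreModel}.
#' @export
initializeModel <- function(hp, N, seed, background, featureNames = NULL) {
  if (is.null(featureNames)) featureNames <- sprintf("feature%05d", seq_len(N))
  withr::local_seed(seed)
  M <- hp$M
  bound <- 1 / sqrt(2 * M)
  modules <- lapply(seq_len(6), function(p) {
    W <- initializeSelectionWeights(N, M, hp)
    rownames(W) <- featureNames
    tauM <- runif(1)
    V <- runif(2 * M, -bound, bound)
    GSBNModule(W = W, tauM = tauM, V = V, bias = 0)
  })
  CoreModel(modules, background, featureNames, dropoutRate = hp$rho)
}

#' Straight-through estimator gradient
#'
#' Passes the gradient with respect to the binary weights through to the
#' continuous weights inside the hardtanh linear region (|W| <= 1) and
#' zeroes it outside.
#'
#' @param grad gradient with respect to the binarized weights.
#' @param W continuous weight matrix of the same shape.
#' @return gradient with respect to \code{W}.
#' @export
steBackward <- function(grad, W) {
  stopIfNot(all(dim(grad) == dim(W)), "shape mismatch")
  grad * (abs(W) <= 1)
}

#' Hierarchy-balanced batch sampler
#'
#' Returns an iterator drawing cells with replacement with probability
#' proportional to their hierarchical loss weights, so phenotypes and
#' datasets are represented equally in expectation regardless of size.
#'
#' @param labels label data.frame.
#' @param batchSize cells per batch.
#' @param seed integer seed; the batch sequence is deterministic.
#' @return function() yielding an integer index vector per call.
#' @export
makeSampler <- function(labels, batchSize, seed = 1) {
  prob <- hierarchicalLossWeights(labels)
  n <- nrow(labels)
  counter <- 0L
  function() {
    counter <<- counter + 1L
    withr::with_seed(deriveSeed(seed, counter),
                     sample.int(n, batchSize, replace = TRUE, prob = prob))
  }
}

#' Hierarchically aggregated validation accuracy
#'
#' F1 of the true category is computed within every (phenotype, dataset)
#' group, then averaged across datasets per phenotype, phenotypes per
#' category and categories, yielding the early-stopping score.
#'
#' @param pred predicted broad categories (factor/character).
#' @param labels label data.frame aligned with \code{pred}.
#' @return scalar in [0, 1].
#' @export
weightedAccuracy <- function(pred, labels) {
  stopIfNot(length(pred) == nrow(labels), "pred and labels disagree")
  pred <- as.character(pred)
  truth <- as.character(labels$broad_category)
  key <- paste(truth, labels$phenotype, labels$dataset, sep = "\r")
  groups <- split(seq_along(pred), key)
  if (length(groups) == 0) stop("no evaluable categories", call. = FALSE)
  f1 <- vapply(groups, function(idx) {
    cls <- truth[idx[1]]
    tp <- sum(pred[idx] == cls)
    if (tp == 0) 0 else 2 * tp / (tp + length(idx))
  }, 1)
  meta <- do.call(rbind, strsplit(names(groups), "\r"))
  perPhen <- vapply(split(f1, paste(meta[, 1], meta[, 2], sep = "\r")),
                    mean, 1)
  phenCat <- vapply(strsplit(names(perPhen), "\r"), `[`, "", 1L)
  perCat <- vapply(split(perPhen, phenCat), mean, 1)
  mean(perCat)
}

## ---------------------------------------------------------------------------
## Backward pass
## ---------------------------------------------------------------------------

## Batch-norm backward (no affine): dKhat -> dK given batch stats.
batchnormBackward <- function(dKhat, K, batchMean, batchVar, eps) {
  n <- nrow(K)
  denom <- sqrt(batchVar + eps)
  xhat <- sweep(sweep(K, 2, batchMean, "-"), 2, denom, "/")
  s1 <- colSums(dKhat)
  s2 <- colSums(dKhat * xhat)
  (sweep(dKhat * n, 2, s1, "-") - sweep(xhat, 2, s2, "*")) /
    rep(n * denom, each = n)
}

## Gradients of one module's contribution to the loss. fw is the cache from
## moduleForwardRaw run in train mode on (L, T); dq is dLoss/dq (length c).
## Valid for continuous WB as well (used by the finite-difference checks).
moduleBackward <- function(fw, dq, WB, W, tauM, V, L, T, R, bg,
                           lambda, dropMask = NULL, gSExtra = NULL) {
  M <- ncol(WB)
  S <- fw$S
  tau <- fw$tau
  dbias <- sum(dq)
  dV <- drop(crossprod(fw$Kdrop, dq))
  dKdrop <- outer(dq, V)
  dKhat <- if (is.null(dropMask)) dKdrop else dKdrop * dropMask
  dK <- batchnormBackward(dKhat, fw$K, fw$batchMean, fw$batchVar, fw$eps)
  dU <- dK[, seq_len(M), drop = FALSE]
  dA <- dK[, M + seq_len(M), drop = FALSE]

  ## --- rank-based score ----------------------------------------------------
  Aranks <- as.matrix(fw$Aranks)
  dWB_U <- -as.matrix(T %*% sweep(dU, 2, tau * S, "/"))
  gS <- colSums(dU) / (2 * tau) +
    colSums(dU * Aranks) / (tau * S^2)
  gTau <- -sum(dU * (fw$U - 1)) / tau
  dUs <- sweep(dU, 2, S, "/")
  Mik <- WB %*% t(dUs)                       # N x c
  gTau <- gTau - sum(Mik[R > tau]) / tau

  ## --- background-subtracted score ----------------------------------------
  c1 <- -colSums(dA * fw$P1) / S
  dWB_A1 <- as.matrix(L %*% sweep(dA, 2, S, "/")) +
    matrix(c1, nrow(WB), M, byrow = TRUE)
  cB <- Matrix::rowSums(bg@B)
  c2 <- colSums(dA * fw$P2) / fw$g
  BtL <- as.matrix(bg@B %*% L)                   # N x c
  dWB_A2 <- -(BtL %*% sweep(dA, 2, fw$g, "/")) + outer(cB, c2)

  ## --- gene-set size penalty and tau coupling ------------------------------
  N <- nrow(WB)
  nrm <- sqrt(sum((S / N)^2))
  if (nrm > 0 && lambda > 0)
    gS <- gS + lambda * (sqrt(12) / sqrt(M)) * S / (N^2 * nrm)
  if (!is.null(gSExtra)) gS <- gS + gSExtra
  jmax <- which.max(S)
  gS[jmax] <- gS[jmax] + gTau
  dtauM <- gTau * 1000 * (tauM > 0)

  dWB <- dWB_U + dWB_A1 + dWB_A2 +
    matrix(gS, nrow(WB), M, byrow = TRUE)
  list(dW = steBackward(dWB, W), dWB = dWB, dtauM = dtauM,
       dV = dV, dbias = dbias)
}

## ---------------------------------------------------------------------------
## NAdam optimizer (PyTorch algorithm, default betas/eps/momentum decay)
## ---------------------------------------------------------------------------

nadamInit <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0, muProd = 1, t = 0L))
}

nadamStep <- function(state, params, grads, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, psi = 0.004) {
  for (nm in names(params)) {
    st <- state[[nm]]
    g <- grads[[nm]]
    st$t <- st$t + 1L
    t <- st$t
    mu_t <- beta1 * (1 - 0.5 * 0.96^(t * psi))
    mu_next <- beta1 * (1 - 0.5 * 0.96^((t + 1) * psi))
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    st$muProd <- st$muProd * mu_t
    vhat <- st$v / (1 - beta2^t)
    step <- ((1 - mu_t) * g / (1 - st$muProd) +
               mu_next * st$m / (1 - st$muProd * mu_next)) /
      (sqrt(vhat) + eps)
    params[[nm]] <- params[[nm]] - lr * step
    state[[nm]] <- st
  }
  list(state = state, params = params)
}

## ---------------------------------------------------------------------------
## Training loop
## ---------------------------------------------------------------------------

#' Train a GSBN core model
#'
#' Mini-batch training with the hierarchy-balanced sampler, the combined
#' loss J = J_S + sum_w v_w CE_w, straight-through-estimator
#' backpropagation through the binarization, and an NAdam optimizer whose
#' state persists across epochs (dampening binary weight flips). The rank
#' cutoff is recomputed from tauM and the current maximum set size at every
#' forward pass. The checkpoint with the highest validation weighted
#' accuracy after the minimum epoch count is returned; training aborts with
#' diagnostics if the loss becomes non-finite.
#'
#' @param trainH,valH \linkS4class{HarmonizedExpression} for the training
#'   and validation split.
#' @param trainLabels,valLabels label data.frames aligned by \code{cell_id}
#'   with the columns of the corresponding matrices.
#' @param hp hyperparameters (\code{\link{gsbnHyperparameters}}).
#' @param seed integer seed; training is bitwise reproducible.
#' @param background optional \linkS4class{BackgroundMap}; built from the
#'   training-data mean log expression when NULL.
#' @param verbose print per-epoch progress.
#' @return The best \linkS4class{CoreModel} checkpoint, with attribute
#'   \code{history} (per-epoch loss and validation accuracy) and
#'   \code{bestEpoch}.
#' @export
trainModel <- function(trainH, trainLabels, valH, valLabels,
                       hp = gsbnHyperparameters(), seed = 1,
                       background = NULL, verbose = FALSE) {
  stopIfNot(ncol(trainH) > 0 && ncol(valH) > 0, "empty split")
  trainLabels <- alignLabels(trainLabels, colnames(trainH))
  valLabels <- alignLabels(valLabels, colnames(valH))
  N <- nFeatures(trainH)
  L <- as.matrix(logNorm(trainH))
  R <- rankSpace(trainH)
  yIdx <- asCategoryIndex(trainLabels$broad_category)
  v <- hierarchicalLossWeights(trainLabels)

  if (is.null(background))
    background <- buildBackgroundMap(rowMeans(L),
                                     nBins = 24,
                                     nSample = min(100L, max(1L, N %/% 48L)),
                                     seed = deriveSeed(seed, 9999L))
  model <- initializeModel(hp, N, deriveSeed(seed, 1L), background,
                           featureNames = rownames(trainH))

  ## flat parameter list: per module W, tauM, V, bias
  params <- list()
  for (p in 1:6) {
    m <- model@modules[[p]]
    params[[paste0("W", p)]] <- m@W
    params[[paste0("tauM", p)]] <- m@tauM
    params[[paste0("V", p)]] <- m@V
    params[[paste0("bias", p)]] <- m@bias
  }
  state <- nadamInit(params)
  runStats <- lapply(1:6, function(p)
    list(mean = rep(0, 2 * hp$M), var = rep(1, 2 * hp$M), fitted = FALSE))

  C <- ncol(L)
  bs <- min(hp$batch_size, C)
  nBatches <- max(ceiling(C / hp$batch_size), hp$min_batches_per_epoch)
  nextBatch <- makeSampler(trainLabels, bs, seed = deriveSeed(seed, 2L))
  aLam <- hp$lambda

  history <- data.frame(epoch = integer(), loss = numeric(),
                        val_weighted_accuracy = numeric())
  best <- list(acc = -Inf, epoch = NA_integer_, params = NULL, stats = NULL)
  minEpoch <- min(hp$min_epochs_before_stop, hp$max_epochs)
  withr::local_seed(deriveSeed(seed, 3L))

  for (epoch in seq_len(hp$max_epochs)) {
    epochLoss <- 0
    for (b in seq_len(nBatches)) {
      idx <- nextBatch()
      Lb <- L[, idx, drop = FALSE]
      Rb <- R[, idx, drop = FALSE]
      vb <- v[idx]
      vb <- vb / sum(vb)
      yb <- yIdx[idx]

      fws <- vector("list", 6)
      masks <- vector("list", 6)
      Q <- matrix(0, length(idx), 6)
      WBs <- vector("list", 6)
      taus <- numeric(6)
      for (p in 1:6) {
        WB <- binarizeWeights(params[[paste0("W", p)]])
        S <- colSums(WB)
        if (any(S == 0))
          stop("training degenerated: module ", p,
               " lost all genes of a gene set at epoch ", epoch,
               call. = FALSE)
        tau <- computeTau(params[[paste0("tauM", p)]], S)
        Tb <- trimRanks(Rb, tau)
        mask <- if (hp$rho > 0)
          matrix(rbinom(length(idx) * 2 * hp$M, 1, 1 - hp$rho),
                 length(idx), 2 * hp$M) / (1 - hp$rho)
        else NULL
        fw <- moduleForwardRaw(WB, tau, params[[paste0("V", p)]],
                               params[[paste0("bias", p)]], Lb, Tb,
                               runStats[[p]], mode = "train",
                               dropMask = mask, bg = background)
        runStats[[p]] <- fw$stats
        fws[[p]] <- fw; masks[p] <- list(mask)
        WBs[[p]] <- WB; taus[p] <- tau
        Q[, p] <- fw$q
      }
      lossP <- predictionLoss(Q, yb, vb)
      lossS <- geneSetSizePenalty(WBs, hp$lambda, hp$M, N)
      loss <- lossP + lossS
      if (!is.finite(loss))
        stop(sprintf(paste0("non-finite loss at epoch %d batch %d ",
                            "(CE = %g, size penalty = %g): training diverged"),
                     epoch, b, lossP, lossS), call. = FALSE)
      epochLoss <- epochLoss + loss / nBatches

      ## dLoss/dQ for weighted CE
      P <- rowSoftmax(Q)
      dQ <- P * vb
      dQ[cbind(seq_along(yb), yb)] <- dQ[cbind(seq_along(yb), yb)] - vb

      grads <- list()
      for (p in 1:6) {
        Tb <- trimRanks(Rb, taus[p])
        gr <- moduleBackward(fws[[p]], dQ[, p], WBs[[p]],
                             params[[paste0("W", p)]],
                             params[[paste0("tauM", p)]],
                             params[[paste0("V", p)]], Lb, Tb, Rb,
                             background, hp$lambda, dropMask = masks[[p]])
        grads[[paste0("W", p)]] <- gr$dW
        grads[[paste0("tauM", p)]] <- gr$dtauM
        grads[[paste0("V", p)]] <- gr$dV
        grads[[paste0("bias", p)]] <- gr$dbias
      }
      upd <- nadamStep(state, params, grads, hp$lr)
      state <- upd$state
      params <- upd$params
    }

    cur <- assembleModel(params, runStats, background, rownames(trainH),
                         hp, fitted = TRUE)
    valPred <- coreForward(cur, valH, mode = "infer")$prediction
    acc <- weightedAccuracy(valPred@yHat, valLabels)
    history <- rbind(history,
                     data.frame(epoch = epoch, loss = epochLoss,
                                val_weighted_accuracy = acc))
    if (verbose)
      message(sprintf("epoch %3d  loss %.4f  val weighted accuracy %.4f",
                      epoch, epochLoss, acc))
    if (epoch >= minEpoch && acc > best$acc)
      best <- list(acc = acc, epoch = epoch, params = params,
                   stats = runStats)
  }
  if (is.null(best$params))     # max_epochs < minEpoch cannot happen, guard
    best <- list(acc = NA_real_, epoch = hp$max_epochs, params = params,
                 stats = runStats)
  out <- assembleModel(best$params, best$stats, background,
                       rownames(trainH), hp, fitted = TRUE)
  attr(out, "history") <- history
  attr(out, "bestEpoch") <- best$epoch
  attr(out, "bestAccuracy") <- best$acc
  out
}

assembleModel <- function(params, runStats, background, featureNames, hp,
                          fitted = FALSE) {
  modules <- lapply(1:6, function(p)
    GSBNModule(W = params[[paste0("W", p)]],
               tauM = params[[paste0("tauM", p)]],
               V = params[[paste0("V", p)]],
               bias = params[[paste0("bias", p)]],
               normMean = runStats[[p]]$mean,
               normVar = runStats[[p]]$var,
               fitted = fitted && isTRUE(runStats[[p]]$fitted)))
  CoreModel(modules, background, featureNames, dropoutRate = hp$rho)
}

alignLabels <- function(labels, cellIds) {
  idx <- match(cellIds, labels$cell_id)
  stopIfNot(!anyNA(idx), "labels missing for some cells")
  labels[idx, , drop = FALSE]
}

#' Ensemble prediction
#'
#' Entrywise average of the member likelihood matrices; category calls and
#' raw potency scores are recomputed from the averaged matrix.
#'
#' @param models an \linkS4class{EnsembleModel} or list of
#'   \linkS4class{CoreModel}.
#' @param H a \linkS4class{HarmonizedExpression}.
#' @return A \linkS4class{PotencyPrediction}.
#' @export
ensemblePredict <- function(models, H) {
  members <- if (is(models, "EnsembleModel")) models@members else models
  stopIfNot(length(members) >= 1, "need at least one model")
  tv <- members[[1]]@tVec
  for (m in members)
    stopIfNot(identical(m@tVec, tv), "member category order mismatch")
  Ps <- lapply(members, function(m)
    coreForward(m, H, mode = "infer")$prediction@P)
  P <- Reduce(`+`, Ps) / length(Ps)
  yHat <- factor(potencyCategories()[max.col(P, ties.method = "first")],
                 levels = potencyCategories())
  PotencyPrediction(P, yHat, rawPotencyScore(P, tv))
}
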