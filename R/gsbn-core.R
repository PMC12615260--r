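#' Trim a rank matrix at a cutoff
#'
#' Elementwise minimum of the rank matrix and the module's rank cutoff tau,
#' so that ranks deeper than tau carry no information.
#'
#' @param R N x C integer rank matrix.
#' @param tau rank cutoff (>= 1).
#' @return N x C trimmed rank matrix.
#' @export
trimRanks <- function(R, tau) {
  stopIfNot(tau >= 1, "tau must be >= 1")
  pmin(R, tau)
}

#' Binarize a weight matrix
#'
#' 1 where the entry is strictly greater than the threshold, 0 otherwise
#' (entries equal to the threshold map to 0).
#'
#' @param M numeric matrix (or vector).
#' @param a threshold (default 0).
#' @return binary matrix of the same shape.
#' @export
binarizeWeights <- function(M, a = 0) {
  out <- (M > a) + 0
  dimnames(out) <- dimnames(M)
  out
}

#' Compute the rank cutoff tau from its learnable parameter
#'
#' tau = 10 + max_j S_j + 1000 * max(0, tauM), rounded to the nearest
#' integer. The construction guarantees that at least ten ranks beyond the
#' largest gene set survive trimming.
#'
#' @param tauM scalar learnable parameter.
#' @param setSizes per-gene-set sizes (column sums of the binary weights).
#' @return integer tau >= 10.
#' @export
#' @examples
#' computeTau(-0.3, c(500, 40)) # 510
#' computeTau(0.5, c(500, 40))  # 1010
computeTau <- function(tauM, setSizes) {
  maxS <- if (length(setSizes)) max(setSizes) else 0
  as.integer(round(10 + maxS + 1000 * max(0, tauM)))
}

#' Rank-based (UCell-style) enrichment score
#'
#' For each cell k and gene set j:
#' ScoreU = 1 + (S_j (S_j + 1) - 2 * sum_i T[i,k] WB[i,j]) / (2 tau S_j).
#' Sets whose genes occupy the top S ranks score exactly 1; sets entirely
#' trimmed at tau attain the minimum (S + 1) / (2 tau).
#'
#' @param T N x C trimmed rank matrix.
#' @param WB N x M binary gene-set matrix.
#' @param tau the rank cutoff used to build \code{T}.
#' @return C x M score matrix.
#' @export
ucellScore <- function(T, WB, tau) {
  S <- colSums(WB)
  if (any(S == 0))
    stop("empty gene set(s): ", paste(which(S == 0), collapse = ", "),
         call. = FALSE)
  A <- crossprod(T, WB)                      # C x M, sum of trimmed ranks
  sweep(-2 * A, 2, S * (S + 1), "+") / (2 * tau * rep(S, each = nrow(A))) + 1
}

#' Background-subtracted (module-score) enrichment
#'
#' Average expression of the gene-set genes minus the aggregated average
#' expression of their expression-matched background genes; background
#' genes are counted with multiplicity when shared across set members.
#'
#' @param L N x C log-normalized expression matrix.
#' @param WB N x M binary gene-set matrix.
#' @param bg a \linkS4class{BackgroundMap}.
#' @return C x M score matrix.
#' @export
amsScore <- function(L, WB, bg) {
  S <- colSums(WB)
  if (any(S == 0))
    stop("empty gene set(s): ", paste(which(S == 0), collapse = ", "),
         call. = FALSE)
  ## GB[x, j] = multiplicity of gene x among the backgrounds of set-j genes
  ## (row i of the map lists the background genes of gene i)
  GB <- as.matrix(Matrix::crossprod(bg@B, WB))
  g <- colSums(GB)
  P1 <- sweep(crossprod(L, WB), 2, S, "/")
  P2 <- sweep(crossprod(L, GB), 2, g, "/")
  as.matrix(P1 - P2)
}

#' Build the expression-matched background map
#'
#' Genes are ranked by reference average log expression and uniformly
#' partitioned into \code{nBins} bins. For each gene, a background size is
#' drawn from Normal(nSample, nSample * (sBin - nSample) / sBin), rounded
#' and clamped to [1, sBin - 1], and that many distinct same-bin genes
#' (self excluded) are sampled without replacement.
#'
#' @param meanLogExpr length-N reference mean log2 expression per gene
#'   (typically row means of L over the training corpus).
#' @param nBins number of bins (default 24).
#' @param nSample mean background genes per gene (default 100).
#' @param seed integer seed (construction is deterministic given the seed).
#' @return A \linkS4class{BackgroundMap}.
#' @export
buildBackgroundMap <- function(meanLogExpr, nBins = 24, nSample = 100,
                               seed = 1) {
  N <- length(meanLogExpr)
  stopIfNot(N > nBins, "need more genes than bins")
  ord <- order(meanLogExpr, seq_len(N))
  bin <- integer(N)
  bin[ord] <- cut(seq_len(N), breaks = nBins, labels = FALSE)
  sizes <- tabulate(bin, nBins)
  if (min(sizes) <= 1)
    stop("degenerate binning: a bin holds a single gene, ",
         "no non-self background candidates; reduce nBins", call. = FALSE)
  if (min(sizes) <= nSample)
    stop(sprintf(paste0("bin size %d <= nSample %d gives non-positive ",
                        "count variance; use a smaller nSample"),
                 min(sizes), nSample), call. = FALSE)
  withr::local_seed(seed)
  ii <- vector("list", N); jj <- vector("list", N)
  for (i in seq_len(N)) {
    sBin <- sizes[bin[i]]
    v <- nSample * (sBin - nSample) / sBin
    cnt <- round(rnorm(1, nSample, sqrt(v)))
    cnt <- min(max(cnt, 1), sBin - 1)
    cand <- setdiff(which(bin == bin[i]), i)
    picked <- if (length(cand) == 1) cand else sample(cand, cnt)
    ii[[i]] <- rep.int(i, length(picked))
    jj[[i]] <- picked
  }
  B <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = 1,
                            dims = c(N, N))
  new("BackgroundMap", B = B, nBins = as.integer(nBins),
      nSample = as.integer(nSample), seed = as.integer(seed))
}

#' Standardize enrichment scores
#'
#' In training mode each score column is standardized by its batch mean
#' and (biased) variance, and running statistics are updated with the
#' given momentum. In inference mode the stored running statistics are
#' applied unchanged.
#'
#' @param K C x 2M enrichment score matrix.
#' @param stats list with elements \code{mean}, \code{var} (length 2M) and
#'   \code{fitted}; required in inference mode.
#' @param mode \code{"train"} or \code{"infer"}.
#' @param momentum running-statistic update momentum (default 0.1).
#' @param eps variance floor guard (default 1e-5).
#' @return list with \code{scores} (standardized matrix) and \code{stats}
#'   (updated running statistics).
#' @export
normalizeScores <- function(K, stats = NULL, mode = c("train", "infer"),
                            momentum = 0.1, eps = 1e-5) {
  mode <- match.arg(mode)
  K <- as.matrix(K)
  if (mode == "infer") {
    if (is.null(stats) || !isTRUE(stats$fitted))
      stop("inference-mode standardization requires fitted statistics",
           call. = FALSE)
    Z <- sweep(sweep(K, 2, stats$mean, "-"), 2, sqrt(stats$var + eps), "/")
    return(list(scores = Z, stats = stats))
  }
  mu <- colMeans(K)
  v <- colMeans(sweep(K, 2, mu, "-")^2)          # biased batch variance
  Z <- sweep(sweep(K, 2, mu, "-"), 2, sqrt(v + eps), "/")
  n <- nrow(K)
  vUnb <- if (n > 1) v * n / (n - 1) else v
  if (is.null(stats))
    stats <- list(mean = rep(0, ncol(K)), var = rep(1, ncol(K)),
                  fitted = FALSE)
  stats$mean <- (1 - momentum) * stats$mean + momentum * mu
  stats$var <- (1 - momentum) * stats$var + momentum * vUnb
  stats$fitted <- TRUE
  list(scores = Z, stats = stats, batchMean = mu, batchVar = v)
}

## Forward pass of one GSBN module. WB may be binary (normal operation) or
## a continuous relaxation (used by the gradient checks). Returns the
## intermediates needed for backpropagation.
moduleForwardRaw <- function(WB, tau, V, bias, L, T, normStats,
                             mode = "infer", dropMask = NULL,
                             bg, momentum = 0.1, eps = 1e-5) {
  S <- colSums(WB)
  U <- {
    A <- as.matrix(crossprod(T, WB))
    sweep(-2 * A, 2, S * (S + 1), "+") / (2 * tau * rep(S, each = nrow(A))) + 1
  }
  GB <- as.matrix(Matrix::crossprod(bg@B, WB))
  g <- colSums(GB)
  P1 <- sweep(as.matrix(crossprod(L, WB)), 2, S, "/")
  P2 <- sweep(as.matrix(crossprod(L, GB)), 2, g, "/")
  A2 <- P1 - P2
  K <- cbind(U, A2)
  nm <- normalizeScores(K, normStats, mode = mode,
                        momentum = momentum, eps = eps)
  Kd <- nm$scores
  if (!is.null(dropMask)) Kd <- Kd * dropMask
  q <- drop(Kd %*% V) + bias
  list(q = q, U = U, A = A2, Aranks = crossprod(T, WB), K = K,
       Khat = nm$scores, Kdrop = Kd, stats = nm$stats,
       batchMean = nm$batchMean, batchVar = nm$batchVar,
       S = S, g = g, P1 = P1, P2 = P2, GB = GB, tau = tau, eps = eps)
}

#' Core model forward pass
#'
#' Runs all six GSBN modules on a harmonized input: binarizes the
#' continuous gene-selection weights, recomputes the rank cutoff, computes
#' both enrichment scores, standardizes them, applies the enrichment layer,
#' and converts the concatenated logits to likelihoods, category calls and
#' raw potency scores. Inference mode is deterministic; training mode uses
#' batch statistics and (when \code{dropMasks} are supplied) dropout.
#'
#' @param model a \linkS4class{CoreModel}.
#' @param H a \linkS4class{HarmonizedExpression} on the model feature space.
#' @param mode \code{"infer"} or \code{"train"}.
#' @param dropMasks optional list of 6 dropout masks (train mode only).
#' @return list with \code{Q} (C x 6 logits), \code{prediction}
#'   (\linkS4class{PotencyPrediction}) and \code{caches} (per-module
#'   intermediates, train mode).
#' @export
coreForward <- function(model, H, mode = c("infer", "train"),
                        dropMasks = NULL) {
  mode <- match.arg(mode)
  stopIfNot(nFeatures(H) == length(model@featureNames),
            sprintf("input has %d features but model expects %d",
                    nFeatures(H), length(model@featureNames)))
  L <- as.matrix(logNorm(H))
  R <- rankSpace(H)
  C <- ncol(L)
  Q <- matrix(0, C, 6,
              dimnames = list(colnames(L), potencyCategories()))
  caches <- vector("list", 6)
  for (p in seq_len(6)) {
    mod <- model@modules[[p]]
    if (mode == "infer" && !mod@fitted)
      stop("model module ", p, " has no fitted normalization statistics; ",
           "train first or use mode = 'train'", call. = FALSE)
    WB <- binarizeWeights(mod@W)
    S <- colSums(WB)
    if (any(S == 0))
      stop("module ", p, " has empty gene set(s); model is degenerate",
           call. = FALSE)
    tau <- computeTau(mod@tauM, S)
    T <- trimRanks(R, tau)
    stats <- list(mean = mod@normMean, var = mod@normVar,
                  fitted = mod@fitted)
    fw <- moduleForwardRaw(WB, tau, mod@V, mod@bias, L, T, stats,
                           mode = mode, dropMask = dropMasks[[p]],
                           bg = model@background)
    Q[, p] <- fw$q
    caches[[p]] <- fw
  }
  P <- rowSoftmax(Q)
  yHat <- factor(potencyCategories()[max.col(P, ties.method = "first")],
                 levels = potencyCategories())
  RPS <- rawPotencyScore(P, model@tVec)
  pred <- PotencyPrediction(P, yHat, RPS)
  list(Q = Q, prediction = pred, caches = caches)
}

#' Raw potency score
#'
#' Expectation of the ordered category anchors under the likelihoods:
#' RPS = P t. One-hot mass on the totipotent column gives 1, on the
#' differentiated column 0, and a uniform row gives 0.5.
#'
#' @param P C x 6 likelihood matrix (rows sum to 1).
#' @param tVec calibration anchors (default \code{potencyAnchors()}).
#' @return length-C numeric vector in [0, 1].
#' @export
rawPotencyScore <- function(P, tVec = potencyAnchors()) {
  stopIfNot(ncol(P) == length(tVec), "P and tVec disagree in width")
  drop(P %*% tVec)
}
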