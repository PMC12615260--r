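#' Diffusion smoothing configuration
#'
#' @param alpha diffusion parameter in [0, 1); 0.9 by default.
#' @param nDispersionGenes number of top-dispersion genes for the cell-cell
#'   similarity (default 1000; capped at the number of informative genes).
#' @param tolerance L-infinity convergence tolerance of the fixed-point
#'   iteration.
#' @param maxIterations iteration cap.
#' @param subsampleThreshold cell count above which block-wise diffusion is
#'   used when \code{subsample = TRUE}.
#' @param subsample enable block-wise diffusion for very large datasets.
#' @return named list.
#' @export
diffusionConfig <- function(alpha = 0.9, nDispersionGenes = 1000,
                            tolerance = 1e-5, maxIterations = 10000,
                            subsampleThreshold = 10000, subsample = FALSE) {
  stopIfNot(alpha >= 0 && alpha < 1, "alpha must lie in [0, 1)")
  list(alpha = alpha, nDispersionGenes = nDispersionGenes,
       tolerance = tolerance, maxIterations = maxIterations,
       subsampleThreshold = subsampleThreshold, subsample = subsample)
}

#' Adaptive k-NN smoothing configuration
#'
#' @param nPcs principal components used for distances (default 30).
#' @param maxNeighborhood candidate nearest neighbours per cell (default 30).
#' @param maxGroup maximum group size of the adaptive search (default 15).
#' @param fallbackK neighbourhood size when no concordant groups are found.
#' @param minCells smoothing is skipped for datasets with at most this many
#'   cells (default 100).
#' @return named list.
#' @export
knnConfig <- function(nPcs = 30, maxNeighborhood = 30, maxGroup = 15,
                      fallbackK = 3, minCells = 100) {
  stopIfNot(fallbackK <= maxNeighborhood,
            "fallbackK cannot exceed maxNeighborhood")
  list(nPcs = as.integer(nPcs),
       maxNeighborhood = as.integer(maxNeighborhood),
       maxGroup = as.integer(maxGroup), fallbackK = as.integer(fallbackK),
       minCells = as.integer(minCells))
}

#' Markov diffusion smoothing of the raw potency score
#'
#' Builds a cell-cell Pearson similarity over the top-dispersion genes
#' (dispersion = variance / mean of log expression), zeroes negative
#' similarities, row-normalizes to a stochastic matrix P, and solves the
#' fixed point s = alpha P s + (1 - alpha) RPS by Jacobi iteration. The
#' result is a convex combination of RPS values, hence bounded by the RPS
#' range.
#'
#' @param L N x C log-normalized expression matrix.
#' @param rps length-C raw potency score.
#' @param cfg configuration from \code{\link{diffusionConfig}}.
#' @return length-C smoothed potency score (SPS).
#' @export
markovDiffusion <- function(L, rps, cfg = diffusionConfig()) {
  C <- length(rps)
  stopIfNot(ncol(L) == C, "L and rps disagree in cell count")
  stopIfNot(C >= 2, "diffusion needs at least two cells")
  if (cfg$alpha == 0) return(rps)
  if (cfg$subsample && C > cfg$subsampleThreshold) {
    blocks <- split(seq_len(C),
                    ceiling(seq_len(C) / cfg$subsampleThreshold))
    out <- rps
    for (b in blocks)
      out[b] <- markovDiffusion(L[, b, drop = FALSE], rps[b],
                                modifyList(cfg, list(subsample = FALSE)))
    return(out)
  }
  mu <- rowMeans(L)
  keep <- which(mu > 0)
  if (length(keep) == 0) {
    warning("constant (all-zero) expression; returning RPS unchanged")
    return(rps)
  }
  disp <- apply(L[keep, , drop = FALSE], 1, var) / mu[keep]
  top <- keep[order(-disp, keep)[seq_len(min(cfg$nDispersionGenes,
                                             length(keep)))]]
  Ls <- L[top, , drop = FALSE]
  sdc <- apply(Ls, 2, sd)
  if (all(sdc == 0)) {
    warning("expression constant across selected genes; returning RPS")
    return(rps)
  }
  sim <- suppressWarnings(cor(Ls))
  sim[is.na(sim)] <- 0
  diag(sim) <- 1                       # zero-variance cells keep themselves
  sim[sim < 0] <- 0
  P <- sim / rowSums(sim)
  s <- rps
  for (it in seq_len(cfg$maxIterations)) {
    sNew <- cfg$alpha * drop(P %*% s) + (1 - cfg$alpha) * rps
    if (max(abs(sNew - s)) < cfg$tolerance) return(sNew)
    s <- sNew
  }
  s
}

#' Category-preserving score binning
#'
#' Within each predicted category p (1..6 ascending potency), cells are
#' ranked ascending by smoothed score (ties broken by cell index) and
#' placed at (p - 1)/6 + r / ((rMax + 1) * 6), keeping every score strictly
#' inside the category's sixth of the unit interval and preserving the
#' within-category order exactly.
#'
#' @param sps length-C smoothed potency scores.
#' @param yHat predicted categories (factor over the six categories).
#' @return length-C binned score.
#' @export
binScores <- function(sps, yHat) {
  p <- asCategoryIndex(yHat)
  out <- numeric(length(sps))
  for (cat in unique(p)) {
    idx <- which(p == cat)
    r <- rank(sps[idx], ties.method = "first")
    out[idx] <- (cat - 1) / 6 + r / ((length(idx) + 1) * 6)
  }
  out
}

#' Map a potency score to its broad category
#'
#' Left-closed, right-open sixths of the unit interval; a score of exactly
#' 1 maps to totipotent.
#'
#' @param score numeric vector in [0, 1].
#' @return factor over the six potency categories.
#' @export
#' @examples
#' scoreToCategory(c(0.10, 0.5, 1.0))
scoreToCategory <- function(score) {
  stopIfNot(all(score >= 0 & score <= 1), "scores must lie in [0, 1]")
  p <- pmin(floor(score * 6) + 1, 6)
  factor(potencyCategories()[p], levels = potencyCategories())
}

#' Adaptive k-nearest-neighbour smoothing
#'
#' Cells are standardized per cell, projected onto the top principal
#' components, and smoothed by a distance-weighted mean over a per-cell
#' neighbourhood whose size k is chosen adaptively: successive nearest-
#' neighbour groups (self + m nearest vs the next m + 1) are compared by
#' the category implied by their mean scores, stopping at the first
#' concordant pair (k = 2m + 1), falling back to k = 3 when none is found
#' up to the maximum group size. Distances are rescaled to unit maximum
#' over each cell's candidate set, and weights are (1 - d)^2 with the cell
#' itself at d = 0. Datasets with at most \code{minCells} cells pass
#' through unchanged.
#'
#' @param L N x C log-normalized expression matrix.
#' @param binned length-C binned smoothed potency score.
#' @param cfg configuration from \code{\link{knnConfig}}.
#' @return list with \code{finalScore}, \code{yHatStar} and \code{kUsed}
#'   (0 where smoothing was skipped).
#' @export
adaptiveKnnSmooth <- function(L, binned, cfg = knnConfig()) {
  C <- length(binned)
  stopIfNot(ncol(L) == C, "L and scores disagree in cell count")
  passThrough <- function(msg = NULL) {
    if (!is.null(msg)) warning(msg)
    list(finalScore = binned, yHatStar = scoreToCategory(binned),
         kUsed = rep(0L, C))
  }
  if (C <= cfg$minCells) return(passThrough())
  if (C - 1 < 4)
    return(passThrough("fewer than 4 neighbours available; skipping"))

  Ls <- scale(L)                        # standardize per cell (columns)
  Ls[is.na(Ls)] <- 0                    # constant cells carry no signal
  nPcs <- min(cfg$nPcs, C - 1, nrow(L))
  pc <- prcomp(t(Ls), center = TRUE, scale. = FALSE, rank. = nPcs)
  scores <- pc$x
  for (j in seq_len(ncol(scores))) {    # deterministic sign convention
    ld <- pc$rotation[, j]
    if (ld[which.max(abs(ld))] < 0) scores[, j] <- -scores[, j]
  }
  D <- as.matrix(dist(scores))

  final <- numeric(C)
  kUsed <- integer(C)
  nCand <- min(cfg$maxNeighborhood, C - 1)
  for (w in seq_len(C)) {
    dw <- D[w, ]
    ord <- order(dw, seq_len(C))
    ord <- ord[ord != w][seq_len(nCand)]
    dmax <- dw[ord[nCand]]
    d <- if (dmax > 0) pmin(dw[ord] / dmax, 1) else rep(0, nCand)

    k <- cfg$fallbackK
    m <- 1L
    while (m + 1L <= cfg$maxGroup && 2L * m + 1L <= nCand) {
      gA <- c(binned[w], binned[ord[seq_len(m)]])
      gB <- binned[ord[(m + 1L):(2L * m + 1L)]]
      if (scoreToCategory(mean(gA)) == scoreToCategory(mean(gB))) {
        k <- 2L * m + 1L
        break
      }
      m <- m + 1L
    }
    nb <- seq_len(k)
    wts <- c(1, (1 - d[nb])^2)
    final[w] <- sum(c(binned[w], binned[ord[nb]]) * wts) / sum(wts)
    kUsed[w] <- k
  }
  list(finalScore = final, yHatStar = scoreToCategory(final), kUsed = kUsed)
}

#' Full postprocessing of raw predictions
#'
#' Applies the three-step refinement: Markov diffusion of the raw potency
#' score, category-preserving binning, and adaptive k-NN smoothing.
#'
#' @param pred a \linkS4class{PotencyPrediction} with raw outputs.
#' @param H the \linkS4class{HarmonizedExpression} the prediction came from.
#' @param diffusion,knn configurations.
#' @return the prediction with \code{SPS}, \code{SPSBinned},
#'   \code{finalScore}, \code{yHatStar} and \code{kUsed} filled in.
#' @export
postProcess <- function(pred, H, diffusion = diffusionConfig(),
                        knn = knnConfig()) {
  L <- as.matrix(logNorm(H))
  sps <- if (ncol(L) >= 2) markovDiffusion(L, pred@RPS, diffusion)
         else pred@RPS
  binned <- binScores(sps, pred@yHat)
  sm <- adaptiveKnnSmooth(L, binned, knn)
  pred@SPS <- sps
  pred@SPSBinned <- binned
  pred@finalScore <- sm$finalScore
  pred@yHatStar <- sm$yHatStar
  pred@kUsed <- as.integer(sm$kUsed)
  pred
}

#' Predict single-cell potency
#'
#' One-call inference: runs the core model (or ensemble) on a harmonized
#' input and, optionally, the full postprocessing chain.
#'
#' @param model a \linkS4class{CoreModel} or \linkS4class{EnsembleModel}.
#' @param H a \linkS4class{HarmonizedExpression}.
#' @param postprocess apply diffusion/binning/k-NN smoothing (default TRUE).
#' @param diffusion,knn postprocessing configurations.
#' @return A \linkS4class{PotencyPrediction}.
#' @export
predictPotency <- function(model, H, postprocess = TRUE,
                           diffusion = diffusionConfig(),
                           knn = knnConfig()) {
  pred <- if (is(model, "EnsembleModel")) ensemblePredict(model, H)
          else coreForward(model, H, mode = "infer")$prediction
  if (postprocess) pred <- postProcess(pred, H, diffusion, knn)
  pred
}
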