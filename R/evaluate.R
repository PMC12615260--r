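#' Weighted Kendall rank correlation
#'
#' Weighted Kendall tau with tau-b style tie correction: every pair (i, j)
#' carries weight w_i * w_j; tau is the weighted concordant-minus-
#' discordant sum over the geometric mean of the weighted untied-pair sums.
#' Ground-truth ranks are coded ascending with maturity, and prediction
#' values are reversed accordingly before comparison (a higher predicted
#' potency must match a lower maturity rank), so perfectly anti-monotone
#' raw predictions yield tau = 1. The p-value uses the classical normal
#' approximation, two-sided.
#'
#' @param predScores numeric predictions (higher = more potent).
#' @param truthRanks ground-truth maturity ranks (1 = least mature).
#' @param weights per-observation non-negative weights; \code{"unit"}
#'   (default) or \code{"balanced"} (each truth level receives equal total
#'   weight split uniformly among its cells), or a numeric vector.
#' @param reversePrediction negate predictions before comparison to match
#'   the maturity coding (default TRUE).
#' @return list with \code{tau}, \code{p_value}, \code{n_cells},
#'   \code{weighting_scheme}.
#' @export
weightedKendall <- function(predScores, truthRanks, weights = "unit",
                            reversePrediction = TRUE) {
  n <- length(predScores)
  stopIfNot(length(truthRanks) == n, "length mismatch")
  scheme <- "numeric"
  if (is.character(weights)) {
    scheme <- match.arg(weights, c("unit", "balanced"))
    weights <- if (scheme == "unit") rep(1, n)
               else balancedWeights(truthRanks)
  }
  stopIfNot(all(weights >= 0) && any(weights > 0),
            "weights must be non-negative, not all zero")
  if (length(unique(predScores)) < 2 || length(unique(truthRanks)) < 2)
    stop("Kendall correlation undefined for constant input", call. = FALSE)
  x <- if (reversePrediction) -predScores else predScores
  y <- truthRanks
  sx <- sign(outer(x, x, "-"))
  sy <- sign(outer(y, y, "-"))
  W <- outer(weights, weights)
  ut <- upper.tri(W)
  num <- sum(W[ut] * sx[ut] * sy[ut])
  dx <- sum(W[ut] * (sx[ut] != 0))
  dy <- sum(W[ut] * (sy[ut] != 0))
  tau <- num / sqrt(dx * dy)
  z <- 3 * tau * sqrt(n * (n - 1)) / sqrt(2 * (2 * n + 5))
  list(tau = tau, p_value = 2 * pnorm(-abs(z)), n_cells = n,
       weighting_scheme = scheme)
}

balancedWeights <- function(truth) {
  lev <- as.character(truth)
  cnt <- table(lev)
  k <- length(cnt)
  unname(1 / (k * as.numeric(cnt[lev])))
}

#' Mean multiclass F1
#'
#' One-vs-rest F1 per ground-truth category present, averaged across those
#' categories.
#'
#' @param pred predicted broad categories.
#' @param truth true broad categories.
#' @return scalar in [0, 1].
#' @export
meanMulticlassF1 <- function(pred, truth) {
  pred <- as.character(pred)
  truth <- as.character(truth)
  stopIfNot(length(pred) == length(truth), "length mismatch")
  cats <- unique(truth)
  f1 <- vapply(cats, function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    if (2 * tp + fp + fn == 0) 0 else 2 * tp / (2 * tp + fp + fn)
  }, 1)
  mean(f1)
}

#' Mean absolute error on category codes
#'
#' Categories are coded 1 (differentiated) to 6 (totipotent); the absolute
#' integer difference is averaged within each ground-truth category, then
#' across categories.
#'
#' @param pred predicted broad categories.
#' @param truth true broad categories.
#' @return scalar in [0, 5].
#' @export
maePotency <- function(pred, truth) {
  pi <- asCategoryIndex(pred)
  ti <- asCategoryIndex(truth)
  stopIfNot(length(pi) == length(ti), "length mismatch")
  err <- abs(pi - ti)
  mean(vapply(split(err, ti), mean, 1))
}
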