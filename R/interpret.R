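#' Gene-set polarity
#'
#' Each gene set carries two enrichment-layer weights (one per score type,
#' at positions j and M + j of V); its polarity is the sign of their mean.
#'
#' @param V length-2M enrichment-layer weight vector.
#' @param j gene-set index (1..M).
#' @return -1, 0 or +1.
#' @export
geneSetPolarity <- function(V, j) {
  M <- length(V) / 2
  stopIfNot(j >= 1 && j <= M, "gene-set index out of range")
  sign(mean(c(V[j], V[M + j])))
}

#' Feature-importance matrix
#'
#' F[i, p] counts, with polarity sign, how often gene i is selected in the
#' gene sets of category-p modules across ensemble members:
#' F[i, p] = sum_l sum_j WB_pl[i, j] * Polarity(V_l, j, p). Genes never
#' selected score 0; importance of an ensemble is the sum of per-member
#' importances.
#'
#' @param models a \linkS4class{CoreModel}, \linkS4class{EnsembleModel} or
#'   list of core models sharing a feature space.
#' @return A \linkS4class{FeatureImportance}.
#' @export
featureImportance <- function(models) {
  members <- if (is(models, "EnsembleModel")) models@members
             else if (is(models, "CoreModel")) list(models)
             else models
  stopIfNot(length(members) >= 1, "need at least one model")
  N <- nrow(members[[1]]@modules[[1]]@W)
  for (m in members)
    stopIfNot(nrow(m@modules[[1]]@W) == N,
              "models disagree in feature-space size")
  F <- matrix(0, N, 6,
              dimnames = list(members[[1]]@featureNames,
                              potencyCategories()))
  for (m in members) {
    for (p in seq_len(6)) {
      mod <- m@modules[[p]]
      WB <- binarizeWeights(mod@W)
      M <- ncol(WB)
      pol <- vapply(seq_len(M), function(j) geneSetPolarity(mod@V, j), 1)
      F[, p] <- F[, p] + drop(WB %*% pol)
    }
  }
  new("FeatureImportance", scores = F,
      modelCount = as.integer(length(members)))
}

#' Positive potency-program score matrix
#'
#' Q^pos is obtained like the module logits but using only the positive
#' enrichment-layer weights: per module, qPos = Knorm %*% max(V, 0).
#' Columns are concatenated across the six modules and, for an ensemble,
#' across members; it is the input for potency-program visualization.
#'
#' @param model a \linkS4class{CoreModel} or \linkS4class{EnsembleModel}.
#' @param H a \linkS4class{HarmonizedExpression}.
#' @return C x (6 * nMembers) matrix.
#' @export
positiveScoreMatrix <- function(model, H) {
  members <- if (is(model, "EnsembleModel")) model@members else list(model)
  out <- NULL
  for (mi in seq_along(members)) {
    m <- members[[mi]]
    fw <- coreForward(m, H, mode = "infer")
    qpos <- vapply(seq_len(6), function(p)
      drop(fw$caches[[p]]$Khat %*% pmax(m@modules[[p]]@V, 0)),
      numeric(ncol(H)))
    colnames(qpos) <- paste0(potencyCategories(),
                             if (length(members) > 1) paste0(".m", mi) else "")
    out <- cbind(out, qpos)
  }
  rownames(out) <- colnames(H)
  out
}

#' Rank potency markers from the importance matrix
#'
#' Positive markers are sorted by descending signed importance, negative
#' markers by ascending signed importance; ties break by feature index.
#'
#' @param fi a \linkS4class{FeatureImportance} (or N x 6 matrix).
#' @param category a potency category name or index 1..6.
#' @param direction \code{"positive"} or \code{"negative"}.
#' @param topN number of markers to return (default 500, clipped with a
#'   warning when it exceeds the number of genes).
#' @return character vector of gene symbols, most extreme first.
#' @export
rankMarkers <- function(fi, category, direction = c("positive", "negative"),
                        topN = 500) {
  direction <- match.arg(direction)
  F <- if (is(fi, "FeatureImportance")) fi@scores else fi
  p <- if (is.numeric(category)) category
       else match(category, potencyCategories())
  stopIfNot(!is.na(p) && p >= 1 && p <= 6, "unknown potency category")
  if (topN > nrow(F)) {
    warning("topN exceeds the number of genes; clipping")
    topN <- nrow(F)
  }
  col <- F[, p]
  ord <- if (direction == "positive") order(-col, seq_along(col))
         else order(col, seq_along(col))
  rownames(F)[ord][seq_len(topN)]
}
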