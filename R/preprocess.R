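#' Map expression onto the harmonized feature space
#'
#' Resolves gene aliases, maps input symbols (human or mouse) onto the
#' dictionary's fixed feature list, collapses genes mapping to the same
#' feature by summation, drops unmapped genes, and zero-fills features that
#' are absent from the input. Output rows follow the feature-list order.
#'
#' @param x a \linkS4class{RawExpression} or genes x cells matrix.
#' @param dict a \linkS4class{GeneDictionary}.
#' @param species \code{"human"} or \code{"mouse"}.
#' @return N x C dense matrix over the dictionary features.
#' @export
harmonizeExpression <- function(x, dict, species = c("human", "mouse")) {
  species <- match.arg(species)
  m <- if (is(x, "RawExpression")) exprValues(x) else x
  feat <- resolveFeatures(rownames(m), dict, species)
  if (length(feat) == 0) {
    stop("no overlap between input genes and dictionary features ",
         sprintf("(0 of %d input genes mapped onto %d features)",
                 nrow(m), length(dict@featureList)), call. = FALSE)
  }
  sub <- as.matrix(m[names(feat), , drop = FALSE])
  rownames(sub) <- unname(feat)
  sub <- collapseDuplicateGenes(sub)
  out <- matrix(0, length(dict@featureList), ncol(m),
                dimnames = list(dict@featureList, colnames(m)))
  out[rownames(sub), ] <- sub
  out
}

#' Dual log/rank representation
#'
#' Converts a harmonized matrix into the two model input encodings: the
#' log-normalized matrix L = log2(1 + x scaled to 1e6 per cell), and the
#' rank matrix R assigning each feature its per-cell ordinal rank with
#' rank 1 for the highest-expressed gene (ties broken by ascending feature
#' index, so all-zero features fill the maximal rank block).
#'
#' @param Xp N x C non-negative harmonized matrix
#'   (from \code{\link{harmonizeExpression}}).
#' @param isCounts logical; kept as metadata (both counts and CPM/TPM are
#'   rescaled per cell to 1e6 before the log transform).
#' @return A \linkS4class{HarmonizedExpression}.
#' @export
#' @examples
#' Xp <- matrix(c(3, 1, 0, 5, 2, 1), nrow = 3,
#'              dimnames = list(paste0("g", 1:3), c("c1", "c2")))
#' H <- dualRepresentation(Xp)
#' logNorm(H)[, 1]    # log2(750001), log2(250001), 0
#' rankSpace(H)[, 2]  # 1, 2, 3
dualRepresentation <- function(Xp, isCounts = TRUE) {
  Xp <- as.matrix(Xp)
  stopIfNot(min(Xp) >= 0, "harmonized expression must be non-negative")
  tot <- colSums(Xp)
  if (any(tot == 0)) {
    stop("all-zero cells cannot be normalized: ",
         paste(utils::head(colnames(Xp)[tot == 0], 10), collapse = ", "),
         call. = FALSE)
  }
  L <- log2(1 + sweep(Xp, 2, tot, "/") * 1e6)
  R <- ordinalRankColumns(Xp)
  HarmonizedExpression(L, R)
}

#' One-step preprocessing
#'
#' Convenience wrapper: harmonize onto the dictionary feature space, then
#' build the dual log/rank representation.
#'
#' @inheritParams harmonizeExpression
#' @return A \linkS4class{HarmonizedExpression}.
#' @export
preprocessExpression <- function(x, dict, species = c("human", "mouse")) {
  isC <- if (is(x, "RawExpression")) isCounts(x) else TRUE
  dualRepresentation(harmonizeExpression(x, dict, species), isCounts = isC)
}
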