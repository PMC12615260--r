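#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#' @importFrom S4Vectors metadata
#' @importFrom Matrix Matrix colSums rowSums t crossprod
#' @importFrom stats rnorm runif var cor prcomp pnorm sd quantile uniroot
#'   rnbinom rbinom rlnorm rgamma rmultinom
NULL

#' Ordered broad potency categories
#'
#' The six broad potency categories in ascending order of developmental
#' potential, from fully differentiated cells up to totipotent cells.
#'
#' @return Character vector of length 6.
#' @export
#' @examples
#' potencyCategories()
potencyCategories <- function() {
  c("Differentiated", "Unipotent", "Oligopotent",
    "Multipotent", "Pluripotent", "Totipotent")
}

#' Calibration anchors of the potency categories
#'
#' Ordered vector t placing the six categories uniformly on the unit
#' interval; the raw potency score is the expectation of this vector under
#' the category likelihoods.
#'
#' @return Numeric vector \code{c(0, 0.2, 0.4, 0.6, 0.8, 1)}.
#' @export
potencyAnchors <- function() seq(0, 1, by = 0.2)

## ---------------------------------------------------------------------------
## RawExpression
## ---------------------------------------------------------------------------

#' @slot values genes x cells non-negative matrix (base or Matrix class).
#' @slot isCounts logical; TRUE when entries are raw (integer) counts.
#' @rdname RawExpression
#' @export
setClass("RawExpression",
  representation(values = "ANY", isCounts = "logical"))

setValidity("RawExpression", function(object) {
  v <- object@values
  msg <- character()
  if (is.null(rownames(v)) || is.null(colnames(v)))
    msg <- c(msg, "values must carry gene rownames and cell colnames")
  if (anyDuplicated(rownames(v)))
    msg <- c(msg, "duplicate gene identifiers (collapse before construction)")
  if (min(v) < 0)
    msg <- c(msg, "expression values must be non-negative")
  if (length(msg)) msg else TRUE
})

#' RawExpression: genes x cells expression input
#'
#' Thin validated container for an input expression matrix (counts or
#' CPM/TPM), genes as rows. Duplicate gene symbols are collapsed by
#' summation before construction.
#'
#' @param values genes x cells matrix with dimnames.
#' @param isCounts logical flag, TRUE for raw counts.
#' @return A \code{RawExpression} object.
#' @export
RawExpression <- function(values, isCounts = TRUE) {
  if (anyDuplicated(rownames(values)))
    values <- collapseDuplicateGenes(values)
  new("RawExpression", values = values, isCounts = isCounts)
}

#' @rdname RawExpression
#' @param x,object a \code{RawExpression}.
#' @export
setMethod("dim", "RawExpression", function(x) dim(x@values))

#' @rdname RawExpression
#' @export
setGeneric("exprValues", function(x) standardGeneric("exprValues"))

#' @rdname RawExpression
#' @export
setMethod("exprValues", "RawExpression", function(x) x@values)

#' @rdname RawExpression
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))

#' @rdname RawExpression
#' @export
setMethod("geneIds", "RawExpression", function(x) rownames(x@values))

#' @rdname RawExpression
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))

#' @rdname RawExpression
#' @export
setMethod("cellIds", "RawExpression", function(x) colnames(x@values))

#' @rdname RawExpression
#' @export
setGeneric("isCounts", function(x) standardGeneric("isCounts"))

#' @rdname RawExpression
#' @export
setMethod("isCounts", "RawExpression", function(x) x@isCounts)

setMethod("show", "RawExpression", function(object) {
  d <- dim(object@values)
  cat("RawExpression:", d[1], "genes x", d[2], "cells;",
      if (object@isCounts) "counts" else "normalized", "\n")
})

## ---------------------------------------------------------------------------
## GeneDictionary
## ---------------------------------------------------------------------------

#' @slot featureList ordered character vector of N harmonized feature symbols.
#' @slot humanToFeature named character; human symbol -> feature symbol.
#' @slot mouseToFeature named character; mouse symbol -> feature symbol.
#' @slot aliasMap named character; alias symbol -> canonical input symbol.
#' @rdname GeneDictionary
#' @export
setClass("GeneDictionary",
  representation(featureList = "character",
                 humanToFeature = "character",
                 mouseToFeature = "character",
                 aliasMap = "character"))

setValidity("GeneDictionary", function(object) {
  msg <- character()
  if (anyDuplicated(object@featureList))
    msg <- c(msg, "featureList has duplicates")
  if (length(object@humanToFeature) &&
      !all(object@humanToFeature %in% object@featureList))
    msg <- c(msg, "humanToFeature targets outside featureList")
  if (length(object@mouseToFeature) &&
      !all(object@mouseToFeature %in% object@featureList))
    msg <- c(msg, "mouseToFeature targets outside featureList")
  if (length(msg)) msg else TRUE
})

setMethod("show", "GeneDictionary", function(object) {
  cat("GeneDictionary:", length(object@featureList), "features;",
      length(object@mouseToFeature), "mouse-mapped;",
      length(object@aliasMap), "aliases\n")
})

#' @rdname GeneDictionary
#' @param x a \code{GeneDictionary}.
#' @export
setGeneric("featureList", function(x) standardGeneric("featureList"))

#' @rdname GeneDictionary
#' @export
setMethod("featureList", "GeneDictionary", function(x) x@featureList)

#' @rdname GeneDictionary
#' @param object a \code{GeneDictionary}.
#' @export
setMethod("length", "GeneDictionary", function(x) length(x@featureList))

## ---------------------------------------------------------------------------
## HarmonizedExpression (SummarizedExperiment with assays L and R)
## ---------------------------------------------------------------------------

#' HarmonizedExpression: dual log/rank representation
#'
#' A \linkS4class{SummarizedExperiment} on the fixed harmonized feature
#' space with two assays: \code{L}, log2(1 + CPM/TPM), and \code{R}, the
#' per-cell integer rank of each feature (rank 1 = highest expression;
#' ties broken by ascending feature index, so each column is a permutation
#' of 1..N).
#'
#' @rdname HarmonizedExpression
#' @export
setClass("HarmonizedExpression", contains = "SummarizedExperiment")

setValidity("HarmonizedExpression", function(object) {
  a <- SummarizedExperiment::assayNames(object)
  msg <- character()
  if (!all(c("L", "R") %in% a))
    msg <- c(msg, "assays 'L' and 'R' are required")
  else {
    L <- SummarizedExperiment::assay(object, "L")
    R <- SummarizedExperiment::assay(object, "R")
    if (min(L) < 0) msg <- c(msg, "L must be non-negative")
    if (ncol(R) > 0) {
      r1 <- sort(R[, 1])
      if (!isTRUE(all.equal(r1, seq_len(nrow(object)), check.attributes = FALSE)))
        msg <- c(msg, "each column of R must be a permutation of 1..N")
    }
  }
  if (length(msg)) msg else TRUE
})

#' @rdname HarmonizedExpression
#' @param L N x C log-normalized matrix.
#' @param R N x C integer rank matrix.
#' @return A \code{HarmonizedExpression} object.
#' @export
HarmonizedExpression <- function(L, R) {
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(L = L, R = R))
  new("HarmonizedExpression", se)
}

#' @rdname HarmonizedExpression
#' @param x a \code{HarmonizedExpression}.
#' @export
setGeneric("logNorm", function(x) standardGeneric("logNorm"))

#' @rdname HarmonizedExpression
#' @export
setMethod("logNorm", "HarmonizedExpression", function(x)
  SummarizedExperiment::assay(x, "L"))

#' @rdname HarmonizedExpression
#' @export
setGeneric("rankSpace", function(x) standardGeneric("rankSpace"))

#' @rdname HarmonizedExpression
#' @export
setMethod("rankSpace", "HarmonizedExpression", function(x)
  SummarizedExperiment::assay(x, "R"))

#' @rdname HarmonizedExpression
#' @export
setGeneric("nFeatures", function(x) standardGeneric("nFeatures"))

#' @rdname HarmonizedExpression
#' @export
setMethod("nFeatures", "HarmonizedExpression", function(x) nrow(x))

setMethod("show", "HarmonizedExpression", function(object) {
  cat("HarmonizedExpression:", nrow(object), "features x",
      ncol(object), "cells (assays L, R)\n")
})

## ---------------------------------------------------------------------------
## BackgroundMap
## ---------------------------------------------------------------------------

#' @slot B N x N sparse binary matrix; B[i, j] = 1 when gene j serves as an
#'   expression-matched background gene for gene i. Diagonal is zero.
#' @slot nBins number of average-expression bins.
#' @slot nSample mean number of background genes per gene.
#' @slot seed integer seed used during construction.
#' @rdname buildBackgroundMap
#' @export
setClass("BackgroundMap",
  representation(B = "ANY", nBins = "integer", nSample = "integer",
                 seed = "integer"))

setValidity("BackgroundMap", function(object) {
  msg <- character()
  if (nrow(object@B) != ncol(object@B))
    msg <- c(msg, "B must be square")
  if (any(Matrix::diag(object@B) != 0))
    msg <- c(msg, "self gene must be excluded from its background")
  if (any(Matrix::rowSums(object@B) < 1))
    msg <- c(msg, "every gene needs at least one background gene")
  if (length(msg)) msg else TRUE
})

setMethod("show", "BackgroundMap", function(object) {
  cat("BackgroundMap:", nrow(object@B), "genes;", object@nBins, "bins;",
      "mean background size", round(mean(Matrix::rowSums(object@B)), 1), "\n")
})

## ---------------------------------------------------------------------------
## GSBNModule and CoreModel
## ---------------------------------------------------------------------------

#' @slot W N x M continuous gene-selection weights (binarized at 0 on the
#'   forward pass).
#' @slot tauM scalar learnable rank-cutoff parameter.
#' @slot V length-2M enrichment-layer weights (UCell block then module-score
#'   block).
#' @slot bias scalar module bias.
#' @slot normMean,normVar running mean/variance (length 2M) of the
#'   enrichment scores, used for standardization at inference.
#' @slot fitted logical; TRUE once normalization statistics are trained.
#' @rdname GSBNModule
#' @export
setClass("GSBNModule",
  representation(W = "matrix", tauM = "numeric", V = "numeric",
                 bias = "numeric", normMean = "numeric", normVar = "numeric",
                 fitted = "logical"))

setValidity("GSBNModule", function(object) {
  msg <- character()
  if (length(object@V) != 2L * ncol(object@W))
    msg <- c(msg, "V must have length 2M")
  if (length(object@normMean) != length(object@V) ||
      length(object@normVar) != length(object@V))
    msg <- c(msg, "normalization statistics must have length 2M")
  if (object@fitted && any(object@normVar <= 0))
    msg <- c(msg, "fitted normalization variances must be positive")
  if (length(msg)) msg else TRUE
})

#' GSBNModule: per-category gene-set binary network parameters
#'
#' @param W,tauM,V,bias,normMean,normVar,fitted see slot documentation.
#' @return A \code{GSBNModule}.
#' @export
GSBNModule <- function(W, tauM, V, bias = 0,
                       normMean = rep(0, length(V)),
                       normVar = rep(1, length(V)),
                       fitted = FALSE) {
  new("GSBNModule", W = W, tauM = tauM, V = V, bias = bias,
      normMean = normMean, normVar = normVar, fitted = fitted)
}

#' @slot modules list of 6 \linkS4class{GSBNModule}, ordered differentiated
#'   to totipotent.
#' @slot background a \linkS4class{BackgroundMap}.
#' @slot tVec ordered calibration anchors (0, 0.2, ..., 1).
#' @slot dropoutRate dropout probability applied to normalized scores during
#'   training.
#' @slot featureNames character vector of N feature symbols.
#' @rdname CoreModel
#' @export
setClass("CoreModel",
  representation(modules = "list", background = "BackgroundMap",
                 tVec = "numeric", dropoutRate = "numeric",
                 featureNames = "character"))

setValidity("CoreModel", function(object) {
  msg <- character()
  if (length(object@modules) != 6L)
    msg <- c(msg, "exactly 6 potency-category modules required")
  if (!all(vapply(object@modules, is, TRUE, class2 = "GSBNModule")))
    msg <- c(msg, "modules must be GSBNModule objects")
  if (length(object@tVec) != 6L || any(diff(object@tVec) <= 0) ||
      object@tVec[1] != 0 || object@tVec[6] != 1)
    msg <- c(msg, "tVec must increase strictly from 0 to 1")
  ns <- vapply(object@modules, function(m) nrow(m@W), 1L)
  if (length(unique(ns)) > 1L || ns[1] != length(object@featureNames))
    msg <- c(msg, "all modules must share the model feature space")
  if (length(msg)) msg else TRUE
})

#' CoreModel: the six-module GSBN potency model
#'
#' @param modules,background,tVec,dropoutRate,featureNames see slots.
#' @return A \code{CoreModel}.
#' @export
CoreModel <- function(modules, background, featureNames,
                      tVec = potencyAnchors(), dropoutRate = 0.5) {
  new("CoreModel", modules = modules, background = background,
      tVec = tVec, dropoutRate = dropoutRate, featureNames = featureNames)
}

setMethod("show", "CoreModel", function(object) {
  M <- ncol(object@modules[[1]]@W)
  sizes <- vapply(object@modules, function(m)
    sum(binarizeWeights(m@W) > 0), 1)
  cat("CoreModel: 6 GSBN modules x", M, "gene sets over",
      length(object@featureNames), "features\n")
  cat("  selected genes per module:", paste(sizes, collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## PotencyPrediction
## ---------------------------------------------------------------------------

#' @slot P C x 6 potency-category likelihood matrix (rows sum to 1).
#' @slot yHat factor of predicted broad categories (model output).
#' @slot RPS raw potency score, the expectation of the category anchors.
#' @slot SPS diffusion-smoothed potency score (NA before postprocessing).
#' @slot SPSBinned category-preserving binned score.
#' @slot finalScore score after adaptive k-NN smoothing.
#' @slot yHatStar final category implied by \code{finalScore}.
#' @slot kUsed integer neighbourhood size used per cell (0 = pass-through).
#' @rdname PotencyPrediction
#' @export
setClass("PotencyPrediction",
  representation(P = "matrix", yHat = "factor", RPS = "numeric",
                 SPS = "numeric", SPSBinned = "numeric",
                 finalScore = "numeric", yHatStar = "factor",
                 kUsed = "integer"))

setValidity("PotencyPrediction", function(object) {
  msg <- character()
  if (ncol(object@P) != 6L) msg <- c(msg, "P must have 6 columns")
  if (nrow(object@P) > 0 && max(abs(rowSums(object@P) - 1)) > 1e-6)
    msg <- c(msg, "rows of P must sum to 1")
  if (length(object@RPS) &&
      (min(object@RPS) < -1e-12 || max(object@RPS) > 1 + 1e-12))
    msg <- c(msg, "RPS must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' PotencyPrediction: per-cell model outputs
#'
#' Holds the likelihood matrix, category calls and the raw, smoothed,
#' binned and final potency scores. Postprocessing slots are NA until
#' \code{\link{postProcess}} fills them.
#'
#' @param P,yHat,RPS see slot documentation.
#' @return A \code{PotencyPrediction}.
#' @export
PotencyPrediction <- function(P, yHat, RPS) {
  C <- nrow(P)
  new("PotencyPrediction", P = P, yHat = yHat, RPS = RPS,
      SPS = rep(NA_real_, C), SPSBinned = rep(NA_real_, C),
      finalScore = rep(NA_real_, C),
      yHatStar = factor(rep(NA_character_, C), levels = potencyCategories()),
      kUsed = rep(NA_integer_, C))
}

#' @rdname PotencyPrediction
#' @param x a \code{PotencyPrediction}.
#' @export
setGeneric("likelihoods", function(x) standardGeneric("likelihoods"))

#' @rdname PotencyPrediction
#' @export
setMethod("likelihoods", "PotencyPrediction", function(x) x@P)

#' @rdname PotencyPrediction
#' @export
setGeneric("potencyCategory", function(x) standardGeneric("potencyCategory"))

#' @rdname PotencyPrediction
#' @export
setMethod("potencyCategory", "PotencyPrediction", function(x) {
  if (!all(is.na(x@yHatStar))) x@yHatStar else x@yHat
})

#' @rdname PotencyPrediction
#' @export
setGeneric("potencyScore", function(x) standardGeneric("potencyScore"))

#' @rdname PotencyPrediction
#' @export
setMethod("potencyScore", "PotencyPrediction", function(x) {
  if (!all(is.na(x@finalScore))) x@finalScore else x@RPS
})

#' @rdname PotencyPrediction
#' @param row.names,optional,... passed on (standard as.data.frame contract).
#' @export
setMethod("as.data.frame", "PotencyPrediction",
  function(x, row.names = NULL, optional = FALSE, ...) {
    data.frame(cell_id = rownames(x@P),
               potency_category = as.character(potencyCategory(x)),
               potency_score = potencyScore(x),
               raw_score = x@RPS,
               smoothed_score = x@SPS,
               binned_score = x@SPSBinned,
               k_used = x@kUsed,
               stringsAsFactors = FALSE)
  })

setMethod("show", "PotencyPrediction", function(object) {
  cat("PotencyPrediction:", nrow(object@P), "cells\n")
  print(table(potencyCategory(object)))
})

## ---------------------------------------------------------------------------
## EnsembleModel and FeatureImportance
## ---------------------------------------------------------------------------

#' @slot members list of \linkS4class{CoreModel} sharing one feature space.
#' @rdname EnsembleModel
#' @export
setClass("EnsembleModel", representation(members = "list"))

setValidity("EnsembleModel", function(object) {
  msg <- character()
  if (length(object@members) < 1L)
    msg <- c(msg, "at least one member model required")
  if (!all(vapply(object@members, is, TRUE, class2 = "CoreModel")))
    msg <- c(msg, "members must be CoreModel objects")
  fn <- lapply(object@members, function(m) m@featureNames)
  if (length(unique(fn)) > 1L)
    msg <- c(msg, "members must share the feature space")
  if (length(msg)) msg else TRUE
})

#' EnsembleModel: averaged GSBN models
#'
#' Member likelihood matrices are averaged entrywise; category calls and
#' raw potency scores are recomputed from the averaged matrix.
#'
#' @param members list of \linkS4class{CoreModel}.
#' @return An \code{EnsembleModel}.
#' @export
EnsembleModel <- function(members) new("EnsembleModel", members = members)

setMethod("show", "EnsembleModel", function(object) {
  cat("EnsembleModel:", length(object@members), "member model(s)\n")
})

#' @slot scores N x 6 signed selection-frequency matrix.
#' @slot modelCount number of ensemble members contributing.
#' @rdname featureImportance
#' @export
setClass("FeatureImportance",
  representation(scores = "matrix", modelCount = "integer"))

setValidity("FeatureImportance", function(object) {
  M <- attr(object@scores, "setsPerModule")
  msg <- character()
  if (ncol(object@scores) != 6L)
    msg <- c(msg, "scores must have one column per potency category")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FeatureImportance", function(object) {
  cat("FeatureImportance:", nrow(object@scores), "genes x 6 categories from",
      object@modelCount, "model(s)\n")
})

#' @rdname featureImportance
#' @param x a \code{FeatureImportance}.
#' @export
setGeneric("importanceScores", function(x) standardGeneric("importanceScores"))

#' @rdname featureImportance
#' @export
setMethod("importanceScores", "FeatureImportance", function(x) x@scores)
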