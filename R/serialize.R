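MODEL_SCHEMA_VERSION <- "1.0"

#' Write a core model to a JSON archive
#'
#' Serializes all module parameters, running normalization statistics, the
#' background map (as sparse triplets), calibration vector, dropout rate
#' and feature names into a single versioned JSON file; numbers are stored
#' at full precision so a round trip is exact.
#'
#' @param model a \linkS4class{CoreModel}.
#' @param path output path (.json).
#' @return \code{path}, invisibly.
#' @export
writeGSBNModel <- function(model, path) {
  bg <- model@background
  trip <- Matrix::summary(as(bg@B, "TsparseMatrix"))
  obj <- list(
    schema = MODEL_SCHEMA_VERSION,
    featureNames = model@featureNames,
    featureChecksum = sum(utf8ToInt(paste(model@featureNames,
                                          collapse = ""))),
    tVec = model@tVec,
    dropoutRate = model@dropoutRate,
    background = list(i = trip$i, j = trip$j,
                      n = nrow(bg@B), nBins = bg@nBins,
                      nSample = bg@nSample, seed = bg@seed),
    modules = lapply(model@modules, function(m)
      list(W = as.vector(m@W), M = ncol(m@W), tauM = m@tauM, V = m@V,
           bias = m@bias, normMean = m@normMean, normVar = m@normVar,
           fitted = m@fitted)))
  json <- jsonlite::toJSON(obj, digits = I(17), auto_unbox = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' Read a core model from a JSON archive
#'
#' @param path path written by \code{\link{writeGSBNModel}}.
#' @return A \linkS4class{CoreModel}.
#' @export
readGSBNModel <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE)
  stopIfNot(identical(obj$schema, MODEL_SCHEMA_VERSION),
            paste("unsupported model schema:", obj$schema))
  n <- obj$background$n
  B <- Matrix::sparseMatrix(i = obj$background$i, j = obj$background$j,
                            x = 1, dims = c(n, n))
  bg <- new("BackgroundMap", B = B,
            nBins = as.integer(obj$background$nBins),
            nSample = as.integer(obj$background$nSample),
            seed = as.integer(obj$background$seed))
  N <- length(obj$featureNames)
  modules <- lapply(obj$modules, function(m)
    GSBNModule(W = matrix(m$W, N, m$M,
                          dimnames = list(obj$featureNames, NULL)),
               tauM = m$tauM, V = m$V, bias = m$bias,
               normMean = m$normMean, normVar = m$normVar,
               fitted = m$fitted))
  CoreModel(modules, bg, obj$featureNames, tVec = obj$tVec,
            dropoutRate = obj$dropoutRate)
}
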