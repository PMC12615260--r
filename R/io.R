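#' Read an expression matrix
#'
#' Reads either a Matrix Market coordinate file with gene/barcode sidecar
#' files, or a dense delimited text file whose first column holds gene
#' symbols and whose header row holds cell identifiers. Duplicate gene
#' symbols are collapsed by summation; negative entries are rejected.
#'
#' @param path path to the matrix (.mtx or delimited text).
#' @param format one of \code{"auto"}, \code{"mtx"}, \code{"dense"}.
#' @param genesFile,barcodesFile sidecar paths for mtx input; default to
#'   \code{genes.tsv} / \code{barcodes.tsv} next to \code{path}.
#' @param isCounts logical; whether values are raw counts.
#' @param sep field separator for dense input (\code{"\t"} or \code{","};
#'   guessed from the file extension by default).
#' @return A \linkS4class{RawExpression}.
#' @export
readExpression <- function(path, format = c("auto", "mtx", "dense"),
                           genesFile = NULL, barcodesFile = NULL,
                           isCounts = TRUE, sep = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "mtx" else "dense"
  if (format == "mtx") {
    dir <- dirname(path)
    if (is.null(genesFile)) genesFile <- file.path(dir, "genes.tsv")
    if (is.null(barcodesFile)) barcodesFile <- file.path(dir, "barcodes.tsv")
    m <- as(Matrix::readMM(path), "CsparseMatrix")
    genes <- readLines(genesFile)
    genes <- vapply(strsplit(genes, "\t"), `[`, "", 1L)
    cells <- readLines(barcodesFile)
    stopIfNot(length(genes) == nrow(m),
              sprintf("genes sidecar has %d entries but matrix has %d rows",
                      length(genes), nrow(m)))
    stopIfNot(length(cells) == ncol(m),
              sprintf("barcodes sidecar has %d entries but matrix has %d columns",
                      length(cells), ncol(m)))
    dimnames(m) <- list(genes, cells)
  } else {
    if (is.null(sep)) sep <- if (grepl("\\.csv$", path)) "," else "\t"
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             check.names = FALSE, row.names = NULL,
                             stringsAsFactors = FALSE)
    genes <- as.character(tab[[1]])
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- genes
  }
  if (min(m) < 0)
    stop("negative expression values in ", path, call. = FALSE)
  RawExpression(m, isCounts = isCounts)
}

#' Write an expression matrix
#'
#' Round-trip counterpart of \code{\link{readExpression}}.
#'
#' @param x a \linkS4class{RawExpression} or genes x cells matrix.
#' @param path output path (.mtx or delimited text).
#' @param format \code{"mtx"} or \code{"dense"}.
#' @param sep field separator for dense output.
#' @return \code{path}, invisibly.
#' @export
writeExpression <- function(x, path, format = c("auto", "mtx", "dense"),
                            sep = "\t") {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mtx$", path)) "mtx" else "dense"
  m <- if (is(x, "RawExpression")) exprValues(x) else x
  if (format == "mtx") {
    Matrix::writeMM(as(Matrix::Matrix(m, sparse = TRUE), "generalMatrix"),
                    path)
    dir <- dirname(path)
    writeLines(rownames(m), file.path(dir, "genes.tsv"))
    writeLines(colnames(m), file.path(dir, "barcodes.tsv"))
  } else {
    tab <- data.frame(gene = rownames(m), as.matrix(m),
                      check.names = FALSE, stringsAsFactors = FALSE)
    utils::write.table(tab, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Read or validate a per-cell label table
#'
#' Labels carry the broad potency category and the phenotype/dataset
#' hierarchy used for loss weighting and evaluation; optional columns are
#' \code{granular_level} (1..24) and \code{relative_order}.
#'
#' @param x path to a TSV with columns \code{cell_id},
#'   \code{broad_category}, \code{phenotype}, \code{dataset} (plus optional
#'   columns), or a data.frame with those columns.
#' @return A validated data.frame; \code{broad_category} becomes an ordered
#'   factor over the six potency categories.
#' @export
readLabels <- function(x) {
  tab <- if (is.character(x))
    utils::read.table(x, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  else as.data.frame(x)
  req <- c("cell_id", "broad_category", "phenotype", "dataset")
  stopIfNot(all(req %in% names(tab)),
            paste("label table needs columns:", paste(req, collapse = ", ")))
  bad <- setdiff(unique(as.character(tab$broad_category)), potencyCategories())
  stopIfNot(length(bad) == 0,
            paste("unknown potency categories:", paste(bad, collapse = ", ")))
  tab$broad_category <- factor(tab$broad_category,
                               levels = potencyCategories(), ordered = TRUE)
  if ("granular_level" %in% names(tab)) {
    gl <- tab$granular_level
    stopIfNot(all(is.na(gl) | (gl >= 1 & gl <= 24)),
              "granular_level must lie in 1..24")
  }
  tab
}

#' Write per-cell predictions to TSV
#'
#' @param pred a \linkS4class{PotencyPrediction}.
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
writePredictions <- function(pred, path) {
  utils::write.table(as.data.frame(pred), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
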