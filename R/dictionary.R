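#' Build a harmonized human/mouse gene dictionary
#'
#' Assembles the fixed feature space from a human-to-mouse ortholog table.
#' When a single mouse gene is the best hit of several human genes, only the
#' human gene with maximum sequence similarity is kept and the others are
#' dropped. Human genes without any ortholog row are retained as singleton
#' features. Feature symbols are the (human) input symbols.
#'
#' @param orthologTable data.frame with columns \code{human_symbol},
#'   \code{mouse_symbol}, \code{similarity}. \code{mouse_symbol} may be NA
#'   for singleton (ortholog-less) human genes.
#' @param aliasTable optional data.frame with columns \code{alias},
#'   \code{symbol} linking alias symbols to canonical input symbols.
#' @return A \linkS4class{GeneDictionary}.
#' @export
#' @examples
#' tab <- data.frame(human_symbol = c("A", "B", "C"),
#'                   mouse_symbol = c("m1", "m1", NA),
#'                   similarity   = c(0.9, 0.8, NA))
#' d <- buildGeneDictionary(tab)
#' featureList(d)   # "A" kept for m1 (max similarity), "C" singleton
buildGeneDictionary <- function(orthologTable, aliasTable = NULL) {
  req <- c("human_symbol", "mouse_symbol", "similarity")
  stopIfNot(all(req %in% names(orthologTable)),
            "orthologTable needs columns human_symbol, mouse_symbol, similarity")
  tab <- orthologTable
  key <- paste(tab$human_symbol, tab$mouse_symbol, sep = "\r")
  if (anyDuplicated(key)) {
    dup <- split(tab$similarity, key)
    bad <- vapply(dup, function(s) length(unique(s)) > 1L, TRUE)
    if (any(bad))
      stop("conflicting similarity for duplicated (human, mouse) pairs: ",
           paste(sub("\r", "/", names(dup)[bad]), collapse = ", "),
           call. = FALSE)
    tab <- tab[!duplicated(key), , drop = FALSE]
  }

  paired <- tab[!is.na(tab$mouse_symbol), , drop = FALSE]
  singles <- unique(tab$human_symbol[is.na(tab$mouse_symbol)])
  ## best-hit filter: one human gene per mouse gene, by max similarity
  keep <- integer(0)
  if (nrow(paired)) {
    ord <- order(paired$mouse_symbol, -paired$similarity)
    paired <- paired[ord, , drop = FALSE]
    keep <- !duplicated(paired$mouse_symbol)
    paired <- paired[keep, , drop = FALSE]
  }
  singles <- setdiff(singles, paired$human_symbol)

  features <- unique(c(paired$human_symbol, singles))
  humanToFeature <- stats::setNames(features, features)
  mouseToFeature <- stats::setNames(paired$human_symbol, paired$mouse_symbol)

  aliasMap <- character(0)
  if (!is.null(aliasTable)) {
    stopIfNot(all(c("alias", "symbol") %in% names(aliasTable)),
              "aliasTable needs columns alias, symbol")
    aliasMap <- stats::setNames(as.character(aliasTable$symbol),
                                as.character(aliasTable$alias))
  }
  new("GeneDictionary", featureList = features,
      humanToFeature = humanToFeature, mouseToFeature = mouseToFeature,
      aliasMap = aliasMap)
}

#' Generate a synthetic fixture dictionary
#'
#' Builds a seed-deterministic stand-in dictionary with the same structure
#' as the full harmonized dictionary (ortholog pairs plus ortholog-less
#' singletons) for testing and simulation; it contains synthetic symbols,
#' not real gene annotations.
#'
#' @param nPairs number of human-mouse ortholog pairs.
#' @param nSingletons number of ortholog-less human genes.
#' @param nAliases number of alias symbols pointing at random features.
#' @param seed integer seed.
#' @return A \linkS4class{GeneDictionary}.
#' @export
syntheticDictionary <- function(nPairs = 450, nSingletons = 50,
                                nAliases = 20, seed = 1) {
  withr::local_seed(seed)
  h <- sprintf("HG%05d", seq_len(nPairs + nSingletons))
  m <- sprintf("mg%05d", seq_len(nPairs))
  tab <- data.frame(
    human_symbol = h,
    mouse_symbol = c(m, rep(NA_character_, nSingletons)),
    similarity = c(round(runif(nPairs, 0.5, 1), 4),
                   rep(NA_real_, nSingletons)),
    stringsAsFactors = FALSE)
  ali <- NULL
  if (nAliases > 0) {
    tgt <- sample(h, nAliases)
    ali <- data.frame(alias = sprintf("AL%04d", seq_len(nAliases)),
                      symbol = tgt, stringsAsFactors = FALSE)
  }
  buildGeneDictionary(tab, ali)
}

## Resolve aliases, then map symbols of one species onto feature symbols.
## Returns a named character (input symbol -> feature) dropping unmapped.
resolveFeatures <- function(symbols, dict, species = c("human", "mouse")) {
  species <- match.arg(species)
  canon <- symbols
  hit <- canon %in% names(dict@aliasMap)
  canon[hit] <- dict@aliasMap[canon[hit]]
  map <- if (species == "human") dict@humanToFeature else dict@mouseToFeature
  feat <- map[canon]
  names(feat) <- symbols
  feat[!is.na(feat)]
}
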