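#' Simulation configuration for potency-structured scRNA-seq data
#'
#' Defines the generative conditions: a negative-binomial count model with
#' lognormal library-size variation and Bernoulli dropout, disjoint
#' per-category marker programs up-shifted by \code{marker_effect} in their
#' own category, mild phenotype-specific marker programs, and a category ->
#' phenotype -> dataset label hierarchy.
#'
#' @param n_genes number of genes (default 500).
#' @param phenotypes_per_category,datasets_per_phenotype,cells_per_phenotype
#'   hierarchy sizes; \code{cells_per_phenotype} is per (phenotype,
#'   dataset) pair.
#' @param markers_per_category disjoint marker genes per category.
#' @param marker_effect fold-change of marker mean expression in the
#'   marker's own category.
#' @param phenotype_markers,phenotype_effect genes and fold-change of the
#'   phenotype-specific programs (drawn from the non-marker pool).
#' @param library_size_mean,library_size_sdlog lognormal library-size model.
#' @param nb_size negative-binomial size (inverse overdispersion).
#' @param dropout_rate extra Bernoulli zero probability.
#' @param seed integer seed.
#' @return named list (class checked by the generator).
#' @export
simulationConfig <- function(n_genes = 500, phenotypes_per_category = 2,
                             datasets_per_phenotype = 2,
                             cells_per_phenotype = 50,
                             markers_per_category = 20, marker_effect = 4,
                             phenotype_markers = 10, phenotype_effect = 2,
                             library_size_mean = 2000,
                             library_size_sdlog = 0.3,
                             nb_size = 2, dropout_rate = 0.2, seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              phenotypes_per_category = as.integer(phenotypes_per_category),
              datasets_per_phenotype = as.integer(datasets_per_phenotype),
              cells_per_phenotype = as.integer(cells_per_phenotype),
              markers_per_category = as.integer(markers_per_category),
              marker_effect = marker_effect,
              phenotype_markers = as.integer(phenotype_markers),
              phenotype_effect = phenotype_effect,
              library_size_mean = library_size_mean,
              library_size_sdlog = library_size_sdlog,
              nb_size = nb_size, dropout_rate = dropout_rate,
              seed = as.integer(seed))
  stopIfNot(cfg$markers_per_category * 6 <= cfg$n_genes,
            "marker allocation exceeds the gene count")
  stopIfNot(all(unlist(cfg[2:5]) >= 1), "hierarchy counts must be >= 1")
  cfg
}

#' Generate a potency-structured synthetic dataset
#'
#' Counts are drawn per cell from a negative binomial around
#' libSize * relativeExpression, where each category's disjoint marker
#' genes have their relative expression multiplied by \code{marker_effect}
#' in cells of that category, and each phenotype adds a milder program of
#' its own. The result is fully determined by the configuration seed.
#'
#' @param cfg configuration from \code{\link{simulationConfig}}.
#' @return list with \code{expression} (\linkS4class{RawExpression}),
#'   \code{labels} (data.frame) and \code{markers} (list of marker gene
#'   names per category).
#' @export
generatePotencyDataset <- function(cfg = simulationConfig()) {
  withr::local_seed(cfg$seed)
  N <- cfg$n_genes
  genes <- sprintf("gene%04d", seq_len(N))
  cats <- potencyCategories()

  markerIdx <- split(seq_len(6 * cfg$markers_per_category),
                     rep(seq_len(6), each = cfg$markers_per_category))
  names(markerIdx) <- cats
  pool <- setdiff(seq_len(N), unlist(markerIdx))

  nPhen <- 6 * cfg$phenotypes_per_category
  phenNames <- paste0("phen_",
                      rep(tolower(substr(cats, 1, 5)),
                          each = cfg$phenotypes_per_category),
                      "_", seq_len(cfg$phenotypes_per_category))
  phenCat <- rep(seq_len(6), each = cfg$phenotypes_per_category)
  nPm <- min(cfg$phenotype_markers, max(0, length(pool) %/% max(nPhen, 1)))
  phenIdx <- if (nPm > 0)
    split(sample(pool, nPm * nPhen), rep(seq_len(nPhen), each = nPm))
  else rep(list(integer(0)), nPhen)

  base <- rlnorm(N, meanlog = 0, sdlog = 1)

  dsNames <- paste0("ds", seq_len(cfg$datasets_per_phenotype))
  cells <- expand.grid(cell = seq_len(cfg$cells_per_phenotype),
                       dataset = dsNames, phen = seq_len(nPhen),
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  C <- nrow(cells)
  lib <- rlnorm(C, log(cfg$library_size_mean) - cfg$library_size_sdlog^2 / 2,
                cfg$library_size_sdlog)

  counts <- matrix(0L, N, C)
  for (k in seq_len(C)) {
    ph <- cells$phen[k]
    rel <- base
    rel[markerIdx[[phenCat[ph]]]] <-
      rel[markerIdx[[phenCat[ph]]]] * cfg$marker_effect
    if (length(phenIdx[[ph]]))
      rel[phenIdx[[ph]]] <- rel[phenIdx[[ph]]] * cfg$phenotype_effect
    p <- rel / sum(rel)
    mu <- lib[k] * p
    x <- rnbinom(N, size = cfg$nb_size, mu = mu)
    if (cfg$dropout_rate > 0)
      x <- x * rbinom(N, 1, 1 - cfg$dropout_rate)
    counts[, k] <- x
  }
  ## guard: a fully zero cell cannot be normalized downstream
  zero <- colSums(counts) == 0
  if (any(zero)) counts[1, zero] <- 1L

  cellIds <- sprintf("cell%05d", seq_len(C))
  dimnames(counts) <- list(genes, cellIds)
  labels <- data.frame(
    cell_id = cellIds,
    broad_category = factor(cats[phenCat[cells$phen]],
                            levels = cats, ordered = TRUE),
    granular_level = (phenCat[cells$phen] - 1L) * 4L +
      ((cells$phen - 1L) %% 4L) + 1L,
    phenotype = phenNames[cells$phen],
    dataset = cells$dataset,
    stringsAsFactors = FALSE)
  list(expression = RawExpression(counts, isCounts = TRUE),
       labels = labels,
       markers = lapply(markerIdx, function(i) genes[i]))
}

## ---------------------------------------------------------------------------
## Label noise
## ---------------------------------------------------------------------------

#' @rdname buildTransitionMatrix
#' @slot P 6 x 6 row-stochastic matrix.
#' @slot sigma Gaussian kernel s.d. in category-rank distance.
#' @export
setClass("TransitionMatrix",
  representation(P = "matrix", sigma = "numeric"))

setValidity("TransitionMatrix", function(object) {
  if (max(abs(rowSums(object@P) - 1)) > 1e-12)
    "rows must sum to 1" else TRUE
})

setMethod("show", "TransitionMatrix", function(object) {
  cat("TransitionMatrix: sigma =", object@sigma,
      "; diagonal =", paste(round(diag(object@P), 3), collapse = ", "), "\n")
})

#' Gaussian rank-distance label-noise transition matrix
#'
#' P[j, i] is proportional to exp(-(j - i)^2 / (2 sigma^2)) over the six
#' potency ranks, rows normalized to unit sum.
#'
#' @param sigma kernel s.d. (> 0).
#' @return A \linkS4class{TransitionMatrix}.
#' @export
buildTransitionMatrix <- function(sigma) {
  stopIfNot(is.numeric(sigma) && sigma > 0, "sigma must be positive")
  d <- outer(1:6, 1:6, "-")
  K <- exp(-d^2 / (2 * sigma^2))
  P <- K / rowSums(K)
  dimnames(P) <- list(potencyCategories(), potencyCategories())
  new("TransitionMatrix", P = P, sigma = sigma)
}

#' Calibrate the label-noise s.d. to a target perturbation level
#'
#' Finds sigma such that the expected fraction of changed labels,
#' 1 - sum_j pi_j P[j, j], equals the target within 1e-4. The uniform-
#' kernel ceiling is 5/6; larger targets are unreachable.
#'
#' @param target target perturbation fraction in (0, 5/6).
#' @param pi label distribution over the six categories (uniform default).
#' @return calibrated sigma.
#' @export
calibrateSigma <- function(target, pi = rep(1 / 6, 6)) {
  stopIfNot(length(pi) == 6 && all(pi >= 0),
            "pi must be a distribution over six categories")
  pi <- pi / sum(pi)
  if (target <= 0 || target >= 5 / 6)
    stop("target perturbation must lie in (0, 5/6): the flat-kernel ",
         "ceiling of the six-category transition matrix is 5/6",
         call. = FALSE)
  f <- function(s) 1 - sum(pi * diag(buildTransitionMatrix(s)@P)) - target
  root <- uniroot(f, lower = 1e-3, upper = 1e3, tol = 1e-10)
  sigma <- root$root
  stopIfNot(abs(f(sigma)) <= 1e-4, "calibration failed to converge")
  sigma
}

#' Perturb potency labels through a transition matrix
#'
#' Cell mode resamples each cell's category independently from its row of
#' the transition matrix; phenotype mode draws once per phenotype and
#' applies the draw to all of its cells.
#'
#' @param labels label data.frame.
#' @param tm a \linkS4class{TransitionMatrix}.
#' @param level \code{"cell"} or \code{"phenotype"}.
#' @param seed integer seed.
#' @return the label data.frame with perturbed \code{broad_category}.
#' @export
perturbLabels <- function(labels, tm, level = c("cell", "phenotype"),
                          seed = 1) {
  level <- match.arg(level)
  withr::local_seed(seed)
  cur <- asCategoryIndex(labels$broad_category)
  new <- cur
  if (level == "cell") {
    for (j in unique(cur)) {
      idx <- which(cur == j)
      new[idx] <- sample.int(6, length(idx), replace = TRUE,
                             prob = tm@P[j, ])
    }
  } else {
    stopIfNot("phenotype" %in% names(labels), "phenotype column required")
    for (ph in unique(labels$phenotype)) {
      idx <- which(labels$phenotype == ph)
      j <- cur[idx[1]]
      new[idx] <- sample.int(6, 1, prob = tm@P[j, ])
    }
  }
  labels$broad_category <- factor(potencyCategories()[new],
                                  levels = potencyCategories(),
                                  ordered = TRUE)
  labels
}

## ---------------------------------------------------------------------------
## Expression perturbations
## ---------------------------------------------------------------------------

#' Downsample each cell to a fixed gene count
#'
#' Keeps the top \code{g} genes by expression per cell and zeroes the
#' rest; ties at the threshold are resolved at random (seeded).
#'
#' @param x \linkS4class{RawExpression} or genes x cells matrix.
#' @param g target number of expressed genes per cell.
#' @param seed integer seed for tie resolution.
#' @return A \linkS4class{RawExpression}.
#' @export
downsampleGeneCounts <- function(x, g, seed = 1) {
  stopIfNot(g >= 1, "g must be >= 1")
  m <- as.matrix(if (is(x, "RawExpression")) exprValues(x) else x)
  withr::local_seed(seed)
  for (k in seq_len(ncol(m))) {
    xk <- m[, k]
    nz <- sum(xk > 0)
    if (nz <= g) next
    thr <- sort(xk, decreasing = TRUE)[g]
    keep <- which(xk > thr)
    tied <- which(xk == thr)
    need <- g - length(keep)
    if (need > 0)
      keep <- c(keep, if (length(tied) == 1) tied
                      else sample(tied, need))
    drop <- setdiff(which(xk > 0), keep)
    m[drop, k] <- 0
  }
  RawExpression(m, isCounts = if (is(x, "RawExpression")) isCounts(x)
                              else TRUE)
}

#' Downsample each cell to a fixed UMI total
#'
#' Cells whose total exceeds \code{u} are resampled by a multinomial draw
#' of \code{u} transcripts with probabilities proportional to the cell's
#' counts; cells at or below the threshold are unaltered.
#'
#' @param x integer-count \linkS4class{RawExpression} or matrix.
#' @param u target UMI count per cell.
#' @param seed integer seed.
#' @return A \linkS4class{RawExpression}.
#' @export
downsampleUmis <- function(x, u, seed = 1) {
  m <- as.matrix(if (is(x, "RawExpression")) exprValues(x) else x)
  if (max(abs(m - round(m))) > 0)
    stop("UMI downsampling requires integer counts", call. = FALSE)
  withr::local_seed(seed)
  tot <- colSums(m)
  for (k in which(tot > u))
    m[, k] <- drop(rmultinom(1, u, m[, k]))
  RawExpression(m, isCounts = TRUE)
}

#' Titrate a phenotype to a fixed rarity
#'
#' Uniform without-replacement subsample of the selected phenotype down to
#' \code{nKeep} cells, leaving all other cells untouched.
#'
#' @param x \linkS4class{RawExpression} or genes x cells matrix.
#' @param labels label data.frame aligned with the cells.
#' @param phenotype phenotype name to downsample.
#' @param nKeep cells to keep.
#' @param seed integer seed.
#' @return list with downsampled \code{expression} and \code{labels}.
#' @export
titrateRarity <- function(x, labels, phenotype, nKeep, seed = 1) {
  m <- if (is(x, "RawExpression")) exprValues(x) else x
  idx <- which(labels$phenotype == phenotype)
  stopIfNot(length(idx) > 0, "phenotype not found")
  stopIfNot(nKeep <= length(idx),
            sprintf("nKeep = %d exceeds phenotype size %d",
                    nKeep, length(idx)))
  withr::local_seed(seed)
  keep <- sort(c(setdiff(seq_len(ncol(m)), idx),
                 if (nKeep == length(idx)) idx else sample(idx, nKeep)))
  list(expression = RawExpression(as.matrix(m[, keep, drop = FALSE]),
                                  isCounts = if (is(x, "RawExpression"))
                                    isCounts(x) else TRUE),
       labels = labels[keep, , drop = FALSE])
}
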