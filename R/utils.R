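## Internal helpers shared across modules.

## Collapse duplicate gene rows by summation (keeps total signal).
collapseDuplicateGenes <- function(values) {
  g <- rownames(values)
  if (!anyDuplicated(g)) return(values)
  out <- rowsum(as.matrix(values), group = g, reorder = FALSE)
  colnames(out) <- colnames(values)
  out
}

## Column-wise ordinal ranks, rank 1 = highest value, ties by ascending
## row index. Returns an integer matrix of the same shape.
ordinalRankColumns <- function(x) {
  x <- as.matrix(x)
  out <- matrix(0L, nrow(x), ncol(x), dimnames = dimnames(x))
  for (k in seq_len(ncol(x))) {
    ord <- order(-x[, k], seq_len(nrow(x)))
    out[ord, k] <- seq_len(nrow(x))
  }
  out
}

## Row-wise softmax with max subtraction.
rowSoftmax <- function(Q) {
  m <- apply(Q, 1, max)
  e <- exp(Q - m)
  e / rowSums(e)
}

## Deterministic seed derivation for sub-streams, kept below 2^31.
deriveSeed <- function(seed, offset) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(offset)) %% 2147483587)
}

stopIfNot <- function(cond, msg) if (!cond) stop(msg, call. = FALSE)
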