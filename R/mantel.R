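.lowerTri <- function(m) m[lower.tri(m)]

.permuteIndices <- function(n) {
  # all permutations of 1:n, one per row (n <= 8 guarded by caller)
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permuteIndices(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    for (r in seq_len(nrow(sub))) {
      rest <- seq_len(n)[-k]
      out[row, ] <- c(k, rest[sub[r, ]])
      row <- row + 1L
    }
  }
  out
}

#' Mantel permutation test between two distance matrices
#'
#' The statistic is the Pearson correlation of the lower-triangle
#' off-diagonal entries. Significance is assessed by jointly permuting the
#' row/column labels of `B`; the p-value is
#' `(1 + #(r_perm >= r_obs)) / (nPermutations + 1)` for the default
#' one-sided "greater" alternative. With `exact = TRUE` (matrices up to
#' 7 x 7) all `n!` label permutations are enumerated and the p-value is
#' the exact proportion `#(r_perm >= r_obs) / n!`, the identity included.
#'
#' @param A,B symmetric numeric matrices of equal dimension with no
#'   missing off-diagonal entries.
#' @param nPermutations random permutations (ignored when `exact`).
#' @param seed integer RNG seed (ignored when `exact`).
#' @param alternative "greater" (default), "less" or "two.sided".
#' @param exact enumerate all permutations instead of sampling.
#' @return A [MantelResult-class].
#' @export
mantelTest <- function(A, B, nPermutations = 999L, seed = 1L,
                       alternative = c("greater", "less", "two.sided"),
                       exact = FALSE) {
  alternative <- match.arg(alternative)
  stopifnot(is.matrix(A), is.matrix(B))
  n <- nrow(A)
  if (n != ncol(A) || n != nrow(B) || n != ncol(B)) {
    stop("matrices must be square and of equal dimension")
  }
  if (anyNA(.lowerTri(A)) || anyNA(.lowerTri(B))) {
    stop("matrices contain missing off-diagonal entries")
  }
  if (max(abs(A - t(A))) > 1e-8 || max(abs(B - t(B))) > 1e-8) {
    stop("matrices must be symmetric")
  }
  x <- .lowerTri(A)
  if (sd(x) == 0 || sd(.lowerTri(B)) == 0) {
    stop("constant off-diagonal entries: Mantel r undefined")
  }
  side <- function(rp, r0) {
    switch(alternative,
           greater = rp >= r0 - 1e-12,
           less = rp <= r0 + 1e-12,
           two.sided = abs(rp) >= abs(r0) - 1e-12)
  }
  r0 <- cor(x, .lowerTri(B))
  if (exact) {
    if (n > 7L) stop("exact enumeration limited to matrices up to 7 x 7")
    perms <- .permuteIndices(n)
    rp <- apply(perms, 1, function(p) cor(x, .lowerTri(B[p, p])))
    p <- mean(side(rp, r0))
    return(new("MantelResult", r = r0, pValue = p,
               nPermutations = NA_integer_, seed = NA_integer_,
               alternative = alternative))
  }
  if (nPermutations < 1L) stop("need at least 1 permutation")
  set.seed(seed)
  hits <- 0L
  for (i in seq_len(nPermutations)) {
    p <- sample.int(n)
    if (side(cor(x, .lowerTri(B[p, p])), r0)) hits <- hits + 1L
  }
  new("MantelResult", r = r0, pValue = (1 + hits) / (nPermutations + 1),
      nPermutations = as.integer(nPermutations), seed = as.integer(seed),
      alternative = alternative)
}
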