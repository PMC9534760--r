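# Independent oracle implementations, deliberately coded on different
# data layouts / algorithms than the production path.

# Weir-Cockerham (1984) per-allele components, brute force.
# popCalls: list of per-population n_i x 2 integer matrices (one locus),
# rows with NA already removed.
oracleWC <- function(popCalls) {
  popCalls <- popCalls[vapply(popCalls, nrow, 1L) > 0L]
  r <- length(popCalls)
  stopifnot(r >= 2L)
  n <- vapply(popCalls, nrow, 1L)
  nbar <- mean(n)
  nc <- (r * nbar - sum(n^2) / (r * nbar)) / (r - 1)
  alleles <- sort(unique(unlist(popCalls)))
  aS <- bS <- cS <- 0
  if (length(alleles) < 2L) return(c(a = 0, b = 0, c = 0))
  for (al in alleles) {
    p <- h <- numeric(r)
    for (i in seq_len(r)) {
      m <- popCalls[[i]]
      copies <- 0; hets <- 0
      for (row in seq_len(nrow(m))) {
        k <- sum(m[row, ] == al)
        copies <- copies + k
        if (k == 1L) hets <- hets + 1
      }
      p[i] <- copies / (2 * n[i])
      h[i] <- hets / n[i]
    }
    pbar <- sum(n * p) / (r * nbar)
    s2 <- sum(n * (p - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n * h) / (r * nbar)
    aS <- aS + (nbar / nc) *
      (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
    bS <- bS + nbar / (nbar - 1) *
      (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
    cS <- cS + hbar / 2
  }
  c(a = aS, b = bS, c = cS)
}

# splits a GenotypeDataset locus into the oracle's per-population layout
popCallsOf <- function(d, locus) {
  m <- alleleCalls(d, locus)
  lapply(populations(d), function(p) {
    rows <- which(d@population == p & !is.na(m[, 1]))
    m[rows, , drop = FALSE]
  })
}

# Dense-matrix REML criterion for the one-way random-intercept model,
# profiled numerically; O(N^3), for small fixtures only.
oracleREML <- function(y, g) {
  g <- as.factor(g)
  Z <- stats::model.matrix(~ g - 1)
  N <- length(y)
  ones <- rep(1, N)
  crit <- function(lambda) {
    V <- diag(N) + lambda * tcrossprod(Z)
    Vi <- solve(V)
    mu <- as.numeric((ones %*% Vi %*% y) / (ones %*% Vi %*% ones))
    r <- y - mu
    Q <- as.numeric(r %*% Vi %*% r)
    as.numeric(determinant(V)$modulus) + log(ones %*% Vi %*% ones) +
      (N - 1) * log(Q)
  }
  # coarse grid then local refinement
  grid <- exp(seq(log(1e-8), log(1e8), length.out = 400))
  vals <- vapply(grid, crit, numeric(1))
  i <- which.min(vals)
  lo <- grid[max(1, i - 1)]; hi <- grid[min(length(grid), i + 1)]
  opt <- optimize(crit, lower = lo, upper = hi, tol = 1e-12)
  lambda <- if (crit(0) <= opt$objective) 0 else opt$minimum
  V <- diag(N) + lambda * tcrossprod(Z)
  Vi <- solve(V)
  mu <- as.numeric((ones %*% Vi %*% y) / (ones %*% Vi %*% ones))
  r <- y - mu
  sw2 <- as.numeric(r %*% Vi %*% r) / (N - 1)
  c(sigmaB2 = lambda * sw2, sigmaW2 = sw2)
}

# All permutations of 1:n via Heap's algorithm (iterative).
heapPermutations <- function(n) {
  a <- seq_len(n)
  out <- matrix(0L, factorial(n), n)
  cvec <- rep(0L, n)
  out[1, ] <- a
  row <- 1L
  i <- 1L
  while (i <= n) {
    if (cvec[i] < i - 1L) {
      if (i %% 2L == 1L) {
        tmp <- a[1]; a[1] <- a[i]; a[i] <- tmp
      } else {
        tmp <- a[cvec[i] + 1L]; a[cvec[i] + 1L] <- a[i]; a[i] <- tmp
      }
      row <- row + 1L
      out[row, ] <- a
      cvec[i] <- cvec[i] + 1L
      i <- 1L
    } else {
      cvec[i] <- 0L
      i <- i + 1L
    }
  }
  out
}

# Balanced two-way ANOVA sums of squares from first principles.
oracleTwoWaySS <- function(y, A, B) {
  A <- as.factor(A); B <- as.factor(B)
  gm <- mean(y)
  ssA <- sum(tapply(y, A, function(v) length(v) * (mean(v) - gm)^2))
  ssB <- sum(tapply(y, B, function(v) length(v) * (mean(v) - gm)^2))
  cellMeans <- tapply(y, list(A, B), mean)
  cellN <- table(A, B)
  amean <- tapply(y, A, mean); bmean <- tapply(y, B, mean)
  ssAB <- 0
  for (i in seq_len(nlevels(A))) {
    for (j in seq_len(nlevels(B))) {
      ssAB <- ssAB + cellN[i, j] *
        (cellMeans[i, j] - amean[i] - bmean[j] + gm)^2
    }
  }
  cellOf <- interaction(A, B)
  ssE <- sum(tapply(y, cellOf, function(v) sum((v - mean(v))^2)))
  c(A = ssA, B = ssB, AB = ssAB, E = ssE)
}

# Small deterministic three-population genotype fixture with missing data:
# 12 individuals, 2 loci, mixed homo/heterozygotes.
wcFixture <- function() {
  calls <- rbind(
    c(1L, 1L, 1L, 2L),
    c(1L, 2L, 2L, 2L),
    c(1L, 1L, 1L, 1L),
    c(2L, 2L, NA, NA),
    c(1L, 2L, 1L, 3L),
    c(2L, 2L, 3L, 3L),
    c(2L, 3L, 1L, 1L),
    c(3L, 3L, 1L, 3L),
    c(1L, 3L, 3L, 3L),
    c(3L, 3L, 2L, 3L),
    c(NA, NA, 2L, 2L),
    c(1L, 1L, 2L, 3L))
  GenotypeDataset(calls, rep(c("low", "mid", "high"), each = 4),
                  c("locA", "locB"))
}
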