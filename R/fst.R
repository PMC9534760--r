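## Weir & Cockerham (1984) theta for multi-allelic co-dominant markers.
##
## For each allele A at a locus, with r populations, n_i genotyped
## individuals in population i, allele frequency p_i and heterozygote
## proportion h_i (individuals carrying exactly one copy of A):
##   nbar  = mean(n_i)
##   n_c   = (r*nbar - sum(n_i^2)/(r*nbar)) / (r - 1)
##   pbar  = sum(n_i p_i) / (r nbar)
##   s2    = sum(n_i (p_i - pbar)^2) / ((r - 1) nbar)
##   hbar  = sum(n_i h_i) / (r nbar)
##   a = (nbar/n_c) (s2 - (pbar(1-pbar) - s2(r-1)/r - hbar/4) / (nbar-1))
##   b = (nbar/(nbar-1)) (pbar(1-pbar) - s2(r-1)/r - hbar(2nbar-1)/(4nbar))
##   c = hbar / 2
## Components are summed over alleles; theta = sum(a) / sum(a + b + c).

.wcLocusComponents <- function(calls2, popf) {
  # calls2: n x 2 integer matrix for one locus, popf: factor (drop unused)
  ok <- !is.na(calls2[, 1])
  calls2 <- calls2[ok, , drop = FALSE]
  popf <- droplevels(popf[ok])
  n_i <- as.numeric(table(popf))
  r <- length(n_i)
  if (r < 2L) {
    stop("need >= 2 populations with non-missing genotypes at the locus")
  }
  nbar <- mean(n_i)
  if (nbar <= 1) stop("Weir-Cockerham components need nbar > 1")
  n_c <- (r * nbar - sum(n_i^2) / (r * nbar)) / (r - 1)
  alleles <- sort(unique(as.vector(calls2)))
  a_sum <- b_sum <- c_sum <- 0
  if (length(alleles) < 2L) {
    return(c(a = 0, b = 0, c = 0))  # monomorphic in the included pops
  }
  for (A in alleles) {
    cnt <- (calls2[, 1] == A) + (calls2[, 2] == A)
    p_i <- tapply(cnt, popf, sum) / (2 * n_i)
    h_i <- tapply(cnt == 1L, popf, sum) / n_i
    pbar <- sum(n_i * p_i) / (r * nbar)
    s2 <- sum(n_i * (p_i - pbar)^2) / ((r - 1) * nbar)
    hbar <- sum(n_i * h_i) / (r * nbar)
    a <- (nbar / n_c) *
      (s2 - (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar / 4) / (nbar - 1))
    b <- (nbar / (nbar - 1)) *
      (pbar * (1 - pbar) - s2 * (r - 1) / r - hbar * (2 * nbar - 1) / (4 * nbar))
    cc <- hbar / 2
    a_sum <- a_sum + a; b_sum <- b_sum + b; c_sum <- c_sum + cc
  }
  c(a = a_sum, b = b_sum, c = c_sum)
}

#' Weir-Cockerham variance components for one locus
#'
#' Returns the among-population (a), among-individual-within-population
#' (b) and within-individual (c) components, summed over all alleles at
#' the locus. Individuals missing at the locus are excluded locus-wise. A
#' locus monomorphic across the included populations yields all-zero
#' components.
#'
#' @param x a [GenotypeDataset-class].
#' @param locus locus name or index.
#' @param pops optional subset of population labels.
#' @return Named numeric vector `c(a, b, c)`.
#' @references Weir BS, Cockerham CC (1984) Estimating F-statistics for
#'   the analysis of population structure. Evolution 38:1358-1370.
#' @export
wcThetaLocus <- function(x, locus, pops = NULL) {
  stopifnot(is(x, "GenotypeDataset"))
  if (!is.null(pops)) x <- subsetPopulations(x, pops)
  .wcLocusComponents(alleleCalls(x, locus), x@population)
}

.allLocusComponents <- function(x) {
  t(vapply(seq_along(x@loci), function(l) {
    tryCatch(.wcLocusComponents(alleleCalls(x, l), x@population),
             error = function(e) c(a = NA_real_, b = NA_real_, c = NA_real_))
  }, numeric(3)))
}

#' Multilocus Weir-Cockerham theta
#'
#' Ratio of sums over loci: `theta = sum(a_l) / sum(a_l + b_l + c_l)`.
#' Loci that carry no variation contribute nothing; a dataset with no
#' variation at any locus is an error. Negative estimates are reported as
#' computed (the estimator is unbiased around zero under panmixia).
#'
#' @inheritParams wcThetaLocus
#' @return Multilocus theta (dimensionless).
#' @export
multilocusTheta <- function(x, pops = NULL) {
  stopifnot(is(x, "GenotypeDataset"))
  if (!is.null(pops)) x <- subsetPopulations(x, pops)
  if (length(levels(x@population)) < 2L) stop("need >= 2 populations")
  comp <- .allLocusComponents(x)
  tot <- rowSums(comp)
  usable <- !is.na(tot)
  denom <- sum(tot[usable])
  if (!any(usable) || denom == 0) {
    stop("no variation: multilocus theta undefined")
  }
  sum(comp[usable, "a"]) / denom
}

#' Pairwise multilocus theta matrix
#'
#' Entry (i, j) is [multilocusTheta()] computed on populations i and j
#' only. Pairs with no shared informative locus are set to `NA`.
#'
#' @param x a [GenotypeDataset-class].
#' @return Symmetric matrix with zero diagonal, dimnames = populations.
#' @export
pairwiseFst <- function(x) {
  stopifnot(is(x, "GenotypeDataset"))
  pops <- levels(x@population)
  k <- length(pops)
  if (k < 2L) stop("need >= 2 populations")
  m <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      th <- tryCatch(multilocusTheta(x, pops = pops[c(i, j)]),
                     error = function(e) NA_real_)
      m[i, j] <- m[j, i] <- th
    }
  }
  m
}

#' Bootstrap (or jackknife) confidence interval for multilocus theta
#'
#' Resamples loci with replacement, recomputes the ratio-of-sums theta per
#' replicate, and returns the 2.5/97.5 percentile bounds. Replicates whose
#' denominator is zero are discarded and counted. `method = "jackknife"`
#' instead deletes one locus at a time and returns a normal-theory
#' interval from the jackknife standard error.
#'
#' @param x a [GenotypeDataset-class] with at least 2 loci.
#' @param nBoot bootstrap replicates (>= 200).
#' @param seed integer RNG seed.
#' @param method "bootstrap" or "jackknife".
#' @return Named numeric `c(low, high)`, with attributes `nDropped`
#'   (degenerate replicates) and `method`.
#' @export
bootstrapFstCI <- function(x, nBoot = 1000L, seed = 1L,
                           method = c("bootstrap", "jackknife")) {
  stopifnot(is(x, "GenotypeDataset"))
  method <- match.arg(method)
  comp <- .allLocusComponents(x)
  comp <- comp[!is.na(rowSums(comp)), , drop = FALSE]
  L <- nrow(comp)
  if (L < 2L) stop("need >= 2 informative loci for a resampling CI")
  a <- comp[, "a"]; tot <- rowSums(comp)
  if (sum(tot) == 0) stop("no variation: theta undefined")
  if (method == "jackknife") {
    thJack <- vapply(seq_len(L), function(l) {
      d <- sum(tot[-l])
      if (d == 0) NA_real_ else sum(a[-l]) / d
    }, numeric(1))
    thJack <- thJack[!is.na(thJack)]
    m <- length(thJack)
    if (m < 2L) stop("all jackknife replicates degenerate")
    se <- sqrt((m - 1) / m * sum((thJack - mean(thJack))^2))
    est <- sum(a) / sum(tot)
    out <- c(low = est - qnorm(0.975) * se, high = est + qnorm(0.975) * se)
    attr(out, "nDropped") <- L - m
  } else {
    if (nBoot < 200L) stop("nBoot must be >= 200")
    set.seed(seed)
    idx <- matrix(sample.int(L, L * nBoot, replace = TRUE), nrow = nBoot)
    aRep <- matrix(a[idx], nrow = nBoot)
    tRep <- matrix(tot[idx], nrow = nBoot)
    den <- rowSums(tRep)
    keep <- den != 0
    if (!any(keep)) stop("all bootstrap replicates degenerate")
    th <- rowSums(aRep)[keep] / den[keep]
    q <- quantile(th, c(0.025, 0.975), names = FALSE, type = 7)
    out <- c(low = q[1], high = q[2])
    attr(out, "nDropped") <- sum(!keep)
  }
  attr(out, "method") <- method
  out
}

#' Full Fst analysis of a genotype dataset
#'
#' Convenience wrapper combining [multilocusTheta()], per-locus theta,
#' [bootstrapFstCI()] and [pairwiseFst()] into an [FstResult-class].
#'
#' @inheritParams bootstrapFstCI
#' @return An [FstResult-class].
#' @export
fstEstimate <- function(x, nBoot = 1000L, seed = 1L,
                        method = c("bootstrap", "jackknife")) {
  method <- match.arg(method)
  comp <- .allLocusComponents(x)
  tot <- rowSums(comp)
  perLocus <- ifelse(is.na(tot) | tot == 0, NA_real_, comp[, "a"] / tot)
  names(perLocus) <- x@loci
  ci <- bootstrapFstCI(x, nBoot = nBoot, seed = seed, method = method)
  new("FstResult",
      thetaGlobal = multilocusTheta(x),
      thetaPerLocus = perLocus,
      ciLow = unname(ci["low"]), ciHigh = unname(ci["high"]),
      pairwise = pairwiseFst(x),
      nBoot = as.integer(if (method == "bootstrap") nBoot else length(x@loci)),
      seed = as.integer(seed), method = method)
}

#' Serialize an FstResult
#'
#' Writes a JSON summary and a per-locus CSV table.
#'
#' @param x an [FstResult-class].
#' @param jsonPath,csvPath output paths (`NULL` to skip either).
#' @return Invisibly, the list serialized to JSON.
#' @export
writeFstResult <- function(x, jsonPath = NULL, csvPath = NULL) {
  stopifnot(is(x, "FstResult"))
  obj <- list(theta_global = x@thetaGlobal, ci_low = x@ciLow,
              ci_high = x@ciHigh, method = x@method, n_boot = x@nBoot,
              seed = x@seed,
              theta_per_locus = as.list(x@thetaPerLocus),
              pairwise = x@pairwise)
  if (!is.null(jsonPath)) {
    jsonlite::write_json(obj, jsonPath, auto_unbox = TRUE, digits = NA,
                         na = "null", matrix = "rowmajor")
  }
  if (!is.null(csvPath)) {
    write.csv(data.frame(locus = names(x@thetaPerLocus),
                         theta = unname(x@thetaPerLocus)),
              csvPath, row.names = FALSE)
  }
  invisible(obj)
}
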