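#' Pst from variance components at a given c/h2 ratio
#'
#' Pst = c * sigmaB2 / (c * sigmaB2 + 2 * h2 * sigmaW2), which depends on
#' the unknown scalars c (proportion of the between-population variance
#' that is additive) and h2 (narrow-sense heritability) only through the
#' ratio r = c / h2:
#' `Pst(r) = r * sigmaB2 / (r * sigmaB2 + 2 * sigmaW2)`.
#'
#' @param vc a [VarianceComponents-class], or a numeric vector
#'   `c(sigmaB2, sigmaW2)`.
#' @param ratio c/h2 ratio(s), strictly positive. Vectorised.
#' @return Pst value(s) in [0, 1].
#' @export
computePst <- function(vc, ratio) {
  if (is(vc, "VarianceComponents")) {
    sb2 <- vc@sigmaB2; sw2 <- vc@sigmaW2
  } else {
    sb2 <- vc[[1]]; sw2 <- vc[[2]]
  }
  if (any(ratio <= 0)) stop("ratio must be > 0")
  if (sb2 < 0 || sw2 < 0) stop("variance components must be non-negative")
  if (sb2 == 0 && sw2 == 0) {
    stop("Pst undefined: both variance components are zero")
  }
  ratio * sb2 / (ratio * sb2 + 2 * sw2)
}

#' Bootstrap confidence band for Pst over a c/h2 grid
#'
#' Resamples the trait table, refits the one-way REML variance components
#' per replicate and evaluates Pst at each grid ratio; per-ratio 95
#' percent percentile intervals are returned along with the retained
#' replicate components (so the band can be re-evaluated at off-grid
#' ratios, see [criticalCH2Ratio()]).
#'
#' The resampling unit is configurable: `"population"` (default) resamples
#' whole populations with replacement and captures the between-population
#' sampling of the trait divergence itself; `"individual"` resamples
#' individuals within populations (stratified), reflecting only
#' within-population sampling error; `"twostage"` does both. Replicates in
#' which both components collapse to zero are dropped and counted; more
#' than 20 percent such replicates is an error.
#'
#' @param traits data.frame with columns `population` and `trait` (and
#'   optionally `trait_name`).
#' @param trait optional `trait_name` filter.
#' @param ratios ascending grid of c/h2 ratios (default 0.05 to 2 in steps
#'   of 0.05).
#' @param nBoot bootstrap replicates (>= 500).
#' @param seed integer RNG seed.
#' @param unit resampling unit (see Details).
#' @return A [PstGrid-class].
#' @export
pstBootstrapCI <- function(traits, trait = NULL,
                           ratios = seq(0.05, 2, by = 0.05),
                           nBoot = 1000L, seed = 1L,
                           unit = c("population", "individual", "twostage")) {
  unit <- match.arg(unit)
  stopifnot(is.data.frame(traits),
            all(c("population", "trait") %in% names(traits)))
  if (!is.null(trait) && "trait_name" %in% names(traits)) {
    traits <- traits[traits$trait_name == trait, , drop = FALSE]
  }
  if (nBoot < 500L) stop("nBoot must be >= 500")
  if (is.unsorted(ratios, strictly = TRUE) || any(ratios <= 0)) {
    stop("ratios must be a strictly ascending positive grid")
  }
  pops <- split(traits$trait, as.character(traits$population))
  pops <- lapply(pops, function(v) v[!is.na(v)])
  if (any(lengths(pops) < 2L)) {
    stop("every population needs >= 2 individuals for the bootstrap")
  }
  k <- length(pops)
  if (k < 2L) stop("need >= 2 populations")

  vcPoint <- fitOneWayREML(values = unlist(pops),
                           groups = rep(names(pops), lengths(pops)))

  set.seed(seed)
  reps <- matrix(NA_real_, nBoot, 2, dimnames = list(NULL, c("sigmaB2", "sigmaW2")))
  for (b in seq_len(nBoot)) {
    if (unit == "individual") {
      samp <- lapply(pops, function(v) v[sample.int(length(v), replace = TRUE)])
    } else {
      pick <- sample.int(k, k, replace = TRUE)
      samp <- pops[pick]
      if (unit == "twostage") {
        samp <- lapply(samp, function(v) v[sample.int(length(v), replace = TRUE)])
      }
      names(samp) <- sprintf("bpop%02d", seq_len(k))  # duplicates stay distinct
    }
    st <- .remlSuffStats(unlist(samp), rep(names(samp), lengths(samp)))
    reps[b, ] <- .remlFromStats(st)
  }
  degenerate <- reps[, 1] == 0 & reps[, 2] == 0
  if (mean(degenerate) > 0.2) {
    stop(sprintf("%.0f%% of bootstrap replicates degenerate (both components zero)",
                 100 * mean(degenerate)))
  }
  reps <- reps[!degenerate, , drop = FALSE]

  pstRep <- function(r) reps[, 1] * r / (reps[, 1] * r + 2 * reps[, 2])
  ciLow <- ciHigh <- numeric(length(ratios))
  for (i in seq_along(ratios)) {
    q <- quantile(pstRep(ratios[i]), c(0.025, 0.975), names = FALSE, type = 7)
    ciLow[i] <- q[1]; ciHigh[i] <- q[2]
  }
  new("PstGrid", ratios = ratios,
      pstPoint = computePst(vcPoint, ratios),
      ciLow = ciLow, ciHigh = ciHigh, replicates = reps,
      nBoot = as.integer(nBoot), nDegenerate = as.integer(sum(degenerate)),
      seed = as.integer(seed), unit = unit)
}

#' Critical c/h2 ratio where Pst ceases to exceed Fst
#'
#' Finds the largest ratio r at which the lower 95 percent bound of Pst
#' does not exceed the upper Fst bound, i.e. the point up to which the
#' trait divergence is indistinguishable from neutral expectation. The
#' grid crossing is refined by bisection using fresh Pst evaluations on
#' the stored bootstrap replicates. A small critical ratio means the
#' Pst > Fst inference is robust to unfavourable assumptions about c/h2.
#'
#' @param grid a [PstGrid-class].
#' @param fstUpper upper bound of the Fst confidence interval (>= 0).
#' @param tol bisection tolerance on the ratio.
#' @return The critical ratio (numeric), or the character sentinel
#'   `"none_below_grid"` (even the smallest grid ratio exceeds `fstUpper`)
#'   or `"beyond_grid"` (overlap still holds at the largest grid ratio).
#' @export
criticalCH2Ratio <- function(grid, fstUpper, tol = 1e-6) {
  stopifnot(is(grid, "PstGrid"), fstUpper >= 0)
  reps <- grid@replicates
  lowAt <- function(r) {
    quantile(reps[, 1] * r / (reps[, 1] * r + 2 * reps[, 2]),
             0.025, names = FALSE, type = 7)
  }
  below <- grid@ciLow <= fstUpper
  if (!any(below)) return("none_below_grid")
  if (below[length(below)]) return("beyond_grid")
  # last crossing wins if the band is non-monotone with few replicates
  iLast <- max(which(below))
  if (!all(below[seq_len(iLast)])) {
    warning("lower Pst band non-monotone across the grid; using the last crossing")
  }
  lo <- grid@ratios[iLast]; hi <- grid@ratios[iLast + 1L]
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (lowAt(mid) <= fstUpper) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Pairwise Pst matrix
#'
#' Entry (i, j) is [computePst()] on variance components refit from
#' populations i and j only. Pairs where both components are zero are set
#' to `NA`.
#'
#' @inheritParams pstBootstrapCI
#' @param ratio a single c/h2 ratio.
#' @return Symmetric matrix with zero diagonal.
#' @export
pairwisePstMatrix <- function(traits, trait = NULL, ratio = 1) {
  stopifnot(is.data.frame(traits))
  if (!is.null(trait) && "trait_name" %in% names(traits)) {
    traits <- traits[traits$trait_name == trait, , drop = FALSE]
  }
  pops <- unique(as.character(traits$population))
  k <- length(pops)
  if (k < 2L) stop("need >= 2 populations")
  m <- matrix(0, k, k, dimnames = list(pops, pops))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      sub <- traits[traits$population %in% pops[c(i, j)], , drop = FALSE]
      p <- tryCatch({
        vc <- fitOneWayREML(sub)
        computePst(vc, ratio)
      }, error = function(e) NA_real_)
      m[i, j] <- m[j, i] <- p
    }
  }
  m
}
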