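## One-way random-intercept REML, profiled in the variance ratio.
##
## Model: y_ij = mu + u_i + e_ij, u_i ~ N(0, sigmaB2), e_ij ~ N(0, sigmaW2).
## With lambda = sigmaB2 / sigmaW2 and d_i = 1 + n_i * lambda, the GLS mean
## is muhat = sum(n_i ybar_i / d_i) / sum(n_i / d_i), and
##   Q(lambda) = SSW + sum(n_i (ybar_i - muhat)^2 / d_i)
## profiles sigmaW2 = Q / (N - 1). Up to constants the REML criterion is
##   f(lambda) = (N - 1) log Q + sum(log d_i) + log(sum(n_i / d_i)),
## which is unimodal in lambda for this model and minimised by a bounded
## scalar search on log(lambda).

.remlSuffStats <- function(values, groups) {
  groups <- droplevels(as.factor(groups))
  n_i <- as.numeric(table(groups))
  ybar <- as.numeric(tapply(values, groups, mean))
  ssw <- sum(tapply(values, groups,
                    function(v) sum((v - mean(v))^2)))
  list(n = n_i, ybar = ybar, ssw = ssw, N = length(values))
}

.remlCriterion <- function(lambda, st) {
  d <- 1 + st$n * lambda
  w <- st$n / d
  mu <- sum(w * st$ybar) / sum(w)
  Q <- st$ssw + sum(st$n * (st$ybar - mu)^2 / d)
  if (Q <= 0) return(-Inf)
  (st$N - 1) * log(Q) + sum(log(d)) + log(sum(w))
}

.remlFromStats <- function(st, lowerLog = -30, upperLog = 30, tol = 1e-10) {
  k <- length(st$n)
  N <- st$N
  totalSS <- st$ssw + sum(st$n * (st$ybar - sum(st$n * st$ybar) / N)^2)
  if (totalSS <= max(1e-24, 1e-15 * mean(st$ybar)^2)) {
    return(c(sigmaB2 = 0, sigmaW2 = 0))
  }
  # degenerate within-group variation: all residual variance is between
  if (st$ssw <= 1e-14 * totalSS) {
    ybar <- st$ybar
    return(c(sigmaB2 = sum((ybar - mean(ybar))^2) / (k - 1), sigmaW2 = 0))
  }
  opt <- optimize(function(x) .remlCriterion(exp(x), st),
                  lower = lowerLog, upper = upperLog, tol = tol)
  f0 <- .remlCriterion(0, st)
  if (f0 <= opt$objective || opt$minimum <= lowerLog + 1e-6) {
    lambda <- 0
  } else {
    lambda <- exp(opt$minimum)
  }
  d <- 1 + st$n * lambda
  w <- st$n / d
  mu <- sum(w * st$ybar) / sum(w)
  Q <- st$ssw + sum(st$n * (st$ybar - mu)^2 / d)
  sw2 <- Q / (N - 1)
  c(sigmaB2 = lambda * sw2, sigmaW2 = sw2)
}

#' REML variance components for a one-way random-intercept model
#'
#' Fits `trait ~ 1 + (1 | population)` by restricted maximum likelihood,
#' profiled in the ratio `lambda = sigmaB2 / sigmaW2` (bounded scalar
#' search on `log(lambda)`). The boundary solution `sigmaB2 = 0` is
#' permitted; a dataset with all values identical returns `(0, 0)`.
#'
#' @param traits data.frame with at least columns `population` and
#'   `trait`; alternatively pass plain vectors via `values`/`groups`.
#' @param trait optional value of `trait_name` to filter on, when the
#'   table carries several traits.
#' @param values,groups optional vectors used instead of `traits`.
#' @return A [VarianceComponents-class] with `method = "reml"`.
#' @export
fitOneWayREML <- function(traits = NULL, trait = NULL,
                          values = NULL, groups = NULL) {
  if (is.null(values)) {
    stopifnot(is.data.frame(traits),
              all(c("population", "trait") %in% names(traits)))
    if (!is.null(trait) && "trait_name" %in% names(traits)) {
      traits <- traits[traits$trait_name == trait, , drop = FALSE]
    }
    values <- traits$trait
    groups <- traits$population
  }
  keep <- !is.na(values) & !is.na(groups)
  values <- values[keep]; groups <- groups[keep]
  st <- .remlSuffStats(values, groups)
  if (length(st$n) < 2L) stop("need >= 2 populations")
  if (all(st$n < 2L)) stop("need >= 2 individuals in at least one population")
  est <- .remlFromStats(st)
  new("VarianceComponents", sigmaB2 = unname(est["sigmaB2"]),
      sigmaW2 = unname(est["sigmaW2"]),
      nPopulations = length(st$n), nTotal = st$N, method = "reml")
}

#' Method-of-moments (ANOVA) variance components, one-way design
#'
#' Classical expected-mean-squares estimator: `sigmaW2 = MSW` and
#' `sigmaB2 = (MSB - MSW) / n0` with the unbalanced-design coefficient
#' `n0 = (N - sum(n_i^2) / N) / (k - 1)`. Negative `sigmaB2` is truncated
#' at zero. Mainly useful as an independent check on the REML fit
#' (the two agree exactly for balanced designs with interior solutions).
#'
#' @inheritParams fitOneWayREML
#' @return A [VarianceComponents-class] with `method = "moments"`.
#' @export
fitOneWayMoments <- function(traits = NULL, trait = NULL,
                             values = NULL, groups = NULL) {
  if (is.null(values)) {
    stopifnot(is.data.frame(traits),
              all(c("population", "trait") %in% names(traits)))
    if (!is.null(trait) && "trait_name" %in% names(traits)) {
      traits <- traits[traits$trait_name == trait, , drop = FALSE]
    }
    values <- traits$trait
    groups <- traits$population
  }
  st <- .remlSuffStats(values, groups)
  k <- length(st$n); N <- st$N
  if (k < 2L) stop("need >= 2 populations")
  gm <- sum(st$n * st$ybar) / N
  ssb <- sum(st$n * (st$ybar - gm)^2)
  msb <- ssb / (k - 1)
  msw <- if (N > k) st$ssw / (N - k) else 0
  n0 <- (N - sum(st$n^2) / N) / (k - 1)
  new("VarianceComponents", sigmaB2 = max(0, (msb - msw) / n0),
      sigmaW2 = msw, nPopulations = k, nTotal = N, method = "moments")
}
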