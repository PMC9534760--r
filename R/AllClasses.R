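#' GenotypeDataset: diploid multi-allelic genotypes grouped by population
#'
#' Individuals-by-loci diploid allele calls for co-dominant markers such as
#' microsatellites. Allele codes are positive integers; missing calls are
#' `NA`. Calls are stored as an integer matrix with two adjacent columns
#' per locus, which keeps the Weir-Cockerham machinery vectorised.
#'
#' @slot calls integer matrix, `nIndividuals x (2 * nLoci)`; columns
#'   `2l - 1` and `2l` hold the two allele copies at locus `l`.
#' @slot population factor of length `nIndividuals`; population of each
#'   individual, levels in input order.
#' @slot loci character vector of locus names.
#' @slot individualIds unique character ids, one per row of `calls`.
#'
#' @seealso [readGenepop()], [simulateGenotypes()], [multilocusTheta()]
#' @export
setClass("GenotypeDataset",
  representation(
    calls = "matrix",
    population = "factor",
    loci = "character",
    individualIds = "character"
  )
)

setValidity("GenotypeDataset", function(object) {
  msg <- character()
  if (!is.integer(object@calls)) {
    msg <- c(msg, "calls must be an integer matrix (NA for missing)")
  }
  if (ncol(object@calls) != 2L * length(object@loci)) {
    msg <- c(msg, "calls must have two columns per locus")
  }
  if (nrow(object@calls) != length(object@population)) {
    msg <- c(msg, "population must have one entry per individual")
  }
  if (length(object@individualIds) != nrow(object@calls)) {
    msg <- c(msg, "individualIds must have one entry per individual")
  }
  if (anyDuplicated(object@individualIds)) {
    msg <- c(msg, "individual ids must be unique")
  }
  if (anyDuplicated(object@loci)) {
    msg <- c(msg, "locus names must be unique")
  }
  if (any(object@calls <= 0L, na.rm = TRUE)) {
    msg <- c(msg, "allele codes must be positive integers")
  }
  # a call is either fully observed or fully missing at a locus
  for (l in seq_along(object@loci)) {
    a <- object@calls[, 2L * l - 1L]
    b <- object@calls[, 2L * l]
    if (any(is.na(a) != is.na(b))) {
      msg <- c(msg, sprintf("half-missing genotype at locus '%s'",
                            object@loci[l]))
      break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Construct a GenotypeDataset
#'
#' @param calls integer matrix with two columns per locus (see
#'   [GenotypeDataset-class]).
#' @param population character or factor of population labels.
#' @param loci character vector of locus names.
#' @param individualIds optional character ids; generated if missing.
#' @return A [GenotypeDataset-class] object.
#' @export
GenotypeDataset <- function(calls, population, loci, individualIds = NULL) {
  storage.mode(calls) <- "integer"
  if (!is.factor(population)) {
    population <- factor(population, levels = unique(population))
  } else {
    population <- droplevels(population)
  }
  if (is.null(individualIds)) {
    individualIds <- sprintf("ind_%04d", seq_len(nrow(calls)))
  }
  new("GenotypeDataset", calls = calls, population = population,
      loci = as.character(loci), individualIds = as.character(individualIds))
}

#' @describeIn GenotypeDataset-class population labels (levels, in order)
#' @param x,object a `GenotypeDataset`
#' @export
setGeneric("populations", function(x) standardGeneric("populations"))

#' @rdname GenotypeDataset-class
#' @export
setMethod("populations", "GenotypeDataset", function(x) levels(x@population))

#' @describeIn GenotypeDataset-class locus names
#' @export
setGeneric("loci", function(x) standardGeneric("loci"))

#' @rdname GenotypeDataset-class
#' @export
setMethod("loci", "GenotypeDataset", function(x) x@loci)

#' @describeIn GenotypeDataset-class number of individuals
#' @export
setGeneric("nIndividuals", function(x) standardGeneric("nIndividuals"))

#' @rdname GenotypeDataset-class
#' @export
setMethod("nIndividuals", "GenotypeDataset", function(x) nrow(x@calls))

#' @describeIn GenotypeDataset-class the two allele columns of one locus
#' @param locus locus name or index
#' @export
setGeneric("alleleCalls", function(x, locus) standardGeneric("alleleCalls"))

#' @rdname GenotypeDataset-class
#' @export
setMethod("alleleCalls", "GenotypeDataset", function(x, locus) {
  if (is.character(locus)) {
    locus <- match(locus, x@loci)
    if (is.na(locus)) stop("unknown locus")
  }
  x@calls[, c(2L * locus - 1L, 2L * locus), drop = FALSE]
})

#' Subset a GenotypeDataset to a set of populations
#'
#' @param x a [GenotypeDataset-class]
#' @param pops character vector of population labels to keep.
#' @return A `GenotypeDataset` restricted to `pops`.
#' @export
subsetPopulations <- function(x, pops) {
  stopifnot(is(x, "GenotypeDataset"))
  missing <- setdiff(pops, levels(x@population))
  if (length(missing)) {
    stop("unknown population(s): ", paste(missing, collapse = ", "))
  }
  keep <- x@population %in% pops
  GenotypeDataset(x@calls[keep, , drop = FALSE],
                  factor(as.character(x@population[keep]), levels = pops),
                  x@loci, x@individualIds[keep])
}

setMethod("show", "GenotypeDataset", function(object) {
  cat("GenotypeDataset:", nrow(object@calls), "individuals,",
      length(levels(object@population)), "populations,",
      length(object@loci), "loci\n")
  tb <- table(object@population)
  cat("  individuals per population:",
      paste(sprintf("%s=%d", names(tb), tb), collapse = ", "), "\n")
})

#' FstResult: Weir-Cockerham theta with resampling confidence interval
#'
#' @slot thetaGlobal multilocus theta (ratio-of-sums over loci).
#' @slot thetaPerLocus named numeric, per-locus theta (`NA` where a locus
#'   is uninformative).
#' @slot ciLow,ciHigh 95 percent interval over loci (bootstrap percentile
#'   or jackknife normal).
#' @slot pairwise symmetric population-by-population matrix of pairwise
#'   multilocus theta, zero diagonal.
#' @slot nBoot number of resampling replicates.
#' @slot seed RNG seed used for the resampling.
#' @slot method "bootstrap" or "jackknife".
#' @seealso [fstEstimate()]
#' @export
setClass("FstResult",
  representation(
    thetaGlobal = "numeric",
    thetaPerLocus = "numeric",
    ciLow = "numeric",
    ciHigh = "numeric",
    pairwise = "matrix",
    nBoot = "integer",
    seed = "integer",
    method = "character"
  )
)

setValidity("FstResult", function(object) {
  msg <- character()
  pw <- object@pairwise
  if (nrow(pw) != ncol(pw)) msg <- c(msg, "pairwise matrix must be square")
  if (nrow(pw) > 0) {
    if (any(abs(diag(pw)) > 1e-12, na.rm = TRUE)) {
      msg <- c(msg, "pairwise diagonal must be zero")
    }
    if (!isTRUE(all.equal(pw, t(pw)))) {
      msg <- c(msg, "pairwise matrix must be symmetric")
    }
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "FstResult", function(object) {
  cat(sprintf("Weir-Cockerham theta: %.4f (95%% CI %.4f-%.4f, %s, %d reps)\n",
              object@thetaGlobal, object@ciLow, object@ciHigh,
              object@method, object@nBoot))
  cat("  per-locus theta:\n")
  print(round(object@thetaPerLocus, 4))
})

#' @describeIn FstResult-class the global multilocus theta
#' @param x an `FstResult`
#' @export
setGeneric("thetaGlobal", function(x) standardGeneric("thetaGlobal"))

#' @rdname FstResult-class
#' @export
setMethod("thetaGlobal", "FstResult", function(x) x@thetaGlobal)

#' @describeIn FstResult-class the pairwise theta matrix
#' @export
setGeneric("pairwiseMatrix", function(x) standardGeneric("pairwiseMatrix"))

#' @rdname FstResult-class
#' @export
setMethod("pairwiseMatrix", "FstResult", function(x) x@pairwise)

#' @describeIn FstResult-class lower and upper CI bounds
#' @export
setGeneric("confint95", function(x) standardGeneric("confint95"))

#' @rdname FstResult-class
#' @export
setMethod("confint95", "FstResult", function(x) c(low = x@ciLow, high = x@ciHigh))

#' VarianceComponents: one-way between/within decomposition of a trait
#'
#' @slot sigmaB2 between-population variance (trait units squared).
#' @slot sigmaW2 within-population (residual) variance.
#' @slot nPopulations,nTotal design sizes.
#' @slot method "reml" or "moments".
#' @seealso [fitOneWayREML()], [computePst()]
#' @export
setClass("VarianceComponents",
  representation(
    sigmaB2 = "numeric",
    sigmaW2 = "numeric",
    nPopulations = "integer",
    nTotal = "integer",
    method = "character"
  )
)

setValidity("VarianceComponents", function(object) {
  msg <- character()
  if (object@sigmaB2 < 0 || object@sigmaW2 < 0) {
    msg <- c(msg, "variance components must be non-negative")
  }
  if (object@nPopulations < 2L) msg <- c(msg, "need at least 2 populations")
  if (object@nTotal < object@nPopulations) {
    msg <- c(msg, "nTotal must be at least nPopulations")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "VarianceComponents", function(object) {
  cat(sprintf(
    "Variance components (%s): sigmaB2 = %.5g, sigmaW2 = %.5g (%d pops, n = %d)\n",
    object@method, object@sigmaB2, object@sigmaW2,
    object@nPopulations, object@nTotal))
})

#' @describeIn VarianceComponents-class between-population variance
#' @param x a `VarianceComponents`
#' @export
setGeneric("sigmaB2", function(x) standardGeneric("sigmaB2"))

#' @rdname VarianceComponents-class
#' @export
setMethod("sigmaB2", "VarianceComponents", function(x) x@sigmaB2)

#' @describeIn VarianceComponents-class within-population variance
#' @export
setGeneric("sigmaW2", function(x) standardGeneric("sigmaW2"))

#' @rdname VarianceComponents-class
#' @export
setMethod("sigmaW2", "VarianceComponents", function(x) x@sigmaW2)

#' PstGrid: Pst over a c/h2 ratio grid with bootstrap confidence bands
#'
#' Pst depends on the unknown proportion of additive between-population
#' variance (c) and the trait heritability (h2) only through the ratio
#' r = c/h2; the grid scans that ratio. Bootstrap replicates of the
#' variance components are retained so Pst (and its confidence band) can
#' be re-evaluated at any off-grid ratio without resampling again.
#'
#' @slot ratios ascending c/h2 grid.
#' @slot pstPoint point estimate of Pst per ratio.
#' @slot ciLow,ciHigh 95 percent percentile bounds per ratio.
#' @slot replicates numeric matrix `nBoot x 2` with bootstrap
#'   `(sigmaB2, sigmaW2)` pairs (degenerate replicates removed).
#' @slot nBoot requested number of bootstrap replicates.
#' @slot nDegenerate replicates dropped because both components were zero.
#' @slot seed RNG seed.
#' @slot unit resampling unit ("population", "individual" or "twostage").
#' @seealso [pstBootstrapCI()], [criticalCH2Ratio()]
#' @export
setClass("PstGrid",
  representation(
    ratios = "numeric",
    pstPoint = "numeric",
    ciLow = "numeric",
    ciHigh = "numeric",
    replicates = "matrix",
    nBoot = "integer",
    nDegenerate = "integer",
    seed = "integer",
    unit = "character"
  )
)

setValidity("PstGrid", function(object) {
  msg <- character()
  k <- length(object@ratios)
  if (is.unsorted(object@ratios, strictly = TRUE)) {
    msg <- c(msg, "ratios must be strictly ascending")
  }
  if (length(object@pstPoint) != k || length(object@ciLow) != k ||
      length(object@ciHigh) != k) {
    msg <- c(msg, "pstPoint/ciLow/ciHigh must match the grid length")
  }
  vals <- c(object@pstPoint, object@ciLow, object@ciHigh)
  if (any(vals < -1e-12 | vals > 1 + 1e-12, na.rm = TRUE)) {
    msg <- c(msg, "Pst values must lie in [0, 1]")
  }
  if (is.unsorted(object@pstPoint)) {
    msg <- c(msg, "Pst point estimates must be non-decreasing in the ratio")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "PstGrid", function(object) {
  cat(sprintf("Pst grid over %d c/h2 ratios [%.3g, %.3g], %d bootstrap reps (%s unit)\n",
              length(object@ratios), min(object@ratios), max(object@ratios),
              object@nBoot, object@unit))
  if (object@nDegenerate > 0L) {
    cat("  degenerate replicates dropped:", object@nDegenerate, "\n")
  }
  i <- unique(round(seq(1, length(object@ratios), length.out = 5)))
  print(data.frame(ratio = object@ratios[i], pst = round(object@pstPoint[i], 4),
                   ci_low = round(object@ciLow[i], 4),
                   ci_high = round(object@ciHigh[i], 4)))
})

#' Tabulate a PstGrid
#'
#' @param grid a [PstGrid-class]
#' @return data.frame with columns ratio, pst, ci_low, ci_high.
#' @export
pstGridTable <- function(grid) {
  stopifnot(is(grid, "PstGrid"))
  data.frame(ratio = grid@ratios, pst = grid@pstPoint,
             ci_low = grid@ciLow, ci_high = grid@ciHigh)
}

#' MantelResult: permutation test of matrix correlation
#'
#' @slot r Pearson correlation of lower-triangle entries.
#' @slot pValue permutation p-value.
#' @slot nPermutations permutations used (`NA` for exhaustive enumeration).
#' @slot seed RNG seed (`NA` for exhaustive enumeration).
#' @slot alternative "greater", "less" or "two.sided".
#' @seealso [mantelTest()]
#' @export
setClass("MantelResult",
  representation(
    r = "numeric",
    pValue = "numeric",
    nPermutations = "integer",
    seed = "integer",
    alternative = "character"
  )
)

setValidity("MantelResult", function(object) {
  msg <- character()
  if (abs(object@r) > 1 + 1e-12) msg <- c(msg, "r must lie in [-1, 1]")
  if (object@pValue <= 0 || object@pValue > 1) {
    msg <- c(msg, "p-value must lie in (0, 1]")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "MantelResult", function(object) {
  cat(sprintf("Mantel test: r = %.4f, p = %.4g (%s, %s permutations)\n",
              object@r, object@pValue, object@alternative,
              if (is.na(object@nPermutations)) "exhaustive"
              else as.character(object@nPermutations)))
})
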