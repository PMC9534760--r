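#' Linear or quadratic least-squares regression
#'
#' Fits `y ~ x` (degree 1) or `y ~ x + x^2` (degree 2) with an intercept
#' and reports the coefficients, R-squared, the overall F test with
#' degrees of freedom `(degree, n - degree - 1)` and its p-value. The
#' identity `R2 = k F / (k F + df_den)` holds for every fit.
#'
#' @param y response values.
#' @param x predictor values (not constant).
#' @param degree 1 (linear) or 2 (quadratic).
#' @return List with elements `coefficients`, `r2`, `f_stat`, `df`
#'   (numerator, denominator), `p_value`, `residuals` and the underlying
#'   `lm` fit.
#' @export
olsFit <- function(y, x, degree = 1) {
  stopifnot(degree %in% c(1, 2), length(y) == length(x))
  keep <- is.finite(y) & is.finite(x)
  y <- y[keep]; x <- x[keep]
  n <- length(y)
  if (n <= degree + 1) stop("too few observations for the requested degree")
  if (sd(x) == 0) stop("predictor is constant: rank-deficient design")
  fit <- if (degree == 1) lm(y ~ x) else lm(y ~ x + I(x^2))
  if (any(is.na(coef(fit)))) stop("rank-deficient design")
  sm <- summary(fit)
  fs <- sm$fstatistic
  list(coefficients = coef(fit), r2 = sm$r.squared,
       f_stat = unname(fs[1]), df = unname(fs[2:3]),
       p_value = unname(pf(fs[1], fs[2], fs[3], lower.tail = FALSE)),
       residuals = unname(resid(fit)), fit = fit)
}

#' Paired t test
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with `d = x - y` and `df = n - 1`,
#' two-sided p-value.
#'
#' @param x,y paired numeric vectors of equal length (n >= 2).
#' @return List with `statistic`, `df`, `p_value`, `method`.
#' @export
pairedT <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (sd(d) == 0) stop("zero variance of differences: t undefined")
  ht <- t.test(x, y, paired = TRUE)
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value, method = "paired t")
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' `D` is the supremum over the pooled support of the absolute difference
#' of the two empirical CDFs; the p-value uses the asymptotic Kolmogorov
#' distribution with the standard two-sample effective sample size (the
#' small-sample exact computation is deliberately not used, and the method
#' label records that).
#'
#' @param x,y numeric samples (non-empty).
#' @return List with `statistic` (D), `p_value`, `method`.
#' @export
ksTwoSample <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  ht <- suppressWarnings(ks.test(x, y, exact = FALSE))
  list(statistic = unname(ht$statistic), p_value = ht$p.value,
       method = "two-sample Kolmogorov-Smirnov (asymptotic)")
}

#' ANCOVA: population effect on a trait, adjusted for body mass
#'
#' Fits the fixed-effects model `trait ~ population + mass` and reports
#' the partial F test for the population factor given mass, with degrees
#' of freedom `(k - 1, n - k - 1)`, together with the mass slope and its t
#' test from the full model.
#'
#' @param traits data.frame with columns `population`, `trait`, `mass_mg`
#'   and optionally `trait_name`.
#' @param trait optional `trait_name` filter.
#' @return List with `f_stat`, `df`, `p_value` (population test),
#'   `mass_slope`, `mass_t`, `mass_p`, and the full `lm` fit.
#' @export
ancovaPopulationMass <- function(traits, trait = NULL) {
  stopifnot(all(c("population", "trait", "mass_mg") %in% names(traits)))
  if (!is.null(trait) && "trait_name" %in% names(traits)) {
    traits <- traits[traits$trait_name == trait, , drop = FALSE]
  }
  traits <- traits[complete.cases(traits[, c("population", "trait",
                                             "mass_mg")]), ]
  traits$population <- factor(traits$population)
  k <- nlevels(traits$population)
  n <- nrow(traits)
  if (k < 2L) stop("need >= 2 populations")
  if (n - k - 1L <= 0L) stop("non-positive residual degrees of freedom")
  full <- lm(trait ~ population + mass_mg, data = traits)
  red <- lm(trait ~ mass_mg, data = traits)
  cmp <- anova(red, full)
  sm <- coef(summary(full))
  ms <- sm["mass_mg", , drop = TRUE]
  list(f_stat = cmp$F[2], df = c(cmp$Df[2], cmp$Res.Df[2]),
       p_value = cmp$`Pr(>F)`[2],
       mass_slope = unname(ms["Estimate"]), mass_t = unname(ms["t value"]),
       mass_p = unname(ms["Pr(>|t|)"]), fit = full)
}

#' Two-way fixed-effects ANOVA of an acclimation experiment
#'
#' Sequential (Type I) sums of squares in the order population,
#' acclimation temperature, interaction, each tested against the residual
#' mean square. Every population-by-temperature cell must be non-empty.
#'
#' @param table data.frame with columns `population`, `acclimation_c`,
#'   `trait` and optionally `trait_name`.
#' @param trait optional `trait_name` filter.
#' @return data.frame (the ANOVA table) with columns `term`, `df`,
#'   `sum_sq`, `mean_sq`, `f_value`, `p_value`.
#' @export
anovaTwoWay <- function(table, trait = NULL) {
  stopifnot(all(c("population", "acclimation_c", "trait") %in% names(table)))
  if (!is.null(trait) && "trait_name" %in% names(table)) {
    table <- table[table$trait_name == trait, , drop = FALSE]
  }
  table$population <- factor(table$population)
  table$acclimation <- factor(table$acclimation_c)
  if (nlevels(table$population) < 2L || nlevels(table$acclimation) < 2L) {
    stop("need >= 2 levels for both factors")
  }
  cells <- table(table$population, table$acclimation)
  if (any(cells == 0L)) {
    empty <- which(cells == 0L, arr.ind = TRUE)[1, ]
    stop(sprintf("empty cell: population %s at %s degrees C",
                 rownames(cells)[empty[1]], colnames(cells)[empty[2]]))
  }
  fit <- lm(trait ~ population * acclimation, data = table)
  at <- anova(fit)  # sequential Type I in model order
  out <- data.frame(term = c("population", "acclimation", "interaction",
                             "residual"),
                    df = at$Df, sum_sq = at$`Sum Sq`, mean_sq = at$`Mean Sq`,
                    f_value = at$`F value`, p_value = at$`Pr(>F)`,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}
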