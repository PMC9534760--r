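#' Warming tolerance
#'
#' The margin between an organism's critical thermal maximum and the
#' maximum environmental temperature it is exposed to: `ctmax - envMax`.
#' Negative values mean the environment can exceed the tolerated maximum.
#' Vectorised.
#'
#' @param ctmax critical thermal maximum (degrees C).
#' @param envMax maximum exposure temperature, macro (TMAX) or micro
#'   (tmax) scale (degrees C).
#' @return Warming tolerance in degrees C.
#' @export
warmingTolerance <- function(ctmax, envMax) {
  stopifnot(all(is.finite(ctmax)), all(is.finite(envMax)))
  ctmax - envMax
}

#' Cooling tolerance
#'
#' The margin between the minimum environmental temperature and the
#' critical thermal minimum: `envMin - ctmin`. Vectorised.
#'
#' @param ctmin critical thermal minimum (degrees C).
#' @param envMin minimum exposure temperature, macro (TMIN) or micro
#'   (tmin) scale (degrees C).
#' @return Cooling tolerance in degrees C.
#' @export
coolingTolerance <- function(ctmin, envMin) {
  stopifnot(all(is.finite(ctmin)), all(is.finite(envMin)))
  envMin - ctmin
}

#' Vulnerability table: warming and cooling tolerances per population
#'
#' Joins per-population trait means with a climate summary and applies the
#' four identities `WT = CTmax - TMAX`, `wt = CTmax - tmax`,
#' `CT = TMIN - CTmin`, `ct = tmin - CTmin`. Populations missing either a
#' trait mean or a climate row are omitted with a message. Output is
#' sorted by population label, so it is invariant to input order.
#'
#' @param tolerances data.frame with columns `population`, `trait_name`
#'   ("CTmax"/"CTmin") and `mean` (degrees C); a `ToleranceSummary` as
#'   produced by [toleranceSummary()].
#' @param climate data.frame with columns `population`, `TMAX`, `tmax`,
#'   `TMIN`, `tmin` (see [climateSummary()]).
#' @return data.frame with columns `population`, `WT`, `wt`, `CT`, `ct`.
#' @export
vulnerabilityTable <- function(tolerances, climate) {
  stopifnot(all(c("population", "trait_name", "mean") %in% names(tolerances)),
            all(c("population", "TMAX", "tmax", "TMIN", "tmin") %in%
                  names(climate)))
  ctmax <- tolerances[tolerances$trait_name == "CTmax", ]
  ctmin <- tolerances[tolerances$trait_name == "CTmin", ]
  pops <- sort(Reduce(intersect, list(ctmax$population, ctmin$population,
                                      climate$population)))
  dropped <- setdiff(unique(c(tolerances$population, climate$population)),
                     pops)
  if (length(dropped)) {
    message("omitting population(s) with incomplete inputs: ",
            paste(sort(dropped), collapse = ", "))
  }
  if (!length(pops)) stop("no population has both trait means and climate")
  cmax <- ctmax$mean[match(pops, ctmax$population)]
  cmin <- ctmin$mean[match(pops, ctmin$population)]
  cl <- climate[match(pops, climate$population), ]
  data.frame(population = pops,
             WT = warmingTolerance(cmax, cl$TMAX),
             wt = warmingTolerance(cmax, cl$tmax),
             CT = coolingTolerance(cmin, cl$TMIN),
             ct = coolingTolerance(cmin, cl$tmin),
             stringsAsFactors = FALSE)
}

#' Per-population trait means and standard errors
#'
#' @param traits data.frame with columns `population`, `trait` and
#'   optionally `trait_name`.
#' @return data.frame with columns `population`, `trait_name`, `n`,
#'   `mean`, `se`.
#' @export
toleranceSummary <- function(traits) {
  stopifnot(all(c("population", "trait") %in% names(traits)))
  if (!"trait_name" %in% names(traits)) traits$trait_name <- "trait"
  agg <- split(traits, list(traits$population, traits$trait_name),
               drop = TRUE)
  out <- do.call(rbind, lapply(agg, function(d) {
    v <- d$trait[!is.na(d$trait)]
    data.frame(population = d$population[1], trait_name = d$trait_name[1],
               n = length(v), mean = mean(v),
               se = if (length(v) > 1) sd(v) / sqrt(length(v)) else 0,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out[order(out$trait_name, out$population), ]
}

#' Acclimation plasticity range
#'
#' Difference between mean tolerances at the high and low reference
#' acclimation treatments: 27 vs 6 degrees C for CTmax, 27 vs 20 for CTmin
#' (the colder CTmin treatments are freezing-censored, see
#' [censorCtminTrials()]).
#'
#' @param means named numeric: names are acclimation temperatures
#'   (degrees C), values the mean tolerance at each.
#' @param trait "CTmax" or "CTmin" (sets the default treatment pair), or
#'   supply `treatments` directly.
#' @param treatments optional numeric pair `c(high, low)`.
#' @return `mean(high) - mean(low)` in degrees C.
#' @export
plasticityRange <- function(means, trait = c("CTmax", "CTmin"),
                            treatments = NULL) {
  if (is.null(treatments)) {
    trait <- match.arg(trait)
    treatments <- if (trait == "CTmax") c(27, 6) else c(27, 20)
  }
  key <- as.character(treatments)
  have <- as.character(as.numeric(names(means)))
  for (k in key) {
    if (!k %in% have) {
      stop(sprintf("missing acclimation treatment: %s degrees C", k))
    }
  }
  unname(means[[match(key[1], have)]] - means[[match(key[2], have)]])
}

#' Acclimation response ratio (ARR)
#'
#' Standardised acclimation plasticity: the change in a critical thermal
#' limit per degree change in acclimation temperature,
#' `(meanHigh - meanLow) / deltaT`, reported to three decimals by
#' convention.
#'
#' @param meanHigh,meanLow mean tolerance at the warmer / cooler
#'   acclimation treatment (degrees C).
#' @param deltaT difference between the acclimation temperatures
#'   (degrees C, > 0).
#' @param digits rounding applied to the returned slope (default 3;
#'   `NA` for no rounding).
#' @return Dimensionless slope (degrees tolerance per degree acclimation).
#' @export
arr <- function(meanHigh, meanLow, deltaT, digits = 3) {
  if (any(deltaT <= 0)) stop("deltaT must be > 0")
  out <- (meanHigh - meanLow) / deltaT
  if (!is.na(digits)) out <- round(out, digits)
  out
}

#' Apply the CTmin freezing-censoring rule to an acclimation table
#'
#' CTmin assays at cold acclimation treatments often hit the freezing
#' point of water before the endpoint, leaving the true CTmin inestimable
#' (right-censored downwards). This removes CTmin rows whose acclimation
#' temperature is outside `allowedTreatments` (default 20 and 27 degrees
#' C) and any row flagged `censored`, and reports the counts removed by
#' reason. Non-CTmin rows pass through untouched.
#'
#' @param table data.frame with columns `trait_name`, `acclimation_c` and
#'   optionally `censored` (logical).
#' @param allowedTreatments acclimation temperatures retained for CTmin.
#' @return The filtered table, with attribute `removed` =
#'   `c(treatment = ..., censored = ...)`.
#' @export
censorCtminTrials <- function(table, allowedTreatments = c(20, 27)) {
  stopifnot(all(c("trait_name", "acclimation_c") %in% names(table)))
  if (!any(table$trait_name == "CTmin")) {
    stop("table contains no CTmin rows")
  }
  if (!"censored" %in% names(table)) table$censored <- FALSE
  isMin <- table$trait_name == "CTmin"
  dropTreat <- isMin & !(table$acclimation_c %in% allowedTreatments)
  dropCens <- isMin & !dropTreat & table$censored
  out <- table[!(dropTreat | dropCens), , drop = FALSE]
  if (!any(out$trait_name == "CTmin")) {
    stop("all CTmin rows removed by the censoring policy")
  }
  rownames(out) <- NULL
  attr(out, "removed") <- c(treatment = sum(dropTreat),
                            censored = sum(dropCens))
  out
}
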