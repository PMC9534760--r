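## Synthetic data with known ground truth.
##
## One global seed expands into fixed per-generator child seeds, so adding
## or re-running one generator never perturbs the streams of the others.

.CHILD_SEED_OFFSET <- c(genotypes = 101L, traits = 211L, logger = 307L,
                        acclimation = 401L, bundle = 503L)

.childSeed <- function(seed, component) {
  offset <- .CHILD_SEED_OFFSET[[component]]
  as.integer((as.numeric(seed) + offset) %% (.Machine$integer.max - 1))
}

#' Configuration for the synthetic-data generators
#'
#' Collects the ground-truth parameters shared by [simulateGenotypes()],
#' [simulateTraits()], [simulateLoggerSeries()] and
#' [simulateAcclimation()]. Every generator is fully deterministic given
#' `seed`.
#'
#' @param nPopulations number of populations.
#' @param nPerPop individuals per population (per data kind). May be a
#'   vector of length `nPopulations` for unbalanced designs.
#' @param nLoci number of marker loci.
#' @param allelesPerLocus alleles segregating per locus (>= 2).
#' @param targetFst island-model differentiation parameter F in [0, 1).
#' @param ancestralFreqs optional list of per-locus ancestral allele
#'   frequency vectors (each summing to 1); defaults to equifrequent.
#' @param sigmaB2,sigmaW2 between- and within-population trait variances
#'   (trait units squared).
#' @param grandMean grand mean of the trait (trait units).
#' @param massSlope optional per-mg effect of body mass on the trait
#'   (default 0: mass independent of trait).
#' @param loggerParams list with elements `mean`, `seasonalAmplitude`,
#'   `dielAmplitude`, `noiseSd` (degrees C), `intervalMin` (sampling
#'   interval, minutes, in [1, 120]), `startDate`, `endDate` (Dates or
#'   "YYYY-MM-DD"), and optional phases `seasonalPhaseDay`,
#'   `dielPhaseHour`.
#' @param arrTrue per-population acclimation slope (degrees tolerance per
#'   degree acclimation); recycled to `nPopulations`.
#' @param acclimationTemps acclimation treatment temperatures (degrees C).
#' @param seed integer seed; fully determines all generator output.
#' @return A validated list of class `SimulationConfig`.
#' @export
simulationConfig <- function(nPopulations = 11, nPerPop = 20, nLoci = 6,
                             allelesPerLocus = 8, targetFst = 0.066,
                             ancestralFreqs = NULL,
                             sigmaB2 = 1, sigmaW2 = 1, grandMean = 0,
                             massSlope = 0,
                             loggerParams = list(),
                             arrTrue = 0.1,
                             acclimationTemps = c(6, 13, 20, 27),
                             seed = 1L) {
  lp <- modifyList(list(mean = 12, seasonalAmplitude = 6, dielAmplitude = 4,
                        noiseSd = 0.5, intervalMin = 30,
                        startDate = "2013-05-01", endDate = "2013-08-31",
                        seasonalPhaseDay = 0, dielPhaseHour = 9),
                   loggerParams)
  lp$startDate <- as.Date(lp$startDate)
  lp$endDate <- as.Date(lp$endDate)
  cfg <- list(nPopulations = as.integer(nPopulations),
              nPerPop = as.integer(nPerPop),
              nLoci = as.integer(nLoci),
              allelesPerLocus = as.integer(allelesPerLocus),
              targetFst = targetFst, ancestralFreqs = ancestralFreqs,
              sigmaB2 = sigmaB2, sigmaW2 = sigmaW2, grandMean = grandMean,
              massSlope = massSlope, loggerParams = lp,
              arrTrue = rep_len(arrTrue, nPopulations),
              acclimationTemps = acclimationTemps,
              seed = as.integer(seed))
  .validateConfig(cfg)
  class(cfg) <- "SimulationConfig"
  cfg
}

.validateConfig <- function(cfg) {
  stopifnot(cfg$nPopulations >= 1L, all(cfg$nPerPop >= 1L), cfg$nLoci >= 1L)
  if (cfg$targetFst < 0 || cfg$targetFst >= 1) {
    stop("targetFst must lie in [0, 1)")
  }
  if (cfg$allelesPerLocus < 2L) stop("allelesPerLocus must be >= 2")
  if (cfg$sigmaB2 < 0 || cfg$sigmaW2 < 0) {
    stop("variance components must be non-negative")
  }
  if (!is.null(cfg$ancestralFreqs)) {
    if (length(cfg$ancestralFreqs) != cfg$nLoci) {
      stop("ancestralFreqs must have one vector per locus")
    }
    ok <- vapply(cfg$ancestralFreqs,
                 function(p) all(p > 0) && abs(sum(p) - 1) < 1e-9, logical(1))
    if (!all(ok)) stop("each ancestral frequency vector must sum to 1")
  }
  lp <- cfg$loggerParams
  if (lp$intervalMin < 1 || lp$intervalMin > 120) {
    stop("logger sampling interval must lie in [1, 120] minutes")
  }
  if (as.numeric(lp$endDate - lp$startDate) < 2) {
    stop("logger span must cover at least 2 days")
  }
  if (lp$noiseSd < 0) stop("logger noise sd must be non-negative")
  invisible(cfg)
}

.popLabels <- function(k) sprintf("pop%02d", seq_len(k))

.rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) { # numerically possible for tiny alpha
    g[which.max(alpha)] <- 1
  }
  g / sum(g)
}

#' Simulate genotypes under the Balding-Nichols island model
#'
#' Per-locus population allele frequencies are drawn from a Dirichlet with
#' parameters `p_a * (1 - F) / F` around the ancestral frequencies `p_a`
#' (F = `targetFst`), so the expected Weir-Cockerham theta is approximately
#' F. Diploid genotypes are then drawn under within-population
#' Hardy-Weinberg proportions. `targetFst = 0` copies the ancestral
#' frequencies to every population (panmixia).
#'
#' @param config a [simulationConfig()].
#' @return A [GenotypeDataset-class].
#' @export
simulateGenotypes <- function(config) {
  stopifnot(inherits(config, "SimulationConfig"))
  set.seed(.childSeed(config$seed, "genotypes"))
  k <- config$nPopulations
  nper <- rep_len(config$nPerPop, k)
  L <- config$nLoci
  A <- config$allelesPerLocus
  anc <- config$ancestralFreqs
  if (is.null(anc)) anc <- replicate(L, rep(1 / A, A), simplify = FALSE)
  FST <- config$targetFst
  n <- sum(nper)
  calls <- matrix(NA_integer_, n, 2L * L)
  pop <- factor(rep(.popLabels(k), nper), levels = .popLabels(k))
  for (l in seq_len(L)) {
    pa <- anc[[l]]
    row0 <- 0L
    for (i in seq_len(k)) {
      pi <- if (FST == 0) pa else .rdirichlet1(pa * (1 - FST) / FST)
      m <- nper[i]
      draws <- sample.int(length(pi), size = 2L * m, replace = TRUE, prob = pi)
      calls[row0 + seq_len(m), 2L * l - 1L] <- draws[seq_len(m)]
      calls[row0 + seq_len(m), 2L * l] <- draws[m + seq_len(m)]
      row0 <- row0 + m
    }
  }
  GenotypeDataset(calls, pop, sprintf("locus%02d", seq_len(L)),
                  sprintf("%s_i%03d", pop, unlist(lapply(nper, seq_len))))
}

#' Simulate a hierarchical trait table
#'
#' Population effects are N(0, `sigmaB2`), residuals N(0, `sigmaW2`), so
#' the generative Pst at ratio r is `r * sigmaB2 / (r * sigmaB2 +
#' 2 * sigmaW2)`. Body mass is lognormal and independent of the trait
#' unless `massSlope` is non-zero.
#'
#' @param config a [simulationConfig()].
#' @param traitName label written into the `trait_name` column.
#' @return data.frame with columns `individual_id`, `population`, `trait`,
#'   `trait_name`, `mass_mg`.
#' @export
simulateTraits <- function(config, traitName = "CTmax") {
  stopifnot(inherits(config, "SimulationConfig"))
  if (any(rep_len(config$nPerPop, config$nPopulations) < 2L)) {
    stop("need at least 2 individuals per population")
  }
  set.seed(.childSeed(config$seed, "traits"))
  k <- config$nPopulations
  nper <- rep_len(config$nPerPop, k)
  u <- rnorm(k, 0, sqrt(config$sigmaB2))
  pop <- rep(.popLabels(k), nper)
  e <- rnorm(sum(nper), 0, sqrt(config$sigmaW2))
  mass <- rlnorm(sum(nper), meanlog = log(150), sdlog = 0.3)
  y <- config$grandMean + rep(u, nper) + e + config$massSlope * (mass - 150)
  data.frame(
    individual_id = sprintf("%s_t%03d", pop, unlist(lapply(nper, seq_len))),
    population = pop, trait = y, trait_name = traitName, mass_mg = mass,
    stringsAsFactors = FALSE)
}

#' Simulate a pond datalogger temperature series
#'
#' T(t) = mean + A_seasonal sin(2 pi (doy - phase_s) / 365) +
#' A_diel sin(2 pi (hour - phase_d) / 24) + Normal(0, noiseSd^2), sampled
#' on a strictly increasing, evenly spaced timestamp grid.
#'
#' @param config a [simulationConfig()].
#' @param population label attached to the series.
#' @return data.frame with columns `timestamp` (POSIXct, UTC) and
#'   `temp_c`, with attribute `population`.
#' @export
simulateLoggerSeries <- function(config, population = "pop01") {
  stopifnot(inherits(config, "SimulationConfig"))
  lp <- config$loggerParams
  set.seed(.childSeed(config$seed, "logger"))
  t0 <- as.POSIXct(paste(lp$startDate, "00:00:00"), tz = "UTC")
  t1 <- as.POSIXct(paste(lp$endDate, "23:59:59"), tz = "UTC")
  ts <- seq(t0, t1, by = lp$intervalMin * 60)
  doy <- as.numeric(strftime(ts, "%j", tz = "UTC"))
  hour <- as.numeric(ts - trunc(ts, "days"), units = "hours")
  temp <- lp$mean +
    lp$seasonalAmplitude * sin(2 * pi * (doy - lp$seasonalPhaseDay) / 365) +
    lp$dielAmplitude * sin(2 * pi * (hour - lp$dielPhaseHour) / 24) +
    rnorm(length(ts), 0, lp$noiseSd)
  out <- data.frame(timestamp = ts, temp_c = temp)
  attr(out, "population") <- population
  out
}

#' Simulate an acclimation experiment
#'
#' Individual tolerance = population intercept + arrTrue[pop] *
#' (T_acc - 20) + Normal(0, sigmaW2). Population intercepts are
#' `grandMean` + N(0, sigmaB2). Group sizes follow `nPerPop` and may be
#' unbalanced via `nPerGroup`.
#'
#' @param config a [simulationConfig()].
#' @param traitName "CTmax" or "CTmin".
#' @param nPerGroup optional matrix (`nPopulations x n_temps`) of group
#'   sizes; defaults to `nPerPop` everywhere.
#' @return data.frame with columns `individual_id`, `population`,
#'   `acclimation_c`, `trait`, `trait_name`, `censored`.
#' @export
simulateAcclimation <- function(config, traitName = "CTmax",
                                nPerGroup = NULL) {
  stopifnot(inherits(config, "SimulationConfig"))
  temps <- config$acclimationTemps
  if (length(temps) < 2L) stop("need at least 2 acclimation temperatures")
  set.seed(.childSeed(config$seed, "acclimation"))
  k <- config$nPopulations
  if (is.null(nPerGroup)) {
    nPerGroup <- matrix(rep_len(config$nPerPop, k), k, length(temps))
  }
  stopifnot(nrow(nPerGroup) == k, ncol(nPerGroup) == length(temps))
  intercepts <- config$grandMean + rnorm(k, 0, sqrt(config$sigmaB2))
  rows <- list()
  for (i in seq_len(k)) {
    for (j in seq_along(temps)) {
      m <- nPerGroup[i, j]
      if (m == 0L) next
      y <- intercepts[i] + config$arrTrue[i] * (temps[j] - 20) +
        rnorm(m, 0, sqrt(config$sigmaW2))
      rows[[length(rows) + 1L]] <- data.frame(
        population = .popLabels(k)[i], acclimation_c = temps[j], trait = y,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  out$individual_id <- sprintf("%s_a%04d", out$population,
                               stats::ave(seq_len(nrow(out)), out$population,
                                          FUN = seq_along))
  out$trait_name <- traitName
  out$censored <- FALSE
  out[, c("individual_id", "population", "acclimation_c", "trait",
          "trait_name", "censored")]
}

#' Write a full synthetic input bundle to disk
#'
#' Produces every file the pipeline consumes: a GENEPOP genotype file,
#' trait CSVs for CTmax and CTmin, one logger CSV per population, a
#' macroclimate monthly table, a phenology-window table and an acclimation
#' CSV. Intended for end-to-end tests and demonstrations.
#'
#' @param config a [simulationConfig()].
#' @param dir output directory (created if needed).
#' @return Invisibly, a named list of the file paths written.
#' @export
writeSyntheticBundle <- function(config, dir) {
  stopifnot(inherits(config, "SimulationConfig"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  k <- config$nPopulations
  pops <- .popLabels(k)
  paths <- list()

  geno <- simulateGenotypes(config)
  # GENEPOP stores no population names; by convention readers label each
  # block with its last individual id, so name those ids after the pops
  for (p in pops) {
    geno@individualIds[max(which(geno@population == p))] <- p
  }
  paths$genotypes <- file.path(dir, "genotypes.gen")
  writeGenepop(geno, paths$genotypes, title = "synthetic island model")

  for (tn in c("CTmax", "CTmin")) {
    cfg_t <- config
    cfg_t$seed <- .childSeed(config$seed, "bundle") +
      if (tn == "CTmax") 0L else 1L
    tr <- simulateTraits(cfg_t, traitName = tn)
    p <- file.path(dir, sprintf("traits_%s.csv", tolower(tn)))
    write.csv(tr, p, row.names = FALSE)
    paths[[paste0("traits_", tolower(tn))]] <- p
  }

  dir.create(file.path(dir, "loggers"), showWarnings = FALSE)
  for (i in seq_len(k)) {
    cfg_i <- config
    cfg_i$seed <- config$seed + i
    s <- simulateLoggerSeries(cfg_i, population = pops[i])
    p <- file.path(dir, "loggers", paste0(pops[i], ".csv"))
    write.csv(data.frame(timestamp = strftime(s$timestamp,
                                              "%Y-%m-%dT%H:%M:%S",
                                              tz = "UTC"),
                         temp_c = s$temp_c), p, row.names = FALSE)
    paths$loggers <- file.path(dir, "loggers")
  }

  lp <- config$loggerParams
  macro <- do.call(rbind, lapply(seq_len(k), function(i) {
    m <- 1:12
    mid <- (m - 0.5) * 365 / 12
    seas <- lp$seasonalAmplitude * sin(2 * pi * (mid - lp$seasonalPhaseDay) / 365)
    data.frame(population = pops[i], month = m,
               tmax_c = lp$mean + seas + lp$dielAmplitude + 2,
               tmin_c = lp$mean + seas - lp$dielAmplitude - 2)
  }))
  paths$macro <- file.path(dir, "macro_monthly.csv")
  write.csv(macro, paths$macro, row.names = FALSE)

  phen <- data.frame(population = pops,
                     start = format(lp$startDate, "%m-%d"),
                     end = format(lp$endDate, "%m-%d"))
  paths$phenology <- file.path(dir, "phenology.csv")
  write.csv(phen, paths$phenology, row.names = FALSE)

  acc <- simulateAcclimation(config, traitName = "CTmax")
  paths$acclimation <- file.path(dir, "acclimation.csv")
  write.csv(acc, paths$acclimation, row.names = FALSE)

  invisible(paths)
}
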