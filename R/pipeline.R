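## End-to-end orchestration: climate -> vulnerability -> Fst -> Pst (per
## trait, with critical c/h2 ratio) -> Mantel -> stats battery ->
## plasticity. Stages communicate only through their serialized outputs;
## stages whose inputs are absent from the config are skipped and
## recorded, while a failure inside a stage aborts the run after writing
## the manifest.

.readRunConfig <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  defaults <- list(out = "thermocline_out", seed = 1L,
                   n_boot_fst = 1000L, n_boot_pst = 1000L,
                   ratio = 1, ratios = list(from = 0.05, to = 2, by = 0.05),
                   pst_unit = "population", alias = NULL,
                   mantel_permutations = 999L)
  cfg <- modifyList(defaults, config)
  pathKeys <- c("genotypes", "traits_ctmax", "traits_ctmin", "loggers",
                "macro", "phenology", "acclimation", "sites")
  for (k in intersect(pathKeys, names(cfg))) {
    if (!is.null(cfg[[k]]) && !file.exists(cfg[[k]])) {
      stop("configured path does not exist: ", k, " = ", cfg[[k]])
    }
  }
  cfg
}

.stageLog <- function(quiet, ...) if (!quiet) message("[thermocline] ", ...)

#' Run the full analysis pipeline from a config
#'
#' Executes every stage whose inputs are configured and writes one CSV or
#' JSON artifact per stage plus a `manifest.json` recording inputs, seeds
#' and per-stage status. Outputs are deterministic given the config and
#' seeds (no wall-clock content). Config keys (all paths optional unless a
#' stage needs them): `genotypes` (GENEPOP), `traits_ctmax`,
#' `traits_ctmin` (trait CSVs), `loggers` (directory of per-population
#' CSVs), `macro`, `phenology`, `acclimation`, `sites` (population,
#' elevation_m), `alias` (named list, logger donors), `out`, `seed`,
#' `n_boot_fst`, `n_boot_pst`, `ratio`, `ratios` (from/to/by),
#' `pst_unit`, `mantel_permutations`.
#'
#' @param config a named list or the path to a YAML file.
#' @param quiet suppress per-stage progress messages.
#' @return Invisibly, the manifest list.
#' @export
runPipeline <- function(config, quiet = FALSE) {
  cfg <- .readRunConfig(config)
  dir.create(cfg$out, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config = cfg[setdiff(names(cfg), "alias")],
                   stages = list())
  outputs <- character(0)

  record <- function(name, status, output = NULL, note = NULL) {
    manifest$stages[[name]] <<- list(status = status, output = output,
                                     note = note)
    if (!is.null(output)) outputs <<- c(outputs, output)
  }
  finishManifest <- function() {
    manifest$outputs <- outputs
    jsonlite::write_json(manifest, file.path(cfg$out, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
    manifest
  }
  runStage <- function(name, needs, fn) {
    missing <- needs[!vapply(needs, function(k) !is.null(cfg[[k]]),
                             logical(1))]
    if (length(missing)) {
      .stageLog(quiet, name, ": skipped (missing input: ",
                paste(missing, collapse = ", "), ")")
      record(name, "skipped", note = paste("missing input:",
                                           paste(missing, collapse = ", ")))
      return(NULL)
    }
    .stageLog(quiet, name, ": running")
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      record(name, "error", note = conditionMessage(res))
      finishManifest()
      stop("stage '", name, "' failed: ", conditionMessage(res))
    }
    record(name, "ok", output = res)
    res
  }

  env <- new.env(parent = emptyenv())

  runStage("climate", c("loggers", "macro", "phenology"), function() {
    files <- list.files(cfg$loggers, pattern = "\\.csv$", full.names = TRUE)
    loggers <- lapply(files, readLoggerCSV)
    names(loggers) <- sub("\\.csv$", "", basename(files))
    macro <- read.csv(cfg$macro, stringsAsFactors = FALSE)
    phen <- read.csv(cfg$phenology, stringsAsFactors = FALSE,
                     colClasses = "character")
    alias <- if (is.null(cfg$alias)) NULL else unlist(cfg$alias)
    cs <- climateSummary(loggers, macro, phen, aliasMap = alias)
    env$climate <- cs
    p <- file.path(cfg$out, "climate.csv")
    write.csv(cs, p, row.names = FALSE)
    p
  })

  runStage("vulnerability", c("traits_ctmax", "traits_ctmin"), function() {
    if (is.null(env$climate)) stop("climate stage did not run")
    tmax <- read.csv(cfg$traits_ctmax, stringsAsFactors = FALSE)
    tmin <- read.csv(cfg$traits_ctmin, stringsAsFactors = FALSE)
    tmax$trait_name <- "CTmax"; tmin$trait_name <- "CTmin"
    tol <- toleranceSummary(rbind(tmax, tmin))
    env$vuln <- vulnerabilityTable(tol, env$climate)
    p <- file.path(cfg$out, "vulnerability.csv")
    write.csv(env$vuln, p, row.names = FALSE)
    p
  })

  runStage("fst", "genotypes", function() {
    geno <- readGenepop(cfg$genotypes)
    fst <- fstEstimate(geno, nBoot = cfg$n_boot_fst, seed = cfg$seed)
    env$fst <- fst
    p <- file.path(cfg$out, "fst.json")
    writeFstResult(fst, jsonPath = p,
                   csvPath = file.path(cfg$out, "fst_per_locus.csv"))
    p
  })

  for (tn in c("CTmax", "CTmin")) {
    key <- paste0("traits_", tolower(tn))
    runStage(paste0("pst_", tn), key, function() {
      tr <- read.csv(cfg[[key]], stringsAsFactors = FALSE)
      ratios <- seq(cfg$ratios$from, cfg$ratios$to, by = cfg$ratios$by)
      grid <- pstBootstrapCI(tr, ratios = ratios, nBoot = cfg$n_boot_pst,
                             seed = cfg$seed, unit = cfg$pst_unit)
      env[[paste0("pst_", tn)]] <- grid
      env[[paste0("traits_", tn)]] <- tr
      p <- file.path(cfg$out, sprintf("pst_%s.csv", tolower(tn)))
      write.csv(pstGridTable(grid), p, row.names = FALSE)
      summ <- list(trait = tn, n_boot = grid@nBoot, unit = grid@unit,
                   n_degenerate = grid@nDegenerate, seed = grid@seed)
      if (!is.null(env$fst)) {
        summ$fst_upper <- env$fst@ciHigh
        summ$critical_ch2_ratio <- criticalCH2Ratio(grid, env$fst@ciHigh)
      }
      jsonlite::write_json(summ,
                           file.path(cfg$out,
                                     sprintf("pst_%s.json", tolower(tn))),
                           auto_unbox = TRUE, digits = NA)
      p
    })
  }

  runStage("mantel", c("genotypes", "traits_ctmax"), function() {
    if (is.null(env$fst)) stop("fst stage did not run")
    res <- list()
    for (tn in c("CTmax", "CTmin")) {
      tr <- env[[paste0("traits_", tn)]]
      if (is.null(tr)) next
      pst <- pairwisePstMatrix(tr, ratio = cfg$ratio)
      fstM <- pairwiseMatrix(env$fst)
      common <- intersect(rownames(pst), rownames(fstM))
      if (length(common) < 3L) stop("need >= 3 shared populations")
      mt <- mantelTest(pst[common, common], fstM[common, common],
                       nPermutations = cfg$mantel_permutations,
                       seed = cfg$seed)
      res[[tn]] <- list(r = mt@r, p_value = mt@pValue,
                        n_permutations = mt@nPermutations)
    }
    p <- file.path(cfg$out, "mantel.json")
    jsonlite::write_json(res, p, auto_unbox = TRUE, digits = NA)
    p
  })

  runStage("stats", c("traits_ctmax", "traits_ctmin"), function() {
    if (is.null(env$vuln)) stop("vulnerability stage did not run")
    v <- env$vuln
    res <- list(
      paired_t_WT_wt = pairedT(v$WT, v$wt)[c("statistic", "df", "p_value")],
      ks_WT_wt = ksTwoSample(v$WT, v$wt)[c("statistic", "p_value")],
      paired_t_CT_ct = pairedT(v$CT, v$ct)[c("statistic", "df", "p_value")],
      ks_CT_ct = ksTwoSample(v$CT, v$ct)[c("statistic", "p_value")])
    if (!is.null(cfg$sites)) {
      sites <- read.csv(cfg$sites, stringsAsFactors = FALSE)
      el <- sites$elevation_m[match(v$population, sites$population)]
      for (col in c("WT", "wt", "CT", "ct")) {
        f1 <- olsFit(v[[col]], el, degree = 1)
        f2 <- olsFit(v[[col]], el, degree = 2)
        res[[paste0(col, "_vs_elevation")]] <-
          list(linear = f1[c("r2", "f_stat", "df", "p_value")],
               quadratic = f2[c("r2", "f_stat", "df", "p_value")])
      }
    }
    p <- file.path(cfg$out, "stats.json")
    jsonlite::write_json(res, p, auto_unbox = TRUE, digits = NA)
    p
  })

  runStage("plasticity", "acclimation", function() {
    acc <- read.csv(cfg$acclimation, stringsAsFactors = FALSE)
    rows <- lapply(split(acc, acc$population), function(d) {
      mns <- tapply(d$trait, d$acclimation_c, mean)
      tn <- if ("trait_name" %in% names(d)) d$trait_name[1] else "CTmax"
      hi <- max(as.numeric(names(mns))); lo <- min(as.numeric(names(mns)))
      data.frame(population = d$population[1], trait_name = tn,
                 plasticity = tryCatch(plasticityRange(mns, tn),
                                       error = function(e) NA_real_),
                 arr = arr(mns[[as.character(hi)]], mns[[as.character(lo)]],
                           hi - lo),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    p <- file.path(cfg$out, "plasticity.csv")
    write.csv(out, p, row.names = FALSE)
    p
  })

  m <- finishManifest()
  .stageLog(quiet, "done: ", length(outputs), " stage output(s) in ", cfg$out)
  invisible(m)
}
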