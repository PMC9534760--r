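#' Read a GENEPOP genotype file
#'
#' Parses the classic GENEPOP dialect: a title line, one locus name per
#' line (or a single comma-separated line), `POP` separators, and
#' individual lines of the form `id , 0101 0202 ...`. Both 2-digit and
#' 3-digit allele encodings are accepted and detected automatically from
#' token length; an allele code of zero marks a missing call. Population
#' labels are taken from the id of the last individual in each block (the
#' usual GENEPOP convention) unless `popNames` overrides them.
#'
#' @param path path to a GENEPOP file.
#' @param popNames optional character vector of population labels, one per
#'   `POP` block, overriding the last-individual convention.
#' @return A [GenotypeDataset-class].
#' @export
readGenepop <- function(path, popNames = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  if (length(lines) < 3L) stop("not a GENEPOP file: fewer than 3 lines")
  isPop <- grepl("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  if (!any(isPop)) stop("not a GENEPOP file: no POP section found")
  firstPop <- which(isPop)[1]
  headerLines <- lines[2:(firstPop - 1L)]
  lociNames <- trimws(unlist(strsplit(headerLines, ",")))
  lociNames <- lociNames[nzchar(lociNames)]
  if (!length(lociNames)) stop("no locus names found before first POP")
  L <- length(lociNames)

  popIdx <- cumsum(isPop)
  body <- which(!isPop & seq_along(lines) > firstPop - 1L &
                  nzchar(trimws(lines)))
  ids <- character(0); popOf <- integer(0)
  tokens <- list()
  digits <- NA_integer_
  for (i in body) {
    parts <- strsplit(lines[i], ",", fixed = TRUE)[[1]]
    if (length(parts) < 2L) {
      stop(sprintf("line %d: expected 'id , genotypes'", i))
    }
    id <- trimws(parts[1])
    toks <- strsplit(trimws(paste(parts[-1], collapse = " ")),
                     "[ \t]+")[[1]]
    toks <- toks[nzchar(toks)]
    if (length(toks) != L) {
      stop(sprintf("line %d: expected %d genotype tokens, found %d",
                   i, L, length(toks)))
    }
    len <- nchar(toks)
    if (any(len %% 2L != 0L)) {
      stop(sprintf("line %d: genotype token of odd length", i))
    }
    if (length(unique(len)) != 1L || !(len[1] %in% c(4L, 6L))) {
      stop(sprintf("line %d: genotype tokens must all be 4 or 6 characters",
                   i))
    }
    d <- len[1] / 2L
    if (is.na(digits)) digits <- d
    else if (digits != d) {
      stop(sprintf("line %d: mixed 2- and 3-digit allele encodings", i))
    }
    ids <- c(ids, id)
    popOf <- c(popOf, popIdx[i])
    tokens[[length(tokens) + 1L]] <- toks
  }
  if (!length(ids)) stop("no individuals found")

  calls <- matrix(NA_integer_, length(ids), 2L * L)
  for (j in seq_along(tokens)) {
    toks <- tokens[[j]]
    a1 <- as.integer(substr(toks, 1L, digits))
    a2 <- as.integer(substr(toks, digits + 1L, 2L * digits))
    miss <- is.na(a1) | is.na(a2) | a1 == 0L | a2 == 0L
    a1[miss] <- NA_integer_; a2[miss] <- NA_integer_
    calls[j, seq(1L, 2L * L, by = 2L)] <- a1
    calls[j, seq(2L, 2L * L, by = 2L)] <- a2
  }

  nPops <- max(popOf)
  if (is.null(popNames)) {
    popNames <- vapply(seq_len(nPops),
                       function(p) ids[max(which(popOf == p))], character(1))
    popNames <- make.unique(popNames, sep = "_")
  }
  if (length(popNames) != nPops) {
    stop("popNames must have one label per POP block")
  }
  if (anyDuplicated(ids)) ids <- make.unique(ids, sep = "_dup")
  GenotypeDataset(calls, factor(popNames[popOf], levels = popNames),
                  lociNames, ids)
}

#' Write a GenotypeDataset to a GENEPOP file
#'
#' @param x a [GenotypeDataset-class].
#' @param path output path.
#' @param title first line of the file.
#' @param digits allele-code width, 2 or 3; `NULL` picks 2 unless any
#'   allele code exceeds 99.
#' @return Invisibly, `path`.
#' @export
writeGenepop <- function(x, path, title = "thermocline export",
                         digits = NULL) {
  stopifnot(is(x, "GenotypeDataset"))
  maxCode <- suppressWarnings(max(x@calls, na.rm = TRUE))
  if (is.null(digits)) digits <- if (!is.finite(maxCode) || maxCode <= 99L) 2L else 3L
  if (!digits %in% c(2L, 3L)) stop("digits must be 2 or 3")
  if (is.finite(maxCode) && maxCode >= 10^digits) {
    stop("allele codes too large for the chosen digit width")
  }
  fmt <- sprintf("%%0%dd", digits)
  enc <- function(a) ifelse(is.na(a), strrep("0", digits), sprintf(fmt, a))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(x@loci, con)
  L <- length(x@loci)
  for (p in levels(x@population)) {
    writeLines("POP", con)
    rows <- which(x@population == p)
    for (r in rows) {
      toks <- vapply(seq_len(L), function(l) {
        paste0(enc(x@calls[r, 2L * l - 1L]), enc(x@calls[r, 2L * l]))
      }, character(1))
      writeLines(paste(x@individualIds[r], ",", paste(toks, collapse = " ")),
                 con)
    }
  }
  invisible(path)
}
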