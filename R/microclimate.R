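#' Read a datalogger temperature series from CSV
#'
#' Expects a header with an ISO-8601 timestamp column and a numeric
#' temperature column (by default `timestamp` and `temp_c`; the first two
#' columns are used as a fallback). Rows are sorted by time; duplicate
#' timestamps are collapsed to their mean with a warning; temperatures
#' outside a (-40, 60) degrees C sanity band are flagged with a warning.
#'
#' @param path CSV path.
#' @param population optional population label attached to the series.
#' @param tz timezone for parsing (default UTC).
#' @return data.frame with columns `timestamp` (POSIXct) and `temp_c`,
#'   attribute `population`.
#' @export
readLoggerCSV <- function(path, population = NULL, tz = "UTC") {
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty logger file: ", path)
  tsCol <- if ("timestamp" %in% names(df)) "timestamp" else names(df)[1]
  tCol <- if ("temp_c" %in% names(df)) "temp_c" else names(df)[2]
  raw <- df[[tsCol]]
  ts <- as.POSIXct(rep(NA_real_, length(raw)), origin = "1970-01-01",
                   tz = tz)
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    miss <- is.na(ts)
    if (!any(miss)) break
    ts[miss] <- as.POSIXct(strptime(raw[miss], fmt, tz = tz), tz = tz)
  }
  if (anyNA(ts)) {
    stop(sprintf("unparseable timestamp at line %d of %s",
                 which(is.na(ts))[1] + 1L, path))
  }
  temp <- as.numeric(df[[tCol]])
  if (anyNA(temp)) {
    stop(sprintf("non-numeric temperature at line %d of %s",
                 which(is.na(temp))[1] + 1L, path))
  }
  if (is.unsorted(ts)) {
    warning("logger records out of order; sorting by timestamp")
    o <- order(ts); ts <- ts[o]; temp <- temp[o]
  }
  if (anyDuplicated(ts)) {
    warning("duplicate timestamps collapsed by mean")
    temp <- as.numeric(tapply(temp, as.numeric(ts), mean))
    ts <- as.POSIXct(sort(unique(as.numeric(ts))), origin = "1970-01-01",
                     tz = tz)
  }
  nOut <- sum(temp <= -40 | temp >= 60)
  if (nOut > 0L) {
    warning(sprintf("%d temperature(s) outside the (-40, 60) C sanity band",
                    nOut))
  }
  out <- data.frame(timestamp = ts, temp_c = temp)
  attr(out, "population") <- population
  out
}

#' Define a phenology (larval-period) window
#'
#' Windows are recurring calendar intervals given as month-day endpoints
#' (inclusive). `start > end` means the window wraps 31 December, e.g. the
#' autumn-to-spring larval period of lowland breeders.
#'
#' @param start,end "MM-DD" strings, or Dates (the year is ignored).
#' @param population optional label.
#' @return A list of class `PhenologyWindow` with integer month-day codes.
#' @export
phenologyWindow <- function(start, end, population = NULL) {
  md <- function(v) {
    if (inherits(v, "Date")) {
      return(as.integer(format(v, "%m")) * 100L + as.integer(format(v, "%d")))
    }
    p <- as.integer(strsplit(as.character(v), "-", fixed = TRUE)[[1]])
    if (length(p) == 3L) p <- p[2:3]  # tolerate YYYY-MM-DD
    if (length(p) != 2L || anyNA(p) || p[1] < 1L || p[1] > 12L ||
        p[2] < 1L || p[2] > 31L) {
      stop("window endpoints must be 'MM-DD' or Dates")
    }
    p[1] * 100L + p[2]
  }
  w <- list(start = md(start), end = md(end), population = population)
  class(w) <- "PhenologyWindow"
  w
}

.inWindow <- function(mdCodes, window) {
  if (window$start <= window$end) {
    mdCodes >= window$start & mdCodes <= window$end
  } else {
    mdCodes >= window$start | mdCodes <= window$end
  }
}

#' Clip a logger series to a phenology window
#'
#' Retains records whose calendar date falls inside the (possibly
#' year-wrapping) window.
#'
#' @param series logger data.frame (`timestamp`, `temp_c`).
#' @param window a [phenologyWindow()].
#' @return The clipped series (error if no records overlap the window).
#' @export
clipToWindow <- function(series, window) {
  stopifnot(inherits(window, "PhenologyWindow"), nrow(series) > 0)
  md <- as.integer(strftime(series$timestamp, "%m", tz = "UTC")) * 100L +
    as.integer(strftime(series$timestamp, "%d", tz = "UTC"))
  keep <- .inWindow(md, window)
  if (!any(keep)) stop("no overlap between the series and the window")
  out <- series[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "population") <- attr(series, "population")
  out
}

#' Daily maxima, minima and ranges of a logger series
#'
#' Days whose records span fewer than `minCoverageHours` hours are
#' excluded (and counted in the `nExcluded` attribute) so that partially
#' logged days cannot bias the daily extremes.
#'
#' @param series logger data.frame (`timestamp`, `temp_c`).
#' @param minCoverageHours minimum first-to-last record span per day
#'   (default 20 h).
#' @return data.frame with columns `date`, `tmax`, `tmin`, `range`;
#'   attribute `nExcluded`.
#' @export
dailyStats <- function(series, minCoverageHours = 20) {
  stopifnot(nrow(series) > 0)
  date <- as.Date(strftime(series$timestamp, "%Y-%m-%d", tz = "UTC"))
  spl <- split(seq_len(nrow(series)), date)
  rows <- lapply(names(spl), function(d) {
    i <- spl[[d]]
    span <- as.numeric(difftime(max(series$timestamp[i]),
                                min(series$timestamp[i]), units = "hours"))
    if (span < minCoverageHours) return(NULL)
    tv <- series$temp_c[i]
    data.frame(date = as.Date(d), tmax = max(tv), tmin = min(tv),
               range = max(tv) - min(tv))
  })
  keep <- !vapply(rows, is.null, logical(1))
  if (!any(keep)) stop("no day meets the coverage threshold")
  out <- do.call(rbind, rows[keep])
  rownames(out) <- NULL
  attr(out, "nExcluded") <- sum(!keep)
  out
}

#' Microclimate summary over a phenology window
#'
#' Computes, from pond datalogger records restricted to the larval-period
#' window: `tmax`, the mean daily maximum over the warmest calendar month
#' (the month with the highest mean daily maximum; ties go to the earlier
#' month); `tmin`, the mean daily minimum over the coldest month; the
#' seasonal range `sr = tmax - tmin`; and `dr`, the mean daily range over
#' all qualifying days. If no calendar month has at least `minMonthDays`
#' qualifying days the monthly step is downgraded (with a warning) to the
#' all-days mean daily maximum/minimum.
#'
#' @param series logger data.frame.
#' @param window optional [phenologyWindow()]; when supplied the series is
#'   clipped first.
#' @param minCoverageHours see [dailyStats()].
#' @param minMonthDays qualifying days required for a month to count
#'   (default 20).
#' @return Named list `tmax`, `tmin`, `sr`, `dr`, plus `warmestMonth` and
#'   `coldestMonth` ("YYYY-MM", `NA` when downgraded).
#' @export
microSummary <- function(series, window = NULL, minCoverageHours = 20,
                         minMonthDays = 20) {
  if (!is.null(window)) series <- clipToWindow(series, window)
  daily <- dailyStats(series, minCoverageHours)
  dr <- mean(daily$range)
  ym <- format(daily$date, "%Y-%m")
  nDays <- table(ym)
  full <- names(nDays)[nDays >= minMonthDays]
  if (!length(full)) {
    warning("no calendar month has enough qualifying days; ",
            "falling back to all-days mean daily extremes")
    return(list(tmax = mean(daily$tmax), tmin = mean(daily$tmin),
                sr = mean(daily$tmax) - mean(daily$tmin), dr = dr,
                warmestMonth = NA_character_, coldestMonth = NA_character_))
  }
  mMax <- vapply(full, function(m) mean(daily$tmax[ym == m]), numeric(1))
  mMin <- vapply(full, function(m) mean(daily$tmin[ym == m]), numeric(1))
  warm <- full[which.max(mMax)]   # which.max takes the first (earlier) tie
  cold <- full[which.min(mMin)]
  tmax <- mMax[[warm]]
  tmin <- mMin[[cold]]
  list(tmax = tmax, tmin = tmin, sr = tmax - tmin, dr = dr,
       warmestMonth = warm, coldestMonth = cold)
}

.daysInMonth <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)

.monthDaysInWindow <- function(month, window) {
  md <- month * 100L + seq_len(.daysInMonth[month])
  sum(.inWindow(md, window))
}

#' Macroclimate summary over a phenology window
#'
#' From a 12-row monthly table of maximum (`tmax_c`) and minimum
#' (`tmin_c`) air temperatures: `TMAX` is the maximum monthly maximum and
#' `TMIN` the minimum monthly minimum over the months in the window. The
#' seasonal range is reported two ways: `SR_extreme = TMAX - TMIN` and
#' `SR_monthly`, the mean within-month range over the included months. A
#' calendar month counts as inside the window when at least
#' `minDaysInMonth` of its days are (window wrapping handled).
#'
#' @param macro data.frame with columns `month` (1-12), `tmax_c`,
#'   `tmin_c` (a `population` column is ignored here).
#' @param window a [phenologyWindow()].
#' @param minDaysInMonth inclusion threshold (default 15 days).
#' @return Named list `TMAX`, `TMIN`, `SR_extreme`, `SR_monthly`,
#'   `months` (included month numbers).
#' @export
macroSummary <- function(macro, window, minDaysInMonth = 15) {
  stopifnot(all(c("month", "tmax_c", "tmin_c") %in% names(macro)),
            inherits(window, "PhenologyWindow"))
  macro <- macro[order(macro$month), , drop = FALSE]
  if (!identical(as.integer(macro$month), 1:12)) {
    stop("macro table must contain exactly the 12 calendar months")
  }
  if (any(macro$tmax_c < macro$tmin_c)) {
    stop("monthly maximum below monthly minimum in macro table")
  }
  inWin <- vapply(1:12, .monthDaysInWindow, integer(1), window = window) >=
    minDaysInMonth
  if (!any(inWin)) stop("no calendar month qualifies for the window")
  tmaxM <- macro$tmax_c[inWin]; tminM <- macro$tmin_c[inWin]
  list(TMAX = max(tmaxM), TMIN = min(tminM),
       SR_extreme = max(tmaxM) - min(tminM),
       SR_monthly = mean(tmaxM - tminM),
       months = which(inWin))
}

#' Per-population climate summary table
#'
#' Applies [microSummary()] and [macroSummary()] population by population,
#' restricted to each population's phenology window, and assembles the
#' combined table (one row per population) used by
#' [vulnerabilityTable()]. `aliasMap` substitutes a donor population's
#' logger series for populations whose logger was lost, without touching
#' macro data or windows.
#'
#' @param loggers named list of logger data.frames (names = populations).
#' @param macro data.frame with columns `population`, `month`, `tmax_c`,
#'   `tmin_c`.
#' @param windows named list of [phenologyWindow()] objects, or a
#'   data.frame with columns `population`, `start`, `end`.
#' @param aliasMap optional named character vector: names are populations
#'   without a logger, values the donor population.
#' @param ... passed on to [microSummary()].
#' @return data.frame with columns `population`, `TMAX`, `TMIN`, `SR`,
#'   `SR_monthly`, `tmax`, `tmin`, `sr`, `dr` (SR = TMAX - TMIN).
#' @export
climateSummary <- function(loggers, macro, windows, aliasMap = NULL, ...) {
  if (is.data.frame(windows)) {
    wl <- lapply(seq_len(nrow(windows)), function(i) {
      phenologyWindow(windows$start[i], windows$end[i],
                      population = windows$population[i])
    })
    names(wl) <- windows$population
    windows <- wl
  }
  pops <- names(windows)
  rows <- lapply(pops, function(p) {
    src <- p
    if (!is.null(aliasMap) && p %in% names(aliasMap)) src <- aliasMap[[p]]
    if (!src %in% names(loggers)) {
      message("skipping population without logger series: ", p)
      return(NULL)
    }
    mm <- macro[macro$population == p, , drop = FALSE]
    if (nrow(mm) != 12L) {
      message("skipping population without a full macro table: ", p)
      return(NULL)
    }
    mi <- microSummary(loggers[[src]], windows[[p]], ...)
    ma <- macroSummary(mm, windows[[p]])
    data.frame(population = p, TMAX = ma$TMAX, TMIN = ma$TMIN,
               SR = ma$SR_extreme, SR_monthly = ma$SR_monthly,
               tmax = mi$tmax, tmin = mi$tmin, sr = mi$sr, dr = mi$dr,
               stringsAsFactors = FALSE)
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no population had both logger and macro inputs")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
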