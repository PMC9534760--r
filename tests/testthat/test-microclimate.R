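makeSeries <- function(times, temps) data.frame(
  timestamp = as.POSIXct(times, tz = "UTC"), temp_c = temps)

test_that("logger CSV reading validates, sorts and collapses duplicates", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("timestamp,temp_c",
               "2013-06-01T00:00:00,10",
               "2013-06-01T01:00:00,11",
               "2013-06-01T02:00:00,12"), f)
  s <- readLoggerCSV(f)
  expect_equal(nrow(s), 3)
  expect_s3_class(s$timestamp, "POSIXct")

  writeLines(c("timestamp,temp_c",
               "2013-06-01T02:00:00,12",
               "2013-06-01T00:00:00,10"), f)
  expect_warning(s2 <- readLoggerCSV(f), "out of order")
  expect_true(!is.unsorted(s2$timestamp))

  writeLines(c("timestamp,temp_c",
               "2013-06-01T00:00:00,10",
               "2013-06-01T00:00:00,12"), f)
  expect_warning(s3 <- readLoggerCSV(f), "duplicate")
  expect_equal(nrow(s3), 1)
  expect_equal(s3$temp_c, 11)

  writeLines(c("timestamp,temp_c", "not-a-time,10"), f)
  expect_error(readLoggerCSV(f), "line 2")
  writeLines("timestamp,temp_c", f)
  expect_error(readLoggerCSV(f), "empty")
})

test_that("window clipping honours inclusive, year-wrapping semantics", {
  days <- seq(as.Date("2012-10-01"), as.Date("2013-09-30"), by = "day")
  s <- makeSeries(paste(days, "12:00:00"), 10)

  w <- phenologyWindow("10-01", "09-30")
  expect_equal(nrow(clipToWindow(s, w)), nrow(s))  # whole-series window

  wWrap <- phenologyWindow("11-15", "03-10")
  cl <- clipToWindow(s, wWrap)
  md <- as.integer(format(as.Date(cl$timestamp), "%m%d"))
  expect_true(all(md >= 1115 | md <= 310))
  expect_equal(nrow(cl), as.numeric(as.Date("2013-03-10") -
                                      as.Date("2012-11-15")) + 1)

  sJune <- makeSeries(paste(seq(as.Date("2013-06-01"),
                                as.Date("2013-06-10"), by = "day"),
                            "12:00:00"), 10)
  expect_error(clipToWindow(sJune, phenologyWindow("01-01", "02-01")),
               "no overlap")
})

test_that("daily statistics respect the coverage rule", {
  hours <- sprintf("2013-06-01 %02d:00:00", 0:23)
  sConst <- makeSeries(hours, 10)
  d <- dailyStats(sConst)
  expect_equal(unlist(d[1, c("tmax", "tmin", "range")]),
               c(tmax = 10, tmin = 10, range = 0))

  # a day with only 2 h of records is excluded at the default threshold
  sShort <- rbind(sConst,
                  makeSeries(c("2013-06-02 10:00:00", "2013-06-02 12:00:00"),
                             c(5, 6)))
  d2 <- dailyStats(sShort)
  expect_equal(nrow(d2), 1)
  expect_equal(attr(d2, "nExcluded"), 1)
  expect_error(dailyStats(makeSeries("2013-06-01 10:00:00", 5)), "coverage")
})

test_that("micro summary picks warmest/coldest months and ties break early", {
  # two full months; June days peak at 20, July at 26; minima 10 vs 12
  days <- seq(as.Date("2013-06-01"), as.Date("2013-07-31"), by = "day")
  july <- format(days, "%m") == "07"
  recs <- do.call(rbind, lapply(seq_along(days), function(i) {
    base <- if (july[i]) 19 else 15
    amp <- if (july[i]) 7 else 5
    makeSeries(paste(days[i], sprintf("%02d:00:00", 0:23)),
               base + amp * sin(2 * pi * (0:23 - 6) / 24))
  }))
  ms <- microSummary(recs)
  expect_equal(ms$warmestMonth, "2013-07")
  expect_equal(ms$coldestMonth, "2013-06")
  expect_equal(ms$tmax, 26, tolerance = 1e-6)
  expect_equal(ms$tmin, 10, tolerance = 1e-6)
  expect_equal(ms$sr, 16, tolerance = 1e-6)
  # dr = mean daily range; discrete hourly sampling of the sinusoid
  expect_equal(ms$dr, mean(c(rep(10, sum(!july)), rep(14, sum(july)))),
               tolerance = 0.2)

  # tie: identical months -> earlier chosen, value unchanged
  recsTie <- do.call(rbind, lapply(seq_along(days), function(i) {
    makeSeries(paste(days[i], sprintf("%02d:00:00", 0:23)),
               15 + 5 * sin(2 * pi * (0:23 - 6) / 24))
  }))
  msTie <- microSummary(recsTie)
  expect_equal(msTie$warmestMonth, "2013-06")
  expect_equal(msTie$tmax, 20, tolerance = 1e-6)

  # under-covered months downgrade to all-days means with a warning
  few <- recs[as.Date(recs$timestamp) <= as.Date("2013-06-05"), ]
  expect_warning(msFew <- microSummary(few), "falling back")
  expect_true(is.na(msFew$warmestMonth))
})

test_that("macro summary aggregates included months per the day rule", {
  macro <- data.frame(population = "x", month = 1:12,
                      tmax_c = c(8, 9, 12, 15, 20, 10, 30, 29, 24, 18, 12, 9),
                      tmin_c = c(-2, -1, 1, 4, 8, 0, 14, 14, 10, 6, 2, -1))
  w1 <- phenologyWindow("07-01", "07-31")
  m1 <- macroSummary(macro, w1)
  expect_equal(m1$TMAX, 30); expect_equal(m1$TMIN, 14)
  expect_equal(m1$SR_extreme, 16); expect_equal(m1$SR_monthly, 16)

  # two months: (20,10) and (30,0) arithmetic
  macro2 <- macro
  macro2$tmax_c[5:6] <- c(20, 30); macro2$tmin_c[5:6] <- c(10, 0)
  m2 <- macroSummary(macro2, phenologyWindow("05-01", "06-30"))
  expect_equal(m2$TMAX, 30); expect_equal(m2$TMIN, 0)
  expect_equal(m2$SR_extreme, 30); expect_equal(m2$SR_monthly, 20)

  # year-wrapping window collects months across the boundary
  # Nov 15-30 (16 d) and Feb 1-15 (15 d) both reach the 15-day threshold
  mWrap <- macroSummary(macro, phenologyWindow("11-15", "02-15"))
  expect_equal(sort(mWrap$months), c(1, 2, 11, 12))
  expect_equal(mWrap$TMAX, max(macro$tmax_c[c(1, 2, 11, 12)]))
  expect_equal(mWrap$TMIN, min(macro$tmin_c[c(1, 2, 11, 12)]))

  expect_error(macroSummary(macro, phenologyWindow("07-20", "07-25")),
               "no calendar month")
  bad <- macro; bad$tmin_c[1] <- 99
  expect_error(macroSummary(bad, w1), "below")
})

test_that("temperature shifts move extremes but not ranges", {
  cfg <- simulationConfig(seed = 14, loggerParams = list(noiseSd = 0.3))
  s <- simulateLoggerSeries(cfg)
  w <- phenologyWindow("05-10", "08-20")
  a <- microSummary(s, w)
  sShift <- s; sShift$temp_c <- s$temp_c + 3
  b <- microSummary(sShift, w)
  expect_equal(b$tmax, a$tmax + 3, tolerance = 1e-9)
  expect_equal(b$tmin, a$tmin + 3, tolerance = 1e-9)
  expect_equal(b$sr, a$sr, tolerance = 1e-9)
  expect_equal(b$dr, a$dr, tolerance = 1e-9)
  expect_gte(a$tmax, a$tmin)
  # clipping then summarising equals summarising a pre-clipped series
  expect_identical(microSummary(clipToWindow(s, w)), a)
})

test_that("climate summary joins populations and applies alias donors", {
  cfg <- simulationConfig(seed = 31)
  loggers <- list(pop01 = simulateLoggerSeries(cfg, "pop01"))
  cfg2 <- cfg; cfg2$seed <- 32L
  loggers$pop02 <- simulateLoggerSeries(cfg2, "pop02")
  macro <- do.call(rbind, lapply(c("pop01", "pop02", "pop03"), function(p) {
    data.frame(population = p, month = 1:12,
               tmax_c = 15 + sin(2 * pi * (1:12) / 12) * 8,
               tmin_c = 2 + sin(2 * pi * (1:12) / 12) * 8)
  }))
  wins <- data.frame(population = c("pop01", "pop02", "pop03"),
                     start = "05-15", end = "08-15")
  cs <- climateSummary(loggers, macro, wins,
                       aliasMap = c(pop03 = "pop01"))
  expect_equal(nrow(cs), 3)
  expect_equal(cs$SR, cs$TMAX - cs$TMIN)
  expect_equal(cs$sr, cs$tmax - cs$tmin)
  # alias population reuses the donor's micro summary
  expect_equal(cs$tmax[cs$population == "pop03"],
               cs$tmax[cs$population == "pop01"])
  # a population with no logger and no alias is dropped with a message
  expect_message(
    cs2 <- climateSummary(loggers, macro, wins),
    "skipping")
  expect_equal(nrow(cs2), 2)
})
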