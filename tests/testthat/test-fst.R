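test_that("complete fixation between two populations gives theta = 1", {
  for (n in c(2, 5, 10)) {
    d <- GenotypeDataset(rbind(matrix(1L, n, 2), matrix(2L, n, 2)),
                         rep(c("A", "B"), each = n), "L1")
    expect_equal(multilocusTheta(d), 1)
  }
})

test_that("a duplicated all-heterozygote population gives a <= 0", {
  calls <- matrix(rep(c(1L, 2L), each = 1), nrow = 20, ncol = 2, byrow = TRUE)
  d <- GenotypeDataset(calls, rep(c("A", "B"), each = 10), "L1")
  comp <- wcThetaLocus(d, 1)
  expect_lte(comp[["a"]], 0)
})

test_that("components match the brute-force WC84 oracle to 1e-12", {
  d <- wcFixture()
  for (l in seq_along(loci(d))) {
    expect_equal(unname(wcThetaLocus(d, l)),
                 unname(oracleWC(popCallsOf(d, l))), tolerance = 1e-12)
  }
  # and on messier simulated data with >2 alleles
  cfg <- simulationConfig(nPopulations = 5, nPerPop = 12, nLoci = 3,
                          allelesPerLocus = 6, targetFst = 0.15, seed = 33)
  g <- simulateGenotypes(cfg)
  g@calls[c(2, 17, 40), 1:2] <- NA_integer_  # inject missing calls
  for (l in 1:3) {
    expect_equal(unname(wcThetaLocus(g, l)),
                 unname(oracleWC(popCallsOf(g, l))), tolerance = 1e-12)
  }
})

test_that("multilocus theta is a ratio of sums with sane edge behaviour", {
  d <- wcFixture()
  comp1 <- wcThetaLocus(d, 1); comp2 <- wcThetaLocus(d, 2)
  expect_equal(multilocusTheta(d),
               (comp1[["a"]] + comp2[["a"]]) / (sum(comp1) + sum(comp2)))

  # single-locus reduction
  d1 <- GenotypeDataset(d@calls[, 1:2], d@population, "locA",
                        d@individualIds)
  expect_equal(multilocusTheta(d1), comp1[["a"]] / sum(comp1))

  # monomorphic everywhere -> explicit error
  dm <- GenotypeDataset(matrix(1L, 8, 2), rep(c("A", "B"), each = 4), "L1")
  expect_error(multilocusTheta(dm), "no variation")
})

test_that("theta is invariant to individual order, allele labels and locus order", {
  d <- wcFixture()
  th <- multilocusTheta(d)

  set.seed(1)
  perm <- sample(nIndividuals(d))
  dPerm <- GenotypeDataset(d@calls[perm, ],
                           as.character(d@population)[perm],
                           d@loci, d@individualIds[perm])
  expect_equal(multilocusTheta(dPerm), th, tolerance = 1e-12)

  relabel <- c(7L, 5L, 9L)  # bijective allele recoding 1->7, 2->5, 3->9
  callsR <- d@calls
  callsR[] <- ifelse(is.na(d@calls), NA_integer_, relabel[d@calls])
  dR <- GenotypeDataset(callsR, d@population, d@loci, d@individualIds)
  expect_equal(multilocusTheta(dR), th, tolerance = 1e-12)

  dSwap <- GenotypeDataset(d@calls[, c(3, 4, 1, 2)], d@population,
                           rev(d@loci), d@individualIds)
  expect_equal(multilocusTheta(dSwap), th, tolerance = 1e-12)
})

test_that("pairwise matrix is symmetric, zero-diagonal and consistent", {
  d <- wcFixture()
  m <- pairwiseFst(d)
  expect_identical(m, t(m))
  expect_true(all(diag(m) == 0))
  expect_equal(m["low", "mid"], multilocusTheta(d, pops = c("low", "mid")))

  d2 <- subsetPopulations(d, c("low", "mid"))
  m2 <- pairwiseFst(d2)
  expect_equal(m2[1, 2], multilocusTheta(d2))

  # excluding a population never touches the remaining pairs
  expect_equal(pairwiseFst(subsetPopulations(d, c("low", "high")))[1, 2],
               m["low", "high"])
})

test_that("a pair simulated from identical frequencies is the least diverged", {
  hits <- 0L
  for (s in 1:50) {
    cfg <- simulationConfig(nPopulations = 2, nPerPop = 15, nLoci = 4,
                            allelesPerLocus = 4, targetFst = 0.25, seed = s)
    g2 <- simulateGenotypes(cfg)  # two well-separated populations
    # third population: re-draw genotypes from pop2's realized frequencies
    set.seed(s + 500)
    callsC <- g2@calls[g2@population == "pop02", , drop = FALSE]
    calls3 <- apply(callsC, 2, sample, size = 15, replace = TRUE)
    d <- GenotypeDataset(rbind(g2@calls, calls3),
                         c(as.character(g2@population), rep("pop03", 15)),
                         loci(g2))
    m <- pairwiseFst(d)
    off <- c(p12 = m[1, 2], p13 = m[1, 3], p23 = m[2, 3])
    if (which.min(off) == 3L) hits <- hits + 1L
  }
  expect_gte(hits, 40L)  # pop2-pop3 share frequencies; allow sampling noise
})

test_that("bootstrap CI over loci behaves and matches a mirrored oracle", {
  d <- wcFixture()
  # identical locus copies -> interval collapses to the point estimate
  dup <- GenotypeDataset(d@calls[, c(1, 2, 1, 2, 1, 2)], d@population,
                         c("c1", "c2", "c3"), d@individualIds)
  ciDup <- bootstrapFstCI(dup, nBoot = 300, seed = 1)
  expect_equal(unname(ciDup["low"]), multilocusTheta(dup))
  expect_equal(unname(ciDup["high"]), multilocusTheta(dup))

  cfg <- simulationConfig(nPopulations = 6, nPerPop = 15, nLoci = 6,
                          allelesPerLocus = 5, targetFst = 0.1, seed = 13)
  g <- simulateGenotypes(cfg)
  ci1 <- bootstrapFstCI(g, nBoot = 1000, seed = 7)
  ci2 <- bootstrapFstCI(g, nBoot = 1000, seed = 7)
  expect_identical(ci1, ci2)

  # mirrored resampling oracle: same seed stream, independent computation
  compOracle <- t(vapply(seq_along(loci(g)),
                         function(l) oracleWC(popCallsOf(g, l)), numeric(3)))
  L <- nrow(compOracle); nBoot <- 1000
  set.seed(7)
  idx <- matrix(sample.int(L, L * nBoot, replace = TRUE), nrow = nBoot)
  thetas <- vapply(seq_len(nBoot), function(b) {
    rows <- idx[b, ]
    sum(compOracle[rows, 1]) / sum(compOracle[rows, ])
  }, numeric(1))
  qo <- quantile(thetas, c(0.025, 0.975), names = FALSE)
  expect_equal(unname(ci1["low"]), qo[1], tolerance = 1e-12)
  expect_equal(unname(ci1["high"]), qo[2], tolerance = 1e-12)

  # the interval brackets the point estimate on simulated data
  expect_lte(ci1[["low"]], multilocusTheta(g))
  expect_gte(ci1[["high"]], multilocusTheta(g))

  # jackknife option
  cj <- bootstrapFstCI(g, method = "jackknife")
  expect_lt(cj[["low"]], cj[["high"]])
})

test_that("fstEstimate assembles a coherent result object", {
  cfg <- simulationConfig(nPopulations = 4, nPerPop = 12, nLoci = 5,
                          allelesPerLocus = 4, targetFst = 0.08, seed = 3)
  g <- simulateGenotypes(cfg)
  r <- fstEstimate(g, nBoot = 500, seed = 2)
  expect_s4_class(r, "FstResult")
  expect_equal(thetaGlobal(r), multilocusTheta(g))
  expect_equal(dim(pairwiseMatrix(r)), c(4, 4))
  expect_named(confint95(r), c("low", "high"))
  j <- tempfile(fileext = ".json"); cc <- tempfile(fileext = ".csv")
  writeFstResult(r, jsonPath = j, csvPath = cc)
  parsed <- jsonlite::read_json(j)
  expect_equal(parsed$theta_global, thetaGlobal(r))
  expect_equal(nrow(read.csv(cc)), 5)
})
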