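test_that("REML matches balanced-ANOVA closed forms and handles boundaries", {
  # sigma_w2 = 0 case: between-group variance of the two means
  vc <- fitOneWayREML(values = c(0, 0, 1, 1), groups = c("a", "a", "b", "b"))
  expect_equal(sigmaW2(vc), 0)
  expect_equal(sigmaB2(vc), 0.5)

  # all values identical -> (0, 0)
  vc0 <- fitOneWayREML(values = rep(3.2, 10), groups = rep(1:2, 5))
  expect_equal(c(sigmaB2(vc0), sigmaW2(vc0)), c(0, 0))

  # a single population -> error
  expect_error(fitOneWayREML(values = rnorm(5), groups = rep("a", 5)),
               ">= 2 populations")

  # balanced interior case: REML = ANOVA moments = (MSB - MSW) / n
  set.seed(8)
  g <- rep(letters[1:6], each = 10)
  y <- rnorm(6, 0, 2)[as.integer(factor(g))] + rnorm(60)
  vcR <- fitOneWayREML(values = y, groups = g)
  vcM <- fitOneWayMoments(values = y, groups = g)
  expect_equal(sigmaB2(vcR), sigmaB2(vcM), tolerance = 1e-7)
  expect_equal(sigmaW2(vcR), sigmaW2(vcM), tolerance = 1e-7)
})

test_that("REML agrees with the dense grid-search oracle on unbalanced data", {
  set.seed(15)
  for (rep in 1:3) {
    sizes <- sample(3:12, 5, replace = TRUE)
    g <- rep(paste0("p", 1:5), times = sizes)
    y <- rnorm(5, 0, 1)[as.integer(factor(g))] + rnorm(sum(sizes), 0, 0.7)
    vc <- fitOneWayREML(values = y, groups = g)
    orc <- oracleREML(y, g)
    expect_equal(sigmaB2(vc), orc[["sigmaB2"]], tolerance = 1e-6)
    expect_equal(sigmaW2(vc), orc[["sigmaW2"]], tolerance = 1e-6)
  }
})

test_that("REML agrees with lme4 on unbalanced data", {
  set.seed(99)
  sizes <- c(4, 9, 6, 13, 5, 8, 11, 3)
  g <- rep(paste0("p", seq_along(sizes)), times = sizes)
  y <- rnorm(length(sizes), 0, 1.1)[as.integer(factor(g))] +
    rnorm(sum(sizes), 0, 0.9)
  vc <- fitOneWayREML(values = y, groups = g)
  m <- lme4::lmer(y ~ 1 + (1 | g), REML = TRUE)
  v <- as.data.frame(lme4::VarCorr(m))$vcov
  expect_equal(sigmaB2(vc), v[1], tolerance = 1e-5)
  expect_equal(sigmaW2(vc), v[2], tolerance = 1e-5)
})

test_that("Pst formula behaves at its analytic anchors and invariances", {
  expect_equal(computePst(c(0, 1), ratio = 0.7), 0)
  expect_equal(computePst(c(3, 0), ratio = 0.7), 1)
  expect_equal(computePst(c(2, 1), ratio = 1), 0.5)
  expect_error(computePst(c(0, 0), 1), "undefined")
  expect_error(computePst(c(1, 1), 0), "ratio")

  # strictly increasing in the ratio when both components are positive
  r <- seq(0.1, 3, by = 0.1)
  p <- computePst(c(0.8, 1.3), r)
  expect_true(all(diff(p) > 0))

  # invariant to shifting or rescaling the trait values
  set.seed(3)
  g <- rep(1:5, each = 8)
  y <- rnorm(5, 0, 1)[g] + rnorm(40, 0, 0.6)
  p0 <- computePst(fitOneWayREML(values = y, groups = g), 1)
  pShift <- computePst(fitOneWayREML(values = y + 100, groups = g), 1)
  pScale <- computePst(fitOneWayREML(values = y * 7, groups = g), 1)
  expect_equal(pShift, p0, tolerance = 1e-6)
  expect_equal(pScale, p0, tolerance = 1e-6)
})

test_that("Pst bootstrap grid collapses, repeats and validates as specified", {
  # noiseless populations: sigma_w2 = 0 in every replicate -> CI = [1, 1]
  tr <- data.frame(population = rep(c("a", "b", "c"), each = 4),
                   trait = rep(c(1, 2, 4), each = 4))
  gr <- pstBootstrapCI(tr, ratios = c(0.5, 1, 2), nBoot = 500, seed = 1)
  expect_true(all(gr@ciLow == 1))
  expect_true(all(gr@ciHigh == 1))
  expect_true(all(gr@pstPoint == 1))

  # determinism
  set.seed(77)
  tr2 <- data.frame(population = rep(c("a", "b", "c", "d"), each = 6),
                    trait = rnorm(24, rep(c(0, 1, 2, 3), each = 6), 1))
  g1 <- pstBootstrapCI(tr2, nBoot = 500, seed = 42)
  g2 <- pstBootstrapCI(tr2, nBoot = 500, seed = 42)
  expect_identical(pstGridTable(g1), pstGridTable(g2))

  # constant data cannot support Pst at all
  trC <- data.frame(population = rep(c("a", "b"), each = 3), trait = 5)
  expect_error(pstBootstrapCI(trC, nBoot = 500, seed = 1))

  # bad grids rejected
  expect_error(pstBootstrapCI(tr2, ratios = c(1, 0.5), nBoot = 500, seed = 1),
               "ascending")
  expect_error(pstBootstrapCI(tr2, nBoot = 100, seed = 1), "nBoot")
})

test_that("critical c/h2 ratio inverts the analytic band and hits sentinels", {
  # replicates constructed with sigmaB2 = sigmaW2 exactly: ci_low(r) = r/(r+2)
  reps <- cbind(sigmaB2 = rep(1, 600), sigmaW2 = rep(1, 600))
  ratios <- seq(0.05, 2, by = 0.05)
  pst <- ratios / (ratios + 2)
  grid <- new("PstGrid", ratios = ratios, pstPoint = pst, ciLow = pst,
              ciHigh = pst, replicates = reps, nBoot = 600L,
              nDegenerate = 0L, seed = 1L, unit = "population")
  expect_equal(criticalCH2Ratio(grid, fstUpper = 0.2), 0.5, tolerance = 1e-5)
  expect_identical(criticalCH2Ratio(grid, fstUpper = 1), "beyond_grid")
  expect_identical(criticalCH2Ratio(grid, fstUpper = 0), "none_below_grid")
})

test_that("pairwise Pst matrix matches independent per-pair fits", {
  trSame <- data.frame(population = rep(c("a", "b"), each = 5),
                       trait = rep(c(1, 2, 3, 4, 5), 2))
  mSame <- pairwisePstMatrix(trSame, ratio = 1)
  expect_equal(mSame["a", "b"], 0)

  trDisj <- data.frame(population = rep(c("a", "b"), each = 4),
                       trait = rep(c(0, 10), each = 4))
  expect_equal(pairwisePstMatrix(trDisj, ratio = 1)["a", "b"], 1)

  set.seed(6)
  tr <- data.frame(population = rep(c("a", "b", "c"), times = c(5, 8, 6)),
                   trait = c(rnorm(5, 0), rnorm(8, 1.5), rnorm(6, 0.5)))
  m <- pairwisePstMatrix(tr, ratio = 0.8)
  expect_identical(m, t(m))
  for (pair in list(c("a", "b"), c("a", "c"), c("b", "c"))) {
    sub <- tr[tr$population %in% pair, ]
    orc <- oracleREML(sub$trait, sub$population)
    expect_equal(m[pair[1], pair[2]],
                 0.8 * orc[["sigmaB2"]] /
                   (0.8 * orc[["sigmaB2"]] + 2 * orc[["sigmaW2"]]),
                 tolerance = 1e-6)
  }
})

test_that("Mantel test matches its anchors, oracle and vegan", {
  set.seed(10)
  A <- matrix(0, 5, 5)
  A[lower.tri(A)] <- runif(10)
  A <- A + t(A)

  mt <- mantelTest(A, A, nPermutations = 199, seed = 1)
  expect_equal(mt@r, 1)
  # mirror the permutation stream: p = (1 + #(r_perm >= 1)) / 200; random
  # label permutations can legitimately reproduce r = 1 (e.g. identity)
  set.seed(1)
  x <- A[lower.tri(A)]
  hits <- sum(vapply(1:199, function(i) {
    p <- sample.int(5)
    cor(x, A[p, p][lower.tri(A)]) >= 1 - 1e-12
  }, logical(1)))
  expect_equal(mt@pValue, (1 + hits) / 200)
  expect_gte(mt@pValue, 1 / 200)

  mtNeg <- mantelTest(A, max(A) + 1 - A - diag(max(A) + 1, 5),
                      nPermutations = 99, seed = 1)
  expect_equal(mtNeg@r, -1)

  # exhaustive enumeration on 4 x 4 equals the Heap-enumeration oracle
  B <- matrix(0, 4, 4); B[lower.tri(B)] <- c(3, 1, 4, 1, 5, 9)
  B <- B + t(B)
  A4 <- matrix(0, 4, 4); A4[lower.tri(A4)] <- c(2, 7, 1, 8, 2, 8)
  A4 <- A4 + t(A4)
  mtEx <- mantelTest(A4, B, exact = TRUE)
  perms <- heapPermutations(4)
  x <- A4[lower.tri(A4)]
  rs <- apply(perms, 1, function(p) cor(x, B[p, p][lower.tri(B)]))
  expect_equal(mtEx@pValue, mean(rs >= mtEx@r - 1e-12))
  expect_equal(mtEx@r, cor(x, B[lower.tri(B)]))

  # r invariant to a joint relabeling of both matrices
  p <- c(3, 1, 4, 2)
  mtRel <- mantelTest(A4[p, p], B[p, p], exact = TRUE)
  expect_equal(mtRel@r, mtEx@r, tolerance = 1e-12)
  expect_equal(mtRel@pValue, mtEx@pValue)

  # agreement with vegan on the statistic
  vg <- vegan::mantel(A4, B, permutations = 99)
  expect_equal(mtEx@r, unname(vg$statistic), tolerance = 1e-12)

  # guards
  expect_error(mantelTest(A4, matrix(1, 4, 4)), "constant")
  Amiss <- A4; Amiss[2, 1] <- Amiss[1, 2] <- NA
  expect_error(mantelTest(Amiss, B), "missing")
  expect_error(mantelTest(A4, B[1:3, 1:3]), "equal dimension")
})
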