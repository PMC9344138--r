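test_that("fitting computes mean and n-1 standard deviation with a floor", {
  wl <- c(400, 402)
  a <- cbind(c(0.5, 0.1), c(0.5, 0.2), c(0.5, 0.3))
  x <- tinySpectra(a, wl, rep(1L, 3), set = "calibration")
  st <- fitClassStats(x, sdFloor = 1e-6)
  expect_equal(unname(classMeans(st)[, 1]), c(0.5, 0.2))
  expect_equal(unname(classSDs(st)[2, 1]), 0.1)
  # zero variance is floored, never zero
  expect_equal(unname(classSDs(st)[1, 1]), 1e-6)

  x1 <- tinySpectra(matrix(0.5, 2, 3), wl, c(1L, 1L, 2L),
                    set = "calibration")
  expect_error(fitClassStats(x1), "class 2 has fewer than 2")
  expect_error(fitClassStats(subsetBySet(x1, "prediction")), "no spectra")
})

test_that("fitted means track the generator truth within standard error", {
  cfg <- recoveryConfig()
  x <- generateSpectra(cfg, seed = 11)
  st <- fitClassStats(x, set = NULL)
  truth <- S4Vectors::metadata(x)$classMeans
  n <- table(classLabels(x))[1]
  se <- sqrt(cfg$noiseSd^2 / n + cfg$bottleOffsetSd^2 / cfg$bottlesPerClass)
  dev <- abs(classMeans(st) - truth) / se
  expect_lt(max(dev), 6)
  expect_gt(mean(dev < 3), 0.95)
})

test_that("log density matches the closed-form normal density", {
  expect_equal(logDensity(0, 0, 1), -log(sqrt(2 * pi)))
  expect_equal(logDensity(1, 0, 1), -log(sqrt(2 * pi)) - 0.5)
  # far tail, sigma = 0.1: direct formula evaluation
  expect_equal(logDensity(0, 1, 0.1),
               -0.5 * log(2 * pi) - log(0.1) - 0.5 * (1 / 0.1)^2)
  # densities above 1 are legal for small sigma
  expect_gt(logDensity(0, 0, 0.01), 0)
  expect_error(logDensity(0, 0, 0), "positive")
})

test_that("log conditionals are sums of per-wavelength log densities", {
  wl <- c(400, 402, 404)
  aCal <- localSeed(1, matrix(rnorm(3 * 8, 0.5, 0.1), 3, 8))
  x <- tinySpectra(aCal, wl, rep(1:2, each = 4), set = "calibration")
  st <- fitClassStats(x)
  sp <- c(0.45, 0.52, 0.61)

  lc1 <- logConditional(sp, st, 402)
  expect_equal(unname(lc1),
               sapply(1:2, function(k)
                 logDensity(sp[2], classMeans(st)[2, k],
                            classSDs(st)[2, k])))
  # additivity over disjoint subsets
  expect_equal(logConditional(sp, st, c(400, 404)) +
                 logConditional(sp, st, 402),
               logConditional(sp, st, wl), tolerance = 1e-12)
  # brute-force product oracle at s = 3
  prods <- sapply(1:2, function(k)
    prod(dnorm(sp, classMeans(st)[, k], classSDs(st)[, k])))
  expect_equal(unname(logConditional(sp, st, wl)), log(prods),
               tolerance = 1e-12)
  expect_error(logConditional(sp, st, numeric(0)), "non-empty")
  expect_error(logConditional(sp, st, 401), "not covered")
})

test_that("posteriors are normalized, stabilized and symmetric", {
  expect_equal(posteriorProbs(rep(-1000, 5), rep(0.2, 5)), rep(0.2, 5))
  # two classes, x at the first mean, unit sigma: phi(0)/(phi(0)+phi(1))
  lc <- c(logDensity(0, 0, 1), logDensity(0, 1, 1))
  expect_equal(posteriorProbs(lc, c(0.5, 0.5))[1],
               dnorm(0) / (dnorm(0) + dnorm(1)))
  # huge magnitudes must not overflow
  for (shift in c(-5000, 0, 5000)) {
    p <- posteriorProbs(c(-1.2, -3.4, -0.7) + shift, c(0.3, 0.3, 0.4))
    expect_equal(sum(p), 1, tolerance = 1e-12)
  }
  # adding a constant to all log conditionals changes nothing
  lcr <- localSeed(2, rnorm(4, -50, 10))
  expect_equal(posteriorProbs(lcr, rep(0.25, 4)),
               posteriorProbs(lcr + 123.456, rep(0.25, 4)),
               tolerance = 1e-12)
  expect_error(posteriorProbs(c(-1, -2), c(0.7, 0.7)), "sum to 1")
})

test_that("prediction is argmax with smallest-label tie-breaking", {
  wl <- c(400, 402)
  mu <- cbind(c(0.2, 0.2), c(0.5, 0.5), c(0.8, 0.8))
  aCal <- do.call(cbind, lapply(1:3, function(k)
    mu[, k] + localSeed(k, matrix(rnorm(8, 0, 0.05), 2, 4))))
  x <- tinySpectra(aCal, wl, rep(1:3, each = 4), set = "calibration")
  st <- fitClassStats(x)
  # spectrum at class 3's mean: nearest mean under comparable sigmas
  expect_equal(predictClasses(matrix(mu[, 3]), st, priors = "equal"), 3L)

  # identical stats for both classes -> smaller label wins
  a2 <- cbind(c(0.1, 0.2), c(0.3, 0.4))
  x2 <- tinySpectra(a2[, c(1, 2, 1, 2)], wl, rep(1:2, each = 2),
                    set = "calibration")
  st2 <- fitClassStats(x2)
  expect_equal(predictClasses(matrix(c(0.2, 0.3)), st2, priors = "equal"),
               1L)
})

test_that("priors follow calibration counts or the equal option", {
  x <- makeEvalFixture(K = 3, nCal = 4)
  st <- fitClassStats(x)
  expect_equal(unname(classPriors(st)), rep(1 / 3, 3))
  expect_equal(unname(classPriors(st, "equal")), rep(1 / 3, 3))
  expect_equal(sum(classPriors(st, c(1, 2, 7))), 1)
  expect_error(classPriors(st, c(0.5, 0.5)), "one entry per class")
})

test_that("cube subset-sums reproduce the direct route bit for bit", {
  x <- makeEvalFixture(seed = 9, W = 9, K = 3, nCal = 10, nPred = 8,
                       informative = c(404, 410))
  st <- fitClassStats(x)
  xp <- subsetBySet(x, "prediction")
  cube <- precomputeCube(xp, st)
  a <- absorbance(xp)
  wl <- wavelengths(x)
  subsets <- list(wl[3], wl, wl[c(1, 4, 7)], wl[c(2, 3, 8, 9)])
  for (s in subsets) {
    direct <- sapply(seq_len(ncol(a)), function(j)
      logConditional(a[, j], st, s))
    expect_identical(unname(cubeLogConditional(cube, s)), unname(direct))
  }
  # cube recomputation is deterministic
  cube2 <- precomputeCube(xp, st)
  expect_identical(cube@densities, cube2@densities)
  # and prediction through the cube equals predictClasses exactly
  lp <- log(classPriors(st))
  sc <- cubeLogConditional(cube, wl[c(2, 5, 6)]) + lp
  cubePred <- st@classIds[apply(sc, 2, which.max)]
  expect_identical(cubePred,
                   predictClasses(xp, st, wl[c(2, 5, 6)]))
})

test_that("relabeling classes permutes fitted stats and predictions", {
  x <- makeEvalFixture(seed = 5, K = 3, nCal = 8, nPred = 10)
  perm <- c(3L, 1L, 2L)  # new label of old class k
  cd <- SummarizedExperiment::colData(x)
  x2 <- SpectraSet(absorbance(x), wavelengths(x), perm[classLabels(x)],
                   cd$bottle_id, cd$sample_id, cd$replicate_id, cd$set)
  st1 <- fitClassStats(x)
  st2 <- fitClassStats(x2)
  ord <- order(perm)  # old class producing new label j
  expect_equal(classMeans(st2), classMeans(st1)[, ord],
               ignore_attr = TRUE)
  p1 <- predictClasses(subsetBySet(x, "prediction"), st1)
  p2 <- predictClasses(subsetBySet(x2, "prediction"), st2)
  expect_identical(p2, perm[p1])
})
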