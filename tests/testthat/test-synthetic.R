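test_that("generation is deterministic given the seed", {
  cfg <- recoveryConfig(bottlesPerClass = 3L)
  x1 <- generateSpectra(cfg, seed = 5)
  x2 <- generateSpectra(cfg, seed = 5)
  expect_identical(absorbance(x1), absorbance(x2))
  x3 <- generateSpectra(cfg, seed = 6)
  expect_false(identical(absorbance(x1), absorbance(x3)))
  # the caller's RNG stream is untouched
  before <- localSeed(1, rnorm(2))
  invisible(generateSpectra(cfg, seed = 5))
  expect_identical(before, localSeed(1, rnorm(2)))
})

test_that("the noise-free limit exposes the pure class structure", {
  cfg <- recoveryConfig(noiseSd = 0, bottleOffsetSd = 0,
                        bottlesPerClass = 2L, samplesPerBottle = 1L)
  x <- generateSpectra(cfg, seed = 1)
  a <- absorbance(x)
  cls <- classLabels(x)
  # all spectra of one class identical
  for (k in 1:5) {
    ak <- a[, cls == k, drop = FALSE]
    expect_identical(ak, ak[, rep(1, ncol(ak)), drop = FALSE],
                     ignore_attr = TRUE)
  }
  # between-class differences exactly zero outside the (truncated) bands
  wl <- wavelengths(x)
  inside <- rep(FALSE, length(wl))
  for (j in seq_along(cfg$bandCenters))
    inside <- inside |
      abs(wl - cfg$bandCenters[j]) <= 4 * cfg$bandWidths[j]
  d12 <- a[, which(cls == 1)[1]] - a[, which(cls == 2)[1]]
  expect_true(all(d12[!inside] == 0))
  # and nonzero at a band center that distinguishes the two classes
  i700 <- match(700, wl)
  expect_gt(abs(d12[i700]), 0)
})

test_that("class-mean offsets at band centers match the configuration", {
  cfg <- recoveryConfig(bottlesPerClass = 20L, samplesPerBottle = 5L)
  x <- generateSpectra(cfg, seed = 11)  # 300 spectra per class
  a <- absorbance(x)
  cls <- classLabels(x)
  wl <- wavelengths(x)
  n <- sum(cls == 1)
  se <- sqrt(cfg$noiseSd^2 / n + cfg$bottleOffsetSd^2 / cfg$bottlesPerClass)
  for (j in seq_along(cfg$bandCenters)) {
    i <- match(cfg$bandCenters[j], wl)
    want <- cfg$bandDelta * cfg$bandLevels[j, ]
    got <- vapply(1:5, function(k) mean(a[i, cls == k]), numeric(1))
    expect_lt(max(abs((got - mean(got)) - (want - mean(want)))), 3 * se)
  }
})

test_that("noise autocorrelation follows the Gaussian correlation model", {
  cfg <- syntheticConfig(grid = waveGrid(400, 600, 2), nClasses = 2L,
                         baseline = 0, sharedPeaks = NULL,
                         bandCenters = c(500), bandDelta = 0,
                         noiseSd = 1, noiseCorrLength = 8,
                         bottleOffsetSd = 0,
                         bottlesPerClass = 50L, samplesPerBottle = 5L,
                         replicatesPerSample = 2L)
  x <- generateSpectra(cfg, seed = 21)
  a <- absorbance(x)  # 101 wavelengths x 1000 spectra of pure noise
  interior <- 20:80
  r1 <- mean(vapply(interior, function(i) cor(a[i, ], a[i + 1, ]),
                    numeric(1)))
  r3 <- mean(vapply(interior, function(i) cor(a[i, ], a[i + 3, ]),
                    numeric(1)))
  L <- cfg$noiseCorrLength
  expect_equal(r1, exp(-2^2 / (2 * L^2)), tolerance = 0.02)
  expect_equal(r3, exp(-6^2 / (2 * L^2)), tolerance = 0.05)
  # unit variance after smoothing
  expect_equal(mean(apply(a[interior, ], 1, sd)), 1, tolerance = 0.05)
})

test_that("white-noise limit has negligible adjacent correlation", {
  cfg <- syntheticConfig(grid = waveGrid(400, 500, 2), nClasses = 2L,
                         baseline = 0, sharedPeaks = NULL,
                         bandCenters = 450, bandDelta = 0, noiseSd = 1,
                         noiseCorrLength = 0, bottleOffsetSd = 0,
                         bottlesPerClass = 40L, samplesPerBottle = 5L)
  x <- generateSpectra(cfg, seed = 8)
  a <- absorbance(x)
  r1 <- mean(vapply(10:40, function(i) cor(a[i, ], a[i + 1, ]), numeric(1)))
  expect_lt(abs(r1), 0.05)
})

test_that("the study-structure dataset reproduces the published counts", {
  x <- makePaperStructure(seed = 3)
  expect_equal(ncol(x), 1533L)
  expect_equal(nrow(x), 1050L)
  tab <- table(classLabels(x))
  expect_equal(as.integer(tab), c(300L, 300L, 300L, 300L, 333L))
  # interference strata: 21 commercial bottles x 9, 48 home x 3
  com <- grepl("com", bottleIds(x))
  home <- grepl("home", bottleIds(x))
  expect_equal(sum(com), 189L)
  expect_equal(sum(home), 144L)
  # interference class heterogeneity exceeds the identification classes
  i <- match(informativeWavelengths(x)[1], wavelengths(x))
  sd5 <- sd(absorbance(x)[i, classLabels(x) == 5])
  sd1 <- sd(absorbance(x)[i, classLabels(x) == 1])
  expect_gt(sd5, 2 * sd1)
})

test_that("doubling band offsets never hurts accuracy on the truth set", {
  for (s in 1:3) {
    cfg1 <- recoveryConfig(bottlesPerClass = 6L)
    cfg2 <- recoveryConfig(bottlesPerClass = 6L,
                           bandDelta = 2 * cfg1$bandDelta)
    r <- vapply(list(cfg1, cfg2), function(cfg) {
      x <- generateSpectra(cfg, seed = 100 + s)
      x <- groupedSplit(x, splitPlan(1:5, 3, 3, 0), seed = 200 + s)
      st <- fitClassStats(x)
      rarTotal(evaluateModel(x, st, informativeWavelengths(x)))
    }, numeric(1))
    expect_gte(r[2], r[1])
  }
})

test_that("configuration validation rejects inconsistent setups", {
  expect_error(recoveryConfig(bandCenters = c(480, 1200)),
               "inside the grid")
  expect_error(recoveryConfig(bandLevels = matrix(0L, 3, 5)),
               "distinguish at least two classes")
  expect_error(recoveryConfig(bandLevels = matrix(1L, 2, 5)),
               "bands x classes")
})
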