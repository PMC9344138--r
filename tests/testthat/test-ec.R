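test_that("equidistant wavelengths follow the ending-wavelength formula", {
  g <- waveGrid(400, 2498, 2)
  wl <- ecWavelengths(404, 22, 49, g)
  expect_length(wl, 22)
  expect_equal(unique(diff(wl)), 98)
  expect_equal(wl[22], 2462)
  # the published 6-wavelength refined model is a subset of this comb
  expect_true(all(c(404, 600, 992, 2070, 2266, 2462) %in% wl))

  expect_equal(ecWavelengths(400, 1, 1, g), 400)
  expect_error(ecWavelengths(404, 22, 50, g), "exceeds the grid end")
  expect_error(ecWavelengths(401, 3, 1, g), "not on grid")
})

test_that("enumeration equals brute force over equidistant subsets", {
  bruteForce <- function(grid, nMax, gMax) {
    wl <- gridWavelengths(grid)
    W <- length(wl)
    out <- character(0)
    for (i in seq_len(W)) for (g in seq_len(gMax)) for (n in seq_len(nMax)) {
      idx <- i + g * (seq_len(n) - 1)
      if (max(idx) > W) break
      out <- c(out, paste(wl[idx], collapse = ","))
    }
    sort(unique(out))
  }
  for (p in list(list(g = waveGrid(400, 408, 2), nMax = 5, gMax = 2,
                      count = 19),
                 list(g = waveGrid(400, 402, 2), nMax = 2, gMax = 1,
                      count = 3),
                 list(g = waveGrid(400, 412, 2), nMax = 4, gMax = 3,
                      count = NA))) {
    specs <- enumerateEC(p$g, p$nMax, p$gMax)
    if (!is.na(p$count)) expect_equal(nrow(specs), p$count)
    # no duplicates, all invariants hold
    got <- vapply(seq_len(nrow(specs)), function(r)
      paste(ecWavelengths(specs$I[r], specs$N[r], specs$G[r], p$g),
            collapse = ","), character(1))
    expect_equal(anyDuplicated(got), 0L)
    expect_equal(specs$E, specs$I + p$g@step * (specs$N - 1) * specs$G)
    expect_true(all(specs$E <= p$g@end))
    expect_true(all(specs$G[specs$N == 1] == 1L))
    expect_identical(sort(got), bruteForce(p$g, p$nMax, p$gMax))
  }
})

test_that("the tiny two-point grid enumerates its three models", {
  specs <- enumerateEC(waveGrid(400, 402, 2), 2, 1)
  got <- lapply(seq_len(nrow(specs)), function(r)
    ecWavelengths(specs$I[r], specs$N[r], specs$G[r], waveGrid(400, 402, 2)))
  expect_setequal(sapply(got, paste, collapse = ","),
                  c("400", "402", "400,402"))
})

test_that("search ranks deterministically by composite with simplicity ties", {
  x <- makeEvalFixture(seed = 21, W = 10, K = 3, nCal = 10, nPred = 8,
                       informative = c(404, 412))
  params <- searchParams(nMax = 5, gMax = 3)
  r1 <- runECSearch(x, params)
  r2 <- runECSearch(x, params)
  expect_equal(r1, r2, ignore_attr = TRUE)
  cmp <- r1$composite
  expect_true(all(diff(cmp) <= 1e-12))
  ties <- which(diff(cmp) == 0)
  for (t in ties) {
    a <- r1[t, ]; b <- r1[t + 1, ]
    expect_true(a$N < b$N || (a$N == b$N && a$G < b$G) ||
                  (a$N == b$N && a$G == b$G && a$I < b$I))
  }
})

test_that("a single perfectly separating wavelength tops the ranking", {
  wl <- seq(400, 416, by = 2)
  W <- length(wl)
  K <- 3
  n <- 12
  cls <- rep(seq_len(K), each = n)
  a <- localSeed(8, matrix(rnorm(W * K * n, 0.5, 0.2), W, K * n))
  a[4, ] <- cls * 10  # wavelength 406 separates the classes perfectly
  x <- tinySpectra(a, wl, cls,
                   set = rep(rep(c("calibration", "prediction"), c(6, 6)), K))
  res <- runECSearch(x, searchParams(nMax = 4, gMax = 3))
  top <- res[1, ]
  expect_true(406 %in% ecWavelengths(top$I, top$N, top$G,
                                     waveGrid(400, 416, 2)))
  expect_equal(top$composite, 100)
  # and the deterministic tie order makes the singleton {406} the winner
  expect_equal(c(top$I, top$N, top$G), c(406, 1, 1))
})

test_that("cube-based search scores equal naive per-model evaluation", {
  x <- makeEvalFixture(seed = 13, W = 9, K = 3, nCal = 9, nPred = 7,
                       informative = c(402, 412))
  st <- fitClassStats(x)
  res <- runECSearch(x, searchParams(nMax = 4, gMax = 3), stats = st)
  g <- spectraGrid(x)
  pick <- localSeed(3, sample(nrow(res), 12))
  for (r in pick) {
    wl <- ecWavelengths(res$I[r], res$N[r], res$G[r], g)
    direct <- evaluateModel(x, st, wl, set = "prediction")
    expect_identical(unname(correctCounts(direct)),
                     as.integer(round(
                       as.numeric(res[r, sprintf("rar.%d", 1:3)]) *
                         classSizes(direct) / 100)))
    expect_identical(compositeScore(direct), res$composite[r])
    expect_identical(rarTotal(direct), res$rarTotal[r])
  }
})

test_that("appending pure-noise wavelengths never changes a model's score", {
  x <- makeEvalFixture(seed = 17, W = 8, K = 2, nCal = 8, nPred = 6,
                       informative = c(404, 410))
  wl <- wavelengths(x)
  extra <- localSeed(4, matrix(rnorm(3 * ncol(x), 0.5, 0.2), 3, ncol(x)))
  cd <- SummarizedExperiment::colData(x)
  x2 <- SpectraSet(rbind(absorbance(x), extra),
                   c(wl, max(wl) + 2 * (1:3)), classLabels(x),
                   cd$bottle_id, cd$sample_id, cd$replicate_id, cd$set)
  st1 <- fitClassStats(x)
  st2 <- fitClassStats(x2)
  for (sub in list(wl[2], wl[c(1, 5)], wl)) {
    r1 <- evaluateModel(x, st1, sub)
    r2 <- evaluateModel(x2, st2, sub)
    expect_identical(correctCounts(r1), correctCounts(r2))
  }
})

test_that("topModels clips deterministically", {
  x <- makeEvalFixture(seed = 2, W = 6, K = 2, nCal = 6, nPred = 5,
                       informative = c(402, 408))
  res <- runECSearch(x, searchParams(nMax = 3, gMax = 2))
  expect_equal(nrow(topModels(res, 10)), 10)
  expect_equal(topModels(res, 1)$composite, max(res$composite))
  expect_equal(nrow(topModels(res, 1e6)), nrow(res))
  expect_true(all(diff(topModels(res, 10)$composite) <= 0))
})
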