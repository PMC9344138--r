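# Small in-code fixtures shared across test files.

# Minimal SpectraSet: one bottle/sample per spectrum unless ids are given.
tinySpectra <- function(a, wl, cls, set = "unassigned", bottle = NULL) {
  a <- as.matrix(a)
  n <- ncol(a)
  if (is.null(bottle)) bottle <- sprintf("b%03d", seq_len(n))
  SpectraSet(a, wl, cls, bottle, paste0(bottle, ".s1"), "r1", set)
}

# Calibration + prediction fixture with K well-separated classes on a small
# grid. Class means differ at `informative` wavelengths (nm) only; all other
# wavelengths are pure noise. Returns a split SpectraSet.
makeEvalFixture <- function(seed = 42, startNm = 400, W = 12, K = 3,
                            nCal = 8, nPred = 6, informative = c(404, 414),
                            sep = 3, noise = 0.2) {
  wl <- startNm + 2 * (seq_len(W) - 1)
  mu <- matrix(0.5, W, K)
  for (j in seq_along(informative)) {
    i <- match(informative[j], wl)
    stopifnot(!is.na(i))
    mu[i, ] <- 0.5 + sep * noise * (seq_len(K) - 1) * (-1)^j
  }
  n <- K * (nCal + nPred)
  cls <- rep(seq_len(K), each = nCal + nPred)
  set <- rep(rep(c("calibration", "prediction"), c(nCal, nPred)), K)
  a <- withr::with_seed(seed,
    mu[, cls, drop = FALSE] + matrix(rnorm(W * n, 0, noise), W, n))
  tinySpectra(a, wl, cls, set)
}

# Deterministic pseudo-data without touching the global RNG stream order
# dependence: helper around withr.
localSeed <- function(seed, code) withr::with_seed(seed, code)
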