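#' Fit per-class Gaussian wavelength statistics
#'
#' For each class present in the chosen set, computes at every grid
#' wavelength the arithmetic mean and the sample standard deviation
#' (denominator n-1) of the absorbances, flooring the standard deviation at
#' `sdFloor`. Fitting always covers the full grid; wavelength-subset models
#' later read the rows they need, so the classifier is never refitted
#' during the search.
#'
#' @param x a [SpectraSet-class]
#' @param sdFloor minimum allowed standard deviation (AU), default `1e-6`
#' @param set which set tag to fit on (default `"calibration"`); `NULL`
#'   fits on all spectra
#' @return a [ClassStats-class]
#' @export
fitClassStats <- function(x, sdFloor = 1e-6, set = "calibration") {
  if (!is.null(set)) x <- subsetBySet(x, set)
  if (ncol(x) == 0L) stop("no spectra to fit on")
  a <- absorbance(x)
  cls <- classLabels(x)
  ids <- sort(unique(cls))
  K <- length(ids)
  W <- nrow(a)
  mu <- sig <- matrix(0, W, K, dimnames = list(NULL, ids))
  nk <- integer(K)
  for (k in seq_len(K)) {
    ak <- a[, cls == ids[k], drop = FALSE]
    nk[k] <- ncol(ak)
    if (nk[k] < 2L)
      stop("class ", ids[k], " has fewer than 2 calibration spectra")
    m <- rowMeans(ak)
    mu[, k] <- m
    sig[, k] <- pmax(sqrt(rowSums((ak - m)^2) / (nk[k] - 1L)), sdFloor)
  }
  new("ClassStats", classIds = as.integer(ids), mu = mu, sigma = sig,
      sdFloor = as.numeric(sdFloor), wavelength = as.numeric(wavelengths(x)),
      nPerClass = nk)
}

setMethod("show", "ClassStats", function(object) {
  cat(sprintf(
    "ClassStats: %d classes x %d wavelengths (sd floor %g AU)\n",
    length(object@classIds), length(object@wavelength), object@sdFloor))
  cat("  calibration spectra per class:",
      paste(sprintf("%d:%d", object@classIds, object@nPerClass),
            collapse = " "), "\n")
})

#' @rdname fitClassStats
#' @param stats a [ClassStats-class]
#' @return `classMeans()` / `classSDs()`: the wavelength-by-class matrix
#' @export
classMeans <- function(stats) stats@mu

#' @rdname fitClassStats
#' @export
classSDs <- function(stats) stats@sigma

#' @rdname fitClassStats
#' @param path CSV path for the audit export (rows = wavelengths, one mean
#'   and one sd column per class)
#' @export
writeClassStats <- function(stats, path) {
  df <- data.frame(wavelength_nm = stats@wavelength)
  for (k in seq_along(stats@classIds)) {
    df[[sprintf("mu_%d", stats@classIds[k])]] <- stats@mu[, k]
    df[[sprintf("sigma_%d", stats@classIds[k])]] <- stats@sigma[, k]
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Class prior probabilities
#'
#' Either proportional to the calibration spectrum counts or equal across
#' classes. A numeric vector of positive probabilities (one per class,
#' summing to 1) is also accepted and passed through.
#'
#' @param stats a [ClassStats-class]
#' @param priors `"proportional"` (default), `"equal"`, or a numeric vector
#' @return named numeric vector of priors summing to 1
#' @export
classPriors <- function(stats, priors = c("proportional", "equal")) {
  K <- length(stats@classIds)
  if (is.numeric(priors)) {
    if (length(priors) != K || any(priors <= 0))
      stop("numeric priors must be positive with one entry per class")
    p <- priors / sum(priors)
  } else {
    priors <- match.arg(priors)
    p <- if (priors == "equal") rep(1 / K, K)
         else stats@nPerClass / sum(stats@nPerClass)
  }
  if (abs(sum(p) - 1) > 1e-12) stop("priors must sum to 1")
  names(p) <- stats@classIds
  p
}

#' Gaussian log density
#'
#' Natural log of the normal density at `x`; may exceed 0 for small sigma
#' (densities above 1 are legal).
#'
#' @param x absorbance value(s)
#' @param mu mean absorbance
#' @param sigma standard deviation; must be positive
#' @return log density value(s)
#' @export
logDensity <- function(x, mu, sigma) {
  if (any(sigma <= 0)) stop("sigma must be positive")
  dnorm(x, mu, sigma, log = TRUE)
}

# Resolve requested wavelengths (nm) to ascending row indices of stats.
.wlIndices <- function(stats, wl) {
  if (is.null(wl)) return(seq_along(stats@wavelength))
  if (length(wl) == 0L) stop("wavelength subset must be non-empty")
  idx <- match(wl, stats@wavelength)
  if (anyNA(idx))
    stop("wavelength(s) not covered by the fitted grid: ",
         paste(wl[is.na(idx)], collapse = ", "))
  sort(idx)
}

#' Per-class log conditional of a spectrum
#'
#' Sum over the selected wavelengths of the Gaussian log densities: the
#' overflow-safe log form of the naive Bayes product of per-wavelength
#' conditionals. Summation runs in ascending wavelength order in plain
#' double precision, the same order and precision as the precomputed-cube
#' path, so the two routes agree bit for bit.
#'
#' @param spectrum absorbance vector over the full fitted grid
#' @param stats a [ClassStats-class]
#' @param wl wavelength subset (nm); `NULL` means the full grid
#' @return named numeric vector: `ln P(spectrum | class = k)` per class
#' @export
logConditional <- function(spectrum, stats, wl = NULL) {
  idx <- .wlIndices(stats, wl)
  K <- length(stats@classIds)
  out <- numeric(K)
  for (k in seq_len(K)) {
    acc <- 0
    for (i in idx)
      acc <- acc + dnorm(spectrum[i], stats@mu[i, k], stats@sigma[i, k],
                         log = TRUE)
    out[k] <- acc
  }
  names(out) <- stats@classIds
  out
}

#' Posterior class probabilities
#'
#' Normalizes `exp(logConditional + log prior)` across classes with the
#' log-sum-exp stabilization, so the Bayes formula never overflows.
#'
#' @param logConditionals per-class log conditionals: a vector, or a
#'   K-by-n matrix (one column per spectrum)
#' @param priors prior probabilities (one per class, summing to 1)
#' @return posteriors of the same shape, each column summing to 1
#' @export
posteriorProbs <- function(logConditionals, priors) {
  if (any(priors <= 0) || abs(sum(priors) - 1) > 1e-12)
    stop("priors must be positive and sum to 1")
  lp <- log(priors)
  if (is.matrix(logConditionals)) {
    z <- logConditionals + lp
    m <- apply(z, 2L, max)
    e <- exp(sweep(z, 2L, m))
    sweep(e, 2L, colSums(e), "/")
  } else {
    z <- logConditionals + lp
    e <- exp(z - max(z))
    e / sum(e)
  }
}

# Per-class decision scores for all columns of `a` (wavelengths x spectra):
# sequential double accumulation in ascending wavelength order plus log
# prior, mirroring the C++ cube kernel exactly.
.decisionScores <- function(a, stats, idx, logPrior) {
  K <- length(stats@classIds)
  S <- ncol(a)
  score <- matrix(0, K, S)
  for (k in seq_len(K)) {
    acc <- numeric(S)
    for (i in idx)
      acc <- acc + dnorm(a[i, ], stats@mu[i, k], stats@sigma[i, k],
                         log = TRUE)
    score[k, ] <- acc + logPrior[k]
  }
  score
}

# Strict-greater argmax over rows, first (smallest class) wins ties.
.argmaxRows <- function(score) {
  best <- rep(1L, ncol(score))
  bestv <- score[1L, ]
  if (nrow(score) > 1L) for (k in 2:nrow(score)) {
    upd <- score[k, ] > bestv
    best[upd] <- k
    bestv[upd] <- score[k, upd]
  }
  best
}

#' Classify spectra
#'
#' Assigns each spectrum the class maximizing
#' `ln P(class = k) + ln P(spectrum | class = k)` over the selected
#' wavelengths (`rule = "posterior"`, the default), or the bare log
#' conditional (`rule = "conditional"`, equivalent to equal priors). Ties
#' break toward the smallest class label.
#'
#' @param x a [SpectraSet-class] or a wavelength-by-spectrum matrix on the
#'   fitted grid
#' @param stats a [ClassStats-class] fitted on the calibration set
#' @param wl wavelength subset (nm); `NULL` means the full grid
#' @param priors see [classPriors()]
#' @param rule decision rule, `"posterior"` or `"conditional"`
#' @return integer vector of predicted class labels
#' @export
predictClasses <- function(x, stats, wl = NULL, priors = "proportional",
                           rule = c("posterior", "conditional")) {
  rule <- match.arg(rule)
  a <- if (is(x, "SpectraSet")) absorbance(x) else as.matrix(x)
  if (nrow(a) != length(stats@wavelength))
    stop("spectra are not on the fitted grid")
  idx <- .wlIndices(stats, wl)
  logPrior <- if (rule == "conditional") rep(0, length(stats@classIds))
              else log(classPriors(stats, priors))
  score <- .decisionScores(a, stats, idx, logPrior)
  stats@classIds[.argmaxRows(score)]
}

#' Precompute the log-density cube
#'
#' Evaluates, for every spectrum, wavelength and class, the Gaussian log
#' density under the class statistics. Any wavelength-subset model is then
#' scored by summing its rows (ascending order), reproducing
#' [logConditional()] bit-identically while costing only additions.
#'
#' @param x a [SpectraSet-class] (already restricted to the evaluation set
#'   of interest) or a wavelength-by-spectrum matrix
#' @param stats a [ClassStats-class] on the same grid
#' @return a [LogDensityCube-class]
#' @export
precomputeCube <- function(x, stats) {
  a <- if (is(x, "SpectraSet")) absorbance(x) else as.matrix(x)
  if (nrow(a) != length(stats@wavelength))
    stop("spectra are not on the fitted grid")
  dens <- lapply(seq_along(stats@classIds), function(k)
    dnorm(a, stats@mu[, k], stats@sigma[, k], log = TRUE))
  new("LogDensityCube", densities = dens, classIds = stats@classIds,
      wavelength = stats@wavelength)
}

setMethod("show", "LogDensityCube", function(object) {
  cat(sprintf("LogDensityCube: %d classes x %d wavelengths x %d spectra\n",
              length(object@classIds), length(object@wavelength),
              ncol(object@densities[[1L]])))
})

#' Subset-sum a log-density cube
#'
#' @param cube a [LogDensityCube-class]
#' @param wl wavelength subset (nm); `NULL` means the full grid
#' @return K-by-n matrix of per-class log conditionals (one column per
#'   spectrum), identical bit for bit to per-spectrum [logConditional()]
#' @export
cubeLogConditional <- function(cube, wl = NULL) {
  idx <- if (is.null(wl)) seq_along(cube@wavelength)
         else sort(match(wl, cube@wavelength))
  if (anyNA(idx)) stop("wavelength(s) not in cube")
  if (length(idx) == 0L) stop("wavelength subset must be non-empty")
  K <- length(cube@classIds)
  S <- ncol(cube@densities[[1L]])
  out <- matrix(0, K, S)
  for (k in seq_len(K)) {
    acc <- numeric(S)
    d <- cube@densities[[k]]
    for (i in idx) acc <- acc + d[i, ]
    out[k, ] <- acc
  }
  rownames(out) <- cube@classIds
  out
}
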