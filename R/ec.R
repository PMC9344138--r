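#' Wavelengths of an equidistant combination model
#'
#' An equidistant model is defined by its initial wavelength `I` (nm, on
#' grid), its number of wavelengths `N`, and its gap `G` in grid steps;
#' successive wavelengths are `step * G` nm apart and the ending wavelength
#' is `E = I + step * (N - 1) * G`, which must not pass the grid end.
#'
#' @param I initial wavelength (nm, on grid)
#' @param N number of wavelengths (>= 1)
#' @param G gap between consecutive wavelengths, in grid steps (>= 1)
#' @param grid a [WaveGrid-class]
#' @return numeric vector of `N` wavelengths; the last element is `E`
#' @examples
#' wl <- ecWavelengths(404, 22, 49, waveGrid(400, 2498, 2))
#' tail(wl, 1)  # ending wavelength 2462
#' @export
ecWavelengths <- function(I, N, G, grid) {
  stopifnot(is(grid, "WaveGrid"), N >= 1L, G >= 1L)
  wavelengthIndex(grid, I)  # validates I is on grid
  wl <- I + grid@step * G * (0:(N - 1L))
  E <- wl[N]
  if (E > grid@end + 1e-9)
    stop(sprintf("ending wavelength %g nm exceeds the grid end %g nm",
                 E, grid@end))
  wl
}

#' Enumerate every valid equidistant model on a grid
#'
#' Yields every canonical `(I, N, G)` with `I` on the grid,
#' `1 <= N <= nMax`, `1 <= G <= gMax`, and ending wavelength inside the
#' grid. Single-wavelength models (`N = 1`) are emitted once each with
#' `G = 1` (the gap is meaningless for a singleton). `iStride` coarsens the
#' start-wavelength lattice and `budget` caps the number of models, both
#' for desk-scale runs; at their defaults the enumeration is exhaustive.
#'
#' @param grid a [WaveGrid-class]
#' @param nMax,gMax upper bounds on `N` and `G`
#' @param iStride stride over start positions, in grid steps (default 1)
#' @param budget maximum number of models to emit (default unlimited)
#' @return data.frame with columns `I`, `E`, `N`, `G` and the 0-based start
#'   index `i0`
#' @export
enumerateEC <- function(grid, nMax, gMax, iStride = 1L, budget = Inf) {
  stopifnot(is(grid, "WaveGrid"), nMax >= 1L, gMax >= 1L, iStride >= 1L)
  W <- nWavelengths(grid)
  parts <- list()
  i0_all <- seq.int(0L, W - 1L, by = iStride)
  parts[[1L]] <- data.frame(i0 = i0_all, N = 1L, G = 1L)
  for (g in seq_len(gMax)) {
    for (n in 2:max(2L, nMax)) {
      if (nMax < 2L) break
      span <- (n - 1L) * g
      m <- W - span  # number of valid start positions
      if (m < 1L) break
      parts[[length(parts) + 1L]] <-
        data.frame(i0 = seq.int(0L, m - 1L, by = iStride), N = n, G = g)
    }
  }
  out <- do.call(rbind, parts)
  if (is.finite(budget)) out <- utils::head(out, budget)
  out$I <- grid@start + grid@step * out$i0
  out$E <- out$I + grid@step * (out$N - 1L) * out$G
  out[, c("I", "E", "N", "G", "i0")]
}

#' Search and refinement parameters
#'
#' @param nMax,gMax equidistant-model bounds (study-scale defaults 1050
#'   and 50)
#' @param iStride start-position stride in grid steps, for desk-scale runs
#' @param budget cap on the number of enumerated models
#' @param evalSet set tag scored during model selection (default
#'   `"prediction"`; the validation set is never touched during search)
#' @param priors see [classPriors()]
#' @param rule decision rule, see [predictClasses()]
#' @param sdFloor standard-deviation floor for fitting (AU)
#' @param topK number of top-ranked models passed to phase-out refinement
#' @param criterion phase-out scoring criterion, `"composite"` (default,
#'   consistent with the search ranking) or `"rarTotal"`
#' @return a `SearchParams` list
#' @export
searchParams <- function(nMax = 1050L, gMax = 50L, iStride = 1L,
                         budget = Inf, evalSet = "prediction",
                         priors = "proportional",
                         rule = c("posterior", "conditional"),
                         sdFloor = 1e-6, topK = 10L,
                         criterion = c("composite", "rarTotal")) {
  stopifnot(nMax >= 1L, gMax >= 1L, iStride >= 1L, topK >= 1L)
  p <- list(nMax = as.integer(nMax), gMax = as.integer(gMax),
            iStride = as.integer(iStride), budget = budget,
            evalSet = evalSet, priors = priors, rule = match.arg(rule),
            sdFloor = sdFloor, topK = as.integer(topK),
            criterion = match.arg(criterion))
  class(p) <- c("SearchParams", "list")
  p
}

#' Scoring context for wavelength-model evaluation
#'
#' Bundles everything needed to score arbitrary wavelength subsets of one
#' evaluation set: the precomputed log-density cube, log priors, true
#' labels and class sizes. Built once, then shared by the exhaustive search
#' and the phase-out so that every model is scored identically.
#'
#' @param x a [SpectraSet-class] with assigned sets
#' @param stats a [ClassStats-class] fitted on the calibration set
#' @param set set tag to score (default `"prediction"`)
#' @param priors,rule see [predictClasses()]
#' @return a `bayesEvaluator` list
#' @export
bayesEvaluator <- function(x, stats, set = "prediction",
                           priors = "proportional",
                           rule = c("posterior", "conditional")) {
  rule <- match.arg(rule)
  xs <- subsetBySet(x, set)
  if (ncol(xs) == 0L) stop("no spectra carry set tag '", set, "'")
  pos <- match(classLabels(xs), stats@classIds)
  if (anyNA(pos))
    stop("evaluation set contains class(es) absent from the fitted stats")
  K <- length(stats@classIds)
  sizes <- tabulate(pos, K)
  if (any(sizes == 0L))
    stop("class ", paste(stats@classIds[sizes == 0L], collapse = ", "),
         " has no spectra in set '", set, "'")
  logPrior <- if (rule == "conditional") rep(0, K)
              else log(classPriors(stats, priors))
  ev <- list(cube = precomputeCube(xs, stats)@densities,
             wavelength = stats@wavelength,
             logPrior = logPrior,
             truePos = pos,
             sizes = sizes,
             classIds = stats@classIds,
             set = set)
  class(ev) <- c("bayesEvaluator", "list")
  ev
}

# Correct counts for arbitrary wavelength subsets (list of nm vectors).
.evalSubsets <- function(ev, wlList) {
  idx <- lapply(wlList, function(wl) {
    i <- match(wl, ev$wavelength)
    if (anyNA(i)) stop("wavelength(s) not on the evaluator grid")
    sort.int(i) - 1L
  })
  cppCountCorrectSubsets(ev$cube, ev$logPrior, ev$truePos, idx)
}

#' Score a single wavelength subset with an evaluator
#'
#' @param ev a [bayesEvaluator()]
#' @param wl wavelength subset (nm)
#' @return an [RAResult-class]
#' @export
evaluateSubset <- function(ev, wl) {
  counts <- .evalSubsets(ev, list(wl))
  .raFromCounts(counts[1L, ], ev$sizes, ev$classIds, ev$set)
}

#' Fit-once evaluation of a single wavelength model (direct route)
#'
#' Classifies the chosen set with [predictClasses()] (no precomputed cube)
#' and scores it. This is the plain per-model route; the cube-based search
#' reproduces its counts exactly.
#'
#' @param x a [SpectraSet-class] with assigned sets
#' @param stats a [ClassStats-class]
#' @param wl wavelength subset (nm); `NULL` means the full grid
#' @param set set tag to score
#' @param priors,rule see [predictClasses()]
#' @return an [RAResult-class]
#' @export
evaluateModel <- function(x, stats, wl = NULL, set = "prediction",
                          priors = "proportional",
                          rule = c("posterior", "conditional")) {
  xs <- subsetBySet(x, set)
  pred <- predictClasses(xs, stats, wl, priors, match.arg(rule))
  evaluateRecognition(classLabels(xs), pred, stats@classIds, evalSet = set)
}

#' Exhaustive equidistant-combination search
#'
#' Enumerates every valid equidistant wavelength model within the bounds,
#' scores each on the evaluation set through the log-density cube, and
#' ranks by the composite indicator (`RAR_Total - RAR_SD`) in descending
#' order with a deterministic tie order: fewer wavelengths first, then
#' smaller gap, then smaller initial wavelength.
#'
#' @param x a [SpectraSet-class] with assigned sets (ignored when
#'   `evaluator` is supplied)
#' @param params a [searchParams()]
#' @param stats optional prefitted [ClassStats-class]; fitted on the
#'   calibration set when absent
#' @param evaluator optional prebuilt [bayesEvaluator()]
#' @return ranked data.frame with columns `I`, `E`, `N`, `G`, per-class
#'   rates, `rarTotal`, `rarSD`, `composite`; the evaluator is attached as
#'   attribute `"evaluator"`
#' @export
runECSearch <- function(x = NULL, params = searchParams(), stats = NULL,
                        evaluator = NULL) {
  if (is.null(evaluator)) {
    if (is.null(stats)) stats <- fitClassStats(x, sdFloor = params$sdFloor)
    evaluator <- bayesEvaluator(x, stats, set = params$evalSet,
                                priors = params$priors, rule = params$rule)
  }
  wl <- evaluator$wavelength
  step <- if (length(wl) > 1L) wl[2L] - wl[1L] else 2
  grid <- waveGrid(wl[1L], wl[length(wl)], step)
  specs <- enumerateEC(grid, params$nMax, params$gMax, params$iStride,
                       params$budget)
  counts <- cppCountCorrectEC(evaluator$cube, evaluator$logPrior,
                              evaluator$truePos, specs$i0, specs$N, specs$G)
  st <- rarStats(counts, evaluator$sizes)
  res <- cbind(specs[, c("I", "E", "N", "G")], st)
  ord <- order(-res$composite, res$N, res$G, res$I, method = "radix")
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "evaluator") <- evaluator
  attr(res, "params") <- params
  res
}

#' First k models of a ranked search result
#'
#' @param results a ranked data.frame from [runECSearch()]
#' @param k how many models to keep (fewer are returned if fewer exist)
#' @return the first `k` rows
#' @export
topModels <- function(results, k = 10L) {
  stopifnot(k >= 1L)
  utils::head(results, k)
}
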