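.criterionOf <- function(result, criterion) {
  switch(criterion, composite = result@composite, rarTotal = result@rarTotal,
         stop("unknown criterion: ", criterion))
}

#' One greedy phase-out step
#'
#' Evaluates every single-wavelength removal from the current set with the
#' calibration-fitted statistics and removes the wavelength whose removal
#' yields the highest criterion value on the evaluation set. Ties remove
#' the smallest wavelength.
#'
#' @param current current wavelength set (nm), length >= 2
#' @param ev a [bayesEvaluator()]
#' @param criterion `"composite"` (default) or `"rarTotal"`
#' @return list with `removed` (nm), `remaining` (nm vector) and `result`
#'   (the [RAResult-class] after removal)
#' @export
wspStep <- function(current, ev, criterion = c("composite", "rarTotal")) {
  criterion <- match.arg(criterion)
  current <- sort(current)
  n <- length(current)
  if (n < 2L) stop("phase-out needs at least 2 wavelengths")
  cands <- lapply(seq_len(n), function(j) current[-j])
  counts <- .evalSubsets(ev, cands)
  st <- rarStats(counts, ev$sizes)
  score <- if (criterion == "composite") st$composite else st$rarTotal
  pick <- which.max(score)  # first maximum = smallest removed wavelength
  list(removed = current[pick], remaining = cands[[pick]],
       result = .raFromCounts(counts[pick, ], ev$sizes, ev$classIds, ev$set))
}

#' Full greedy phase-out path
#'
#' Starting from a wavelength set, repeatedly applies [wspStep()] until a
#' single wavelength remains, recording every state (including the start)
#' with its evaluation.
#'
#' @param start starting wavelength set (nm), non-empty
#' @param ev a [bayesEvaluator()]
#' @param criterion `"composite"` (default) or `"rarTotal"`
#' @return a [WSPPath-class]
#' @export
wspPath <- function(start, ev, criterion = c("composite", "rarTotal")) {
  criterion <- match.arg(criterion)
  start <- sort(start)
  if (length(start) < 1L) stop("starting set must be non-empty")
  states <- list(start)
  results <- list(evaluateSubset(ev, start))
  removed <- numeric(0)
  current <- start
  while (length(current) >= 2L) {
    stp <- wspStep(current, ev, criterion)
    current <- stp$remaining
    states[[length(states) + 1L]] <- current
    results[[length(results) + 1L]] <- stp$result
    removed <- c(removed, stp$removed)
  }
  new("WSPPath", wavelengths = states, results = results,
      removed = removed, criterion = criterion)
}

#' Best model along a phase-out path
#'
#' Returns the state maximizing the path criterion; ties prefer fewer
#' wavelengths and, at equal count, the later (more reduced) state.
#'
#' @param path a [WSPPath-class]
#' @return list with `wavelengths`, `result`, `stateIndex`
#' @export
selectBest <- function(path) {
  n <- length(path@wavelengths)
  if (n == 0L) stop("empty path")
  best <- 1L
  bestScore <- .criterionOf(path@results[[1L]], path@criterion)
  if (n > 1L) for (j in 2:n) {
    s <- .criterionOf(path@results[[j]], path@criterion)
    # states shrink monotonically, so >= implements "fewer wavelengths,
    # then later state" on ties
    if (s >= bestScore) { best <- j; bestScore <- s }
  }
  list(wavelengths = path@wavelengths[[best]],
       result = path@results[[best]], stateIndex = best)
}

#' @describeIn wspPath numeric trace of a path (one row per state)
#' @param x a [WSPPath-class]
#' @param ... unused
#' @export
pathTrace <- function(x, ...) {
  data.frame(
    state = seq_along(x@wavelengths),
    nWavelengths = lengths(x@wavelengths),
    removed_nm = c(NA, x@removed),
    rarTotal = vapply(x@results, slot, numeric(1L), "rarTotal"),
    rarSD = vapply(x@results, slot, numeric(1L), "rarSD"),
    composite = vapply(x@results, slot, numeric(1L), "composite"))
}

setMethod("show", "WSPPath", function(object) {
  sel <- selectBest(object)
  cat(sprintf(
    "WSPPath: %d -> 1 wavelengths (criterion %s); best state %d (N = %d, %s %.1f)\n",
    length(object@wavelengths[[1L]]), object@criterion, sel$stateIndex,
    length(sel$wavelengths), object@criterion,
    .criterionOf(sel$result, object@criterion)))
})

setMethod("length", "WSPPath", function(x) length(x@wavelengths))
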