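#' @import methods
#' @importFrom stats dnorm rnorm
#' @importFrom S4Vectors DataFrame metadata SimpleList
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
#'   rowData assayNames
#' @importFrom SummarizedExperiment colData<-
#' @importFrom Rcpp sourceCpp
#' @useDynLib SpectralNB, .registration = TRUE
NULL

.SET_TAGS <- c("calibration", "prediction", "validation", "unassigned")
.META_COLS <- c("class_label", "bottle_id", "sample_id", "replicate_id", "set")

#' Uniform wavelength grid
#'
#' A strictly increasing, equally spaced set of wavelengths defined by its
#' first wavelength, last wavelength and step, all in nanometres. The
#' instrument grid used throughout the package examples is 400--2498 nm at a
#' 2 nm step (1050 points).
#'
#' @slot start first wavelength (nm)
#' @slot end last wavelength (nm)
#' @slot step positive wavelength increment (nm)
#' @seealso [waveGrid()], [gridWavelengths()], [wavelengthIndex()]
#' @exportClass WaveGrid
setClass("WaveGrid",
  representation(start = "numeric", end = "numeric", step = "numeric"))

setValidity("WaveGrid", function(object) {
  msg <- character()
  if (length(object@start) != 1L || length(object@end) != 1L ||
      length(object@step) != 1L)
    msg <- c(msg, "start, end and step must be scalars")
  else {
    if (!is.finite(object@step) || object@step <= 0)
      msg <- c(msg, "step must be a positive number")
    if (object@start >= object@end)
      msg <- c(msg, "start must be smaller than end")
    r <- (object@end - object@start) / object@step
    if (abs(r - round(r)) > 1e-9)
      msg <- c(msg, "end - start must be an integer multiple of step")
  }
  if (length(msg)) msg else TRUE
})

#' Spectral dataset container
#'
#' `SpectraSet` extends [SummarizedExperiment::SummarizedExperiment] with an
#' `"absorbance"` assay holding one column per measured spectrum and one row
#' per grid wavelength. Column metadata records the class label, the
#' bottle/sample/replicate hierarchy, and the set assignment
#' (`calibration` / `prediction` / `validation` / `unassigned`); row metadata
#' records the wavelength in nm.
#'
#' All spectra of one physical sample share a bottle and a class label, and
#' grouped splitting ([groupedSplit()]) keeps every bottle's spectra in a
#' single set so that replicate structure never leaks between sets.
#'
#' @seealso [SpectraSet()], [readSpectra()], [writeSpectra()], [groupedSplit()]
#' @exportClass SpectraSet
setClass("SpectraSet", contains = "SummarizedExperiment")

setValidity("SpectraSet", function(object) {
  msg <- character()
  if (!"absorbance" %in% SummarizedExperiment::assayNames(object))
    return("assay 'absorbance' is required")
  cd <- colData(object)
  missing_cols <- setdiff(.META_COLS, colnames(cd))
  if (length(missing_cols))
    return(paste0("missing metadata column(s): ",
                  paste(missing_cols, collapse = ", ")))
  wl <- rowData(object)$wavelength_nm
  if (is.null(wl))
    return("rowData column 'wavelength_nm' is required")
  if (length(wl) > 1L) {
    d <- diff(wl)
    if (any(d <= 0))
      msg <- c(msg, "wavelengths must be strictly increasing")
    else if (max(d) - min(d) > 1e-9)
      msg <- c(msg, "wavelengths must be uniformly spaced")
  }
  a <- assay(object, "absorbance")
  if (length(a) && !all(is.finite(a)))
    msg <- c(msg, "absorbance values must all be finite")
  bad_set <- setdiff(unique(as.character(cd$set)), .SET_TAGS)
  if (length(bad_set))
    msg <- c(msg, paste0("invalid set tag(s): ", paste(bad_set, collapse = ", ")))
  if (ncol(object)) {
    key <- paste(cd$sample_id)
    bb <- tapply(as.character(cd$bottle_id), key, function(z) length(unique(z)))
    kk <- tapply(cd$class_label, key, function(z) length(unique(z)))
    if (any(bb > 1L))
      msg <- c(msg, "every spectrum of one sample_id must share bottle_id")
    if (any(kk > 1L))
      msg <- c(msg, "every spectrum of one sample_id must share class_label")
  }
  if (length(msg)) msg else TRUE
})

#' Per-class Gaussian wavelength statistics
#'
#' The conditional model of the naive Bayes classifier: for each class and
#' each grid wavelength, the arithmetic mean and the sample standard
#' deviation (denominator n-1) of the calibration absorbances, with the
#' standard deviation floored at `sdFloor` to guard against degenerate
#' zero-variance wavelengths. Statistics are fitted once over the full grid;
#' any wavelength-subset model simply reads its rows.
#'
#' @slot classIds ordered integer class labels (length K)
#' @slot mu wavelength-by-class matrix of mean absorbances (AU)
#' @slot sigma wavelength-by-class matrix of floored standard deviations (AU)
#' @slot sdFloor minimum allowed standard deviation (AU)
#' @slot wavelength grid wavelengths (nm)
#' @slot nPerClass calibration spectrum count per class
#' @seealso [fitClassStats()], [classPriors()], [predictClasses()]
#' @exportClass ClassStats
setClass("ClassStats",
  representation(classIds = "integer", mu = "matrix", sigma = "matrix",
                 sdFloor = "numeric", wavelength = "numeric",
                 nPerClass = "integer"))

setValidity("ClassStats", function(object) {
  msg <- character()
  K <- length(object@classIds)
  W <- length(object@wavelength)
  if (!identical(dim(object@mu), c(W, K)))
    msg <- c(msg, "mu must be wavelength x class")
  if (!identical(dim(object@sigma), c(W, K)))
    msg <- c(msg, "sigma must be wavelength x class")
  if (length(object@sdFloor) != 1L || object@sdFloor <= 0)
    msg <- c(msg, "sdFloor must be a positive scalar")
  else if (length(object@sigma) && any(object@sigma < object@sdFloor))
    msg <- c(msg, "sigma must be >= sdFloor everywhere")
  if (length(object@nPerClass) != K)
    msg <- c(msg, "nPerClass must have one entry per class")
  if (length(msg)) msg else TRUE
})

#' Precomputed log-density cube
#'
#' For every (spectrum, wavelength, class) triple, the natural log of the
#' Gaussian density of that absorbance under the class statistics. Summing
#' cube entries over any wavelength subset (in ascending wavelength order)
#' reproduces the direct per-subset log conditional bit-identically, which is
#' what makes the exhaustive equidistant-combination search tractable: the
#' classifier is fitted once and millions of wavelength models are scored by
#' subset sums.
#'
#' @slot densities list of K wavelength-by-spectrum log-density matrices,
#'   one per class (in `classIds` order)
#' @slot classIds integer class labels
#' @slot wavelength grid wavelengths (nm)
#' @seealso [precomputeCube()], [cubeLogConditional()]
#' @exportClass LogDensityCube
setClass("LogDensityCube",
  representation(densities = "list", classIds = "integer",
                 wavelength = "numeric"))

#' Recognition-accuracy evaluation of one wavelength model
#'
#' Per-class recognition accuracy rates (RAR_i, percent), their sample
#' standard deviation RAR_SD (denominator K-1), the spectrum-weighted total
#' RAR_Total, and the composite model-selection indicator
#' RAR_Total - RAR_SD (percentage points).
#'
#' @slot classIds integer class labels
#' @slot classSizes spectrum count per class in the evaluated set
#' @slot correctCounts correctly identified spectra per class
#' @slot rarPerClass per-class recognition accuracy (percent)
#' @slot rarTotal total recognition accuracy (percent)
#' @slot rarSD sample standard deviation of the per-class rates (percent)
#' @slot composite `rarTotal - rarSD` (percentage points)
#' @slot evalSet which set tag was scored
#' @seealso [evaluateRecognition()], [compositeScore()]
#' @exportClass RAResult
setClass("RAResult",
  representation(classIds = "integer", classSizes = "integer",
                 correctCounts = "integer", rarPerClass = "numeric",
                 rarTotal = "numeric", rarSD = "numeric",
                 composite = "numeric", evalSet = "character"))

setValidity("RAResult", function(object) {
  msg <- character()
  K <- length(object@classIds)
  if (length(object@classSizes) != K || length(object@correctCounts) != K ||
      length(object@rarPerClass) != K)
    msg <- c(msg, "per-class slots must all have length K")
  if (any(object@correctCounts < 0L) ||
      any(object@correctCounts > object@classSizes))
    msg <- c(msg, "correctCounts must lie in [0, classSizes]")
  if (length(msg)) msg else TRUE
})

#' Greedy wavelength phase-out path
#'
#' The ordered record of a wavelength step-by-step phase-out run: the
#' starting wavelength set and, after each single-wavelength removal, the
#' remaining set with its evaluation, down to one wavelength. The final
#' model is the best state seen anywhere along the path ([selectBest()]).
#'
#' @slot wavelengths list of wavelength sets (nm), from start to singleton
#' @slot results list of [RAResult-class] evaluations, parallel to
#'   `wavelengths`
#' @slot removed wavelengths removed at each step (nm)
#' @slot criterion scoring criterion used for removal decisions
#'   (`"composite"` or `"rarTotal"`)
#' @seealso [wspPath()], [wspStep()], [selectBest()]
#' @exportClass WSPPath
setClass("WSPPath",
  representation(wavelengths = "list", results = "list",
                 removed = "numeric", criterion = "character"))

setValidity("WSPPath", function(object) {
  msg <- character()
  n <- length(object@wavelengths)
  if (length(object@results) != n)
    msg <- c(msg, "one result per state is required")
  if (length(object@removed) != n - 1L)
    msg <- c(msg, "removed must have one entry per step")
  sizes <- lengths(object@wavelengths)
  if (n > 1L && any(diff(sizes) != -1L))
    msg <- c(msg, "consecutive states must differ by exactly one wavelength")
  if (length(msg)) msg else TRUE
})

#' Full search-and-refine report
#'
#' Result bundle of [ecWspPipeline()]: the full-grid direct Bayes baseline,
#' the ranked equidistant-combination search, the top-ranked models with
#' their phase-out paths and refined selections, the overall winner, and the
#' winner's one-shot validation evaluation.
#'
#' @slot baseline [RAResult-class] of the full-grid direct Bayes model
#' @slot ecResults ranked data.frame of all evaluated equidistant models
#' @slot topSpecs the top-k rows of `ecResults` passed to refinement
#' @slot paths list of [WSPPath-class], one per top model
#' @slot refined data.frame comparing each top model before/after refinement
#' @slot winner list: `wavelengths`, `result`, `parentRank`
#' @slot validation [RAResult-class] of the winner on the validation set, or
#'   `NULL` when validation was not requested
#' @slot validationPredictions data.frame of per-spectrum true and
#'   predicted labels on the validation set (zero rows when validation was
#'   not requested)
#' @slot params the [searchParams()] used
#' @slot manifest list of run facts (counts, seeds, versions)
#' @exportClass ECWSPReport
setClass("ECWSPReport",
  representation(baseline = "RAResult", ecResults = "data.frame",
                 topSpecs = "data.frame", paths = "list",
                 refined = "data.frame", winner = "list",
                 validation = "ANY", validationPredictions = "data.frame",
                 params = "list", manifest = "list"))
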