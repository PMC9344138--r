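#' Recognition-accuracy arithmetic from correct counts
#'
#' Vectorized core shared by every evaluation route in the package (single
#' models, the exhaustive search and the phase-out all call it), so scores
#' from different routes are identical by construction. Per-class rates are
#' `100 * correct / size`; the total is the spectrum-weighted identity
#' `100 * sum(correct) / sum(size)`; the dispersion is the sample standard
#' deviation (denominator K-1) of the K per-class rates; the composite is
#' `total - sd`.
#'
#' @param counts matrix of correct counts, one row per model, one column
#'   per class (a vector is treated as one row)
#' @param sizes spectrum count per class
#' @return data.frame with columns `rar.<class i>` (percent), `rarTotal`,
#'   `rarSD`, `composite`
#' @export
rarStats <- function(counts, sizes) {
  if (!is.matrix(counts)) counts <- matrix(counts, nrow = 1L)
  K <- length(sizes)
  stopifnot(ncol(counts) == K)
  if (any(sizes <= 0L)) stop("every class must have at least one spectrum")
  rar <- 100 * sweep(counts, 2L, sizes, "/")
  total <- 100 * rowSums(counts) / sum(sizes)
  ctr <- rar - rowMeans(rar)
  sdv <- sqrt(rowSums(ctr * ctr) / (K - 1L))
  out <- as.data.frame(rar)
  colnames(out) <- paste0("rar.", seq_len(K))
  out$rarTotal <- total
  out$rarSD <- sdv
  out$composite <- total - sdv
  out
}

.raFromCounts <- function(counts, sizes, classIds, evalSet = NA_character_) {
  st <- rarStats(counts, sizes)
  new("RAResult", classIds = as.integer(classIds),
      classSizes = as.integer(sizes),
      correctCounts = as.integer(counts),
      rarPerClass = as.numeric(st[1L, seq_along(sizes)]),
      rarTotal = st$rarTotal[1L], rarSD = st$rarSD[1L],
      composite = st$composite[1L], evalSet = as.character(evalSet))
}

#' Evaluate predicted against true class labels
#'
#' @param truth integer vector of true class labels
#' @param predicted integer vector of predicted labels, same length
#' @param classIds class label order for reporting; defaults to the sorted
#'   labels present in `truth`, every one of which must be represented
#' @param evalSet optional tag recording which set was scored
#' @return an [RAResult-class]
#' @export
evaluateRecognition <- function(truth, predicted,
                                classIds = sort(unique(truth)),
                                evalSet = NA_character_) {
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length")
  pos <- match(truth, classIds)
  if (anyNA(pos))
    stop("true label(s) outside classIds: ",
         paste(unique(truth[is.na(pos)]), collapse = ", "))
  K <- length(classIds)
  sizes <- tabulate(pos, K)
  if (any(sizes == 0L))
    stop("class ", paste(classIds[sizes == 0L], collapse = ", "),
         " has no spectra in the evaluated set")
  correct <- vapply(seq_len(K), function(k)
    sum(truth == classIds[k] & predicted == classIds[k]), integer(1L))
  .raFromCounts(correct, sizes, classIds, evalSet)
}

#' @rdname evaluateRecognition
#' @param result an [RAResult-class]
#' @return `compositeScore()`: `rarTotal - rarSD`, on unrounded values
#' @export
compositeScore <- function(result) result@composite

#' @rdname evaluateRecognition
#' @export
rarTotal <- function(result) result@rarTotal

#' @rdname evaluateRecognition
#' @export
rarSD <- function(result) result@rarSD

#' @rdname evaluateRecognition
#' @export
rarPerClass <- function(result) {
  r <- result@rarPerClass
  names(r) <- result@classIds
  r
}

#' @rdname evaluateRecognition
#' @export
correctCounts <- function(result) {
  r <- result@correctCounts
  names(r) <- result@classIds
  r
}

#' @rdname evaluateRecognition
#' @export
classSizes <- function(result) {
  r <- result@classSizes
  names(r) <- result@classIds
  r
}

setMethod("show", "RAResult", function(object) {
  cat(sprintf("RAResult%s: RAR_Total %.1f%%, RAR_SD %.1f, composite %.1f\n",
              if (is.na(object@evalSet)) "" else
                sprintf(" (%s set)", object@evalSet),
              object@rarTotal, object@rarSD, object@composite))
  cat("  per class:",
      paste(sprintf("%d: %.1f%% (%d/%d)", object@classIds,
                    object@rarPerClass, object@correctCounts,
                    object@classSizes), collapse = "  "), "\n")
})

#' Recover integer correct counts from printed percentage rates
#'
#' Inverts one-decimal-rounded per-class rates over known class sizes: for
#' each class, finds the unique integer count whose rate rounds to the
#' printed value. Used to recompute published total/dispersion cells from
#' per-class table rows.
#'
#' @param rarPercent per-class rates as printed (percent, one decimal)
#' @param sizes class sizes
#' @return integer vector of correct counts
#' @export
countsFromRAR <- function(rarPercent, sizes) {
  stopifnot(length(rarPercent) == length(sizes))
  vapply(seq_along(sizes), function(i) {
    cand <- which(abs(round(100 * (0:sizes[i]) / sizes[i], 1) -
                      rarPercent[i]) < 1e-9) - 1L
    if (length(cand) != 1L)
      stop(sprintf("rate %.1f%% over %d spectra maps to %d counts",
                   rarPercent[i], sizes[i], length(cand)))
    cand
  }, integer(1L))
}

#' Format an evaluation as a report table row
#'
#' One row in the style of the published summary tables: method name,
#' wavelength-model parameters where applicable, per-class rates, total and
#' dispersion, rounded to one decimal for display (internal comparisons
#' always use unrounded values).
#'
#' @param result an [RAResult-class]
#' @param method method label
#' @param I,E,N,G optional wavelength-model parameters
#' @return a one-row data.frame
#' @export
rarTableRow <- function(result, method, I = NA, E = NA, N = NA, G = NA) {
  row <- data.frame(method = method, I = I, E = E, N = N, G = G)
  for (k in seq_along(result@classIds))
    row[[sprintf("RAR_%d", result@classIds[k])]] <-
      round(result@rarPerClass[k], 1)
  row$RAR_Total <- round(result@rarTotal, 1)
  row$RAR_SD <- round(result@rarSD, 1)
  row
}
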