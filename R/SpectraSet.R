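#' Construct a SpectraSet
#'
#' @param absorbance numeric matrix of absorbances (AU), one row per grid
#'   wavelength, one column per spectrum
#' @param wavelength numeric vector of grid wavelengths (nm), strictly
#'   increasing and uniformly spaced, one per row of `absorbance`
#' @param classLabel integer class label per spectrum (1..K)
#' @param bottleId,sampleId,replicateId identifiers per spectrum; all
#'   spectra of one `sampleId` must share `bottleId` and `classLabel`
#' @param set set tag per spectrum; one of `calibration`, `prediction`,
#'   `validation`, `unassigned` (default)
#' @param metadata optional list stored in the object metadata
#' @return a [SpectraSet-class]
#' @export
SpectraSet <- function(absorbance, wavelength, classLabel, bottleId,
                       sampleId, replicateId, set = "unassigned",
                       metadata = list()) {
  absorbance <- as.matrix(absorbance)
  n <- ncol(absorbance)
  if (length(set) == 1L) set <- rep(set, n)
  cd <- DataFrame(class_label = as.integer(classLabel),
                  bottle_id = as.character(bottleId),
                  sample_id = as.character(sampleId),
                  replicate_id = as.character(replicateId),
                  set = as.character(set))
  if (is.null(colnames(absorbance)))
    colnames(absorbance) <- sprintf("spec%04d", seq_len(n))
  rd <- DataFrame(wavelength_nm = as.numeric(wavelength))
  se <- SummarizedExperiment(assays = list(absorbance = absorbance),
                             rowData = rd, colData = cd,
                             metadata = metadata)
  new("SpectraSet", se)
}

#' @rdname SpectraSet
#' @param x a [SpectraSet-class]
#' @return `absorbance()`: the wavelength-by-spectrum assay matrix
#' @export
absorbance <- function(x) assay(x, "absorbance")

#' @rdname SpectraSet
#' @return `wavelengths()`: numeric vector of grid wavelengths (nm)
#' @export
wavelengths <- function(x) rowData(x)$wavelength_nm

#' @rdname SpectraSet
#' @return `classLabels()`: integer class label per spectrum
#' @export
classLabels <- function(x) colData(x)$class_label

#' @rdname SpectraSet
#' @return `bottleIds()`: bottle identifier per spectrum
#' @export
bottleIds <- function(x) colData(x)$bottle_id

#' @rdname SpectraSet
#' @return `setTags()`: set tag per spectrum
#' @export
setTags <- function(x) colData(x)$set

#' @rdname SpectraSet
#' @param value replacement character vector of set tags
#' @export
`setTags<-` <- function(x, value) {
  colData(x)$set <- as.character(value)
  validObject(x)
  x
}

#' @rdname SpectraSet
#' @param set set tag(s) to keep
#' @return `subsetBySet()`: the spectra carrying one of the given tags
#' @export
subsetBySet <- function(x, set) {
  x[, setTags(x) %in% set]
}

setMethod("show", "SpectraSet", function(object) {
  g <- spectraGrid(object)
  cat(sprintf("SpectraSet: %d spectra x %d wavelengths (%g-%g nm, step %g)\n",
              ncol(object), nrow(object), g@start, g@end, g@step))
  cl <- table(classLabels(object))
  cat("  classes: ",
      paste(sprintf("%s:%d", names(cl), as.integer(cl)), collapse = " "), "\n")
  st <- table(factor(setTags(object), levels = .SET_TAGS))
  cat("  sets:    ",
      paste(sprintf("%s:%d", names(st), as.integer(st)), collapse = " "), "\n")
})

.checkUniform <- function(wl) {
  if (any(diff(wl) <= 0))
    stop("wavelength headers must be strictly increasing")
  if (length(wl) > 2L) {
    d <- diff(wl)
    bad <- which(abs(d - d[1L]) > 1e-9)
    if (length(bad))
      stop(sprintf("non-uniform wavelength spacing between %g and %g nm",
                   wl[bad[1L]], wl[bad[1L] + 1L]))
  }
  invisible(wl)
}

#' Read a wide-format spectra CSV
#'
#' The expected layout is one row per spectrum: metadata columns
#' `class_label, bottle_id, sample_id, replicate_id, set` followed by one
#' numeric column per wavelength, headers in nm, strictly increasing and
#' uniformly spaced. A missing `set` column is tolerated and filled with
#' `"unassigned"`. Lines starting with `#` are skipped.
#'
#' @param path CSV file path
#' @param grid optional [WaveGrid-class]; when given, the file's wavelength
#'   headers must match it exactly
#' @return a [SpectraSet-class]
#' @export
readSpectra <- function(path, grid = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE,
                          check.names = FALSE)
  need <- setdiff(.META_COLS, "set")
  missing_cols <- setdiff(need, colnames(dt))
  if (length(missing_cols))
    stop("missing metadata column(s): ", paste(missing_cols, collapse = ", "))
  if (!"set" %in% colnames(dt)) dt$set <- "unassigned"
  wl_cols <- setdiff(colnames(dt), .META_COLS)
  wl <- suppressWarnings(as.numeric(wl_cols))
  if (any(is.na(wl)))
    stop("non-numeric wavelength header(s): ",
         paste(wl_cols[is.na(wl)], collapse = ", "))
  .checkUniform(wl)
  a <- t(as.matrix(dt[, wl_cols, drop = FALSE]))
  if (!all(is.finite(a))) {
    bad_row <- which(!apply(is.finite(a), 2L, all))[1L]
    stop("non-finite absorbance in spectrum row ", bad_row)
  }
  if (!is.null(grid)) {
    want <- gridWavelengths(grid)
    if (length(wl) != length(want) || any(abs(wl - want) > 1e-9))
      stop("wavelength headers do not match the expected grid")
  }
  SpectraSet(a, wl, dt$class_label, dt$bottle_id, dt$sample_id,
             dt$replicate_id, dt$set)
}

#' Write a SpectraSet to the wide CSV format
#'
#' Absorbances are written with 17 significant digits so that a
#' write/read round trip reproduces them exactly.
#'
#' @param x a [SpectraSet-class]
#' @param path output CSV path
#' @return the path, invisibly
#' @export
writeSpectra <- function(x, path) {
  a <- t(absorbance(x))
  txt <- matrix(sprintf("%.17g", a), nrow = nrow(a),
                dimnames = list(NULL, as.character(wavelengths(x))))
  out <- data.frame(class_label = classLabels(x),
                    bottle_id = bottleIds(x),
                    sample_id = colData(x)$sample_id,
                    replicate_id = colData(x)$replicate_id,
                    set = setTags(x),
                    txt, check.names = FALSE,
                    stringsAsFactors = FALSE)
  data.table::fwrite(out, path, quote = FALSE)
  invisible(path)
}
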