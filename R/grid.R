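#' Construct a uniform wavelength grid
#'
#' @param start first wavelength (nm)
#' @param end last wavelength (nm); `end - start` must be an exact multiple
#'   of `step`
#' @param step wavelength increment (nm), default 2
#' @return a [WaveGrid-class]
#' @examples
#' g <- waveGrid(400, 2498, 2)
#' nWavelengths(g)  # 1050
#' @export
waveGrid <- function(start, end, step = 2) {
  new("WaveGrid", start = as.numeric(start), end = as.numeric(end),
      step = as.numeric(step))
}

#' Number of wavelengths on a grid
#' @param grid a [WaveGrid-class]
#' @return integer point count
#' @export
nWavelengths <- function(grid) {
  stopifnot(is(grid, "WaveGrid"))
  as.integer(round((grid@end - grid@start) / grid@step)) + 1L
}

#' All wavelengths of a grid
#' @param grid a [WaveGrid-class]
#' @return numeric vector of wavelengths (nm)
#' @export
gridWavelengths <- function(grid) {
  stopifnot(is(grid, "WaveGrid"))
  grid@start + grid@step * (seq_len(nWavelengths(grid)) - 1L)
}

#' Column index of a wavelength on a grid
#'
#' Maps a physical wavelength (nm) to its 1-based column index. Public
#' interfaces speak nm throughout; indices only appear where a matrix row
#' must be addressed.
#'
#' @param grid a [WaveGrid-class]
#' @param wavelength_nm wavelength(s) to look up (nm); must lie on the grid
#' @return integer index (1 for `start`, `nWavelengths(grid)` for `end`)
#' @examples
#' wavelengthIndex(waveGrid(400, 2498, 2), c(400, 404, 2498))  # 1 3 1050
#' @export
wavelengthIndex <- function(grid, wavelength_nm) {
  stopifnot(is(grid, "WaveGrid"))
  r <- (wavelength_nm - grid@start) / grid@step
  i <- round(r)
  bad <- abs(r - i) > 1e-9 | i < 0 | i > (nWavelengths(grid) - 1L)
  if (any(bad))
    stop("wavelength(s) not on grid: ",
         paste(wavelength_nm[bad], collapse = ", "))
  as.integer(i) + 1L
}

#' @describeIn waveGrid derive the grid of a [SpectraSet-class]
#' @param x a [SpectraSet-class]
#' @export
spectraGrid <- function(x) {
  wl <- wavelengths(x)
  step <- if (length(wl) > 1L) wl[2L] - wl[1L] else 2
  waveGrid(wl[1L], wl[length(wl)], step)
}

setMethod("show", "WaveGrid", function(object) {
  cat(sprintf("WaveGrid: %g-%g nm, step %g nm (%d points)\n",
              object@start, object@end, object@step, nWavelengths(object)))
})
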