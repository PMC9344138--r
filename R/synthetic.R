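#' Per-class amplitude level patterns for informative bands
#'
#' Integer level matrix (bands x classes) placing each class's amplitude at
#' every informative band. The default 3-band / 5-class pattern is chosen
#' so that *every* band is essential: for each band there is a pair of
#' classes distinguished by that band alone, so no band can be dropped
#' without merging two classes. For other shapes a modular construction is
#' used (`level[j, k] = (k - 1) * u_j mod K` with `u_j` coprime to `K`),
#' which keeps all class patterns pairwise distinct.
#'
#' @param nBands number of informative bands
#' @param nClasses number of classes
#' @return integer matrix, `nBands` rows by `nClasses` columns
#' @export
bandLevelMatrix <- function(nBands, nClasses) {
  if (nBands == 3L && nClasses == 5L) {
    return(rbind(c(0L, 0L, 1L, 1L, 0L),
                 c(0L, 1L, 0L, 1L, 1L),
                 c(0L, 0L, 0L, 0L, 1L)))
  }
  coprime <- Filter(function(u) {
    a <- u; b <- nClasses
    while (b) { t <- b; b <- a %% b; a <- t }
    a == 1L
  }, seq_len(max(2L * nBands * nClasses, 10L)))
  u <- coprime[((seq_len(nBands) - 1L) %% length(coprime)) + 1L]
  t(vapply(seq_len(nBands), function(j)
    ((seq_len(nClasses) - 1L) * u[j]) %% nClasses, integer(nClasses)))
}

#' Synthetic Vis-NIR spectra configuration
#'
#' Phenomenological model of multi-class absorbance spectra: a constant
#' baseline plus strong Gaussian bands shared by all classes (emulating the
#' dominant water absorptions of aqueous samples, by default near 1450 and
#' 1930 nm), weak class-specific Gaussian bands at known centers, a
#' constant per-bottle baseline shift, and wavelength-correlated noise
#' (Gaussian autocorrelation `exp(-d^2 / (2 L^2))` at lag `d` nm). Class
#' amplitudes at the informative bands follow [bandLevelMatrix()] scaled so
#' that the closest pair of classes is separated by
#' `separation * sqrt(noiseSd^2 + bottleOffsetSd^2)` at the band center.
#'
#' Class-band shapes are truncated to zero beyond four widths from their
#' center, so outside the informative bands all classes share exactly the
#' same noiseless spectrum.
#'
#' @param grid a [WaveGrid-class]
#' @param nClasses number of classes (class labels `1..nClasses`)
#' @param baseline constant absorbance offset (AU)
#' @param sharedPeaks data.frame with columns `center` (nm), `width` (nm,
#'   Gaussian sd) and `amplitude` (AU), common to all classes
#' @param bandCenters informative band centers (nm, inside the grid)
#' @param bandWidths informative band Gaussian widths (nm), recycled
#' @param bandLevels optional integer level matrix (bands x classes);
#'   defaults to [bandLevelMatrix()]
#' @param separation closest-pair class separation at a band center, in
#'   units of the total within-class standard deviation (default 3)
#' @param bandDelta absolute level spacing (AU); overrides `separation`
#'   when given, and defaults to 0.05 AU when the configuration is
#'   noise-free
#' @param noiseSd per-wavelength noise standard deviation (AU)
#' @param noiseCorrLength noise correlation length `L` (nm); 0 gives white
#'   noise
#' @param bottleOffsetSd standard deviation of the per-bottle constant
#'   baseline shift (AU)
#' @param bottlesPerClass,samplesPerBottle,replicatesPerSample hierarchy
#'   counts for [generateSpectra()]
#' @param interferenceClass optional class label whose bottles each draw
#'   their own band-amplitude profile (heterogeneous catch-all class);
#'   `NA` disables
#' @param interferenceSd sd of the per-bottle amplitude draws for the
#'   interference class (AU); defaults to the level spacing
#' @return a `SyntheticConfig` list
#' @seealso [generateSpectra()], [recoveryConfig()], [makePaperStructure()]
#' @export
syntheticConfig <- function(grid = waveGrid(400, 2498, 2),
                            nClasses = 5L,
                            baseline = 0.2,
                            sharedPeaks = data.frame(
                              center = c(1450, 1930),
                              width = c(45, 60),
                              amplitude = c(1.0, 1.5)),
                            bandCenters = c(520, 2150, 2350),
                            bandWidths = 28,
                            bandLevels = NULL,
                            separation = 3,
                            bandDelta = NULL,
                            noiseSd = 0.012,
                            noiseCorrLength = 4,
                            bottleOffsetSd = 0.002,
                            bottlesPerClass = 20L,
                            samplesPerBottle = 5L,
                            replicatesPerSample = 3L,
                            interferenceClass = NA_integer_,
                            interferenceSd = NULL) {
  validObject(grid)
  stopifnot(nClasses >= 2L, noiseSd >= 0, bottleOffsetSd >= 0,
            noiseCorrLength >= 0, bottlesPerClass >= 1L,
            samplesPerBottle >= 1L, replicatesPerSample >= 1L)
  nBands <- length(bandCenters)
  if (nBands) {
    if (any(bandCenters < grid@start | bandCenters > grid@end))
      stop("informative band centers must lie inside the grid")
    bandWidths <- rep_len(bandWidths, nBands)
    stopifnot(all(bandWidths > 0))
  }
  if (is.null(bandLevels)) bandLevels <- bandLevelMatrix(nBands, nClasses)
  if (nBands && !identical(dim(bandLevels),
                           c(nBands, as.integer(nClasses))))
    stop("bandLevels must be bands x classes")
  sdTot <- sqrt(noiseSd^2 + bottleOffsetSd^2)
  if (is.null(bandDelta))
    bandDelta <- if (sdTot > 0) separation * sdTot else 0.05
  if (nBands && any(apply(bandLevels, 1L,
                          function(z) length(unique(z)) < 2L)))
    stop("every informative band must distinguish at least two classes")
  if (is.null(interferenceSd)) interferenceSd <- bandDelta
  cfg <- list(grid = grid, nClasses = as.integer(nClasses),
              baseline = baseline, sharedPeaks = sharedPeaks,
              bandCenters = bandCenters, bandWidths = bandWidths,
              bandLevels = bandLevels, bandDelta = bandDelta,
              noiseSd = noiseSd, noiseCorrLength = noiseCorrLength,
              bottleOffsetSd = bottleOffsetSd,
              bottlesPerClass = as.integer(bottlesPerClass),
              samplesPerBottle = as.integer(samplesPerBottle),
              replicatesPerSample = as.integer(replicatesPerSample),
              interferenceClass = as.integer(interferenceClass),
              interferenceSd = interferenceSd)
  class(cfg) <- c("SyntheticConfig", "list")
  cfg
}

#' Reduced-grid benchmark configuration
#'
#' The default configuration of the parameter-recovery benchmark: five
#' classes on a 400--1000 nm grid (2 nm step, 301 points) with three
#' informative bands (480, 700, 880 nm) at closest-pair separation 3 sigma,
#' correlated noise, and a 10 bottles x 3 samples x 3 replicates hierarchy
#' per class (90 spectra per class).
#'
#' @param ... overrides passed to [syntheticConfig()]
#' @return a `SyntheticConfig`
#' @export
recoveryConfig <- function(...) {
  args <- list(grid = waveGrid(400, 1000, 2),
               sharedPeaks = data.frame(center = c(650, 960),
                                        width = c(120, 35),
                                        amplitude = c(0.35, 0.5)),
               bandCenters = c(480, 700, 880),
               bottlesPerClass = 10L,
               samplesPerBottle = 3L)
  over <- list(...)
  args[names(over)] <- over
  do.call(syntheticConfig, args)
}

#' @rdname recoveryConfig
#' @return `recoverySplitPlan()`: a 4/3/3 bottle allocation per class
#' @export
recoverySplitPlan <- function() splitPlan(1:5, 4, 3, 3)

# Noiseless wavelength-by-class mean matrix (truncated class bands).
.classMeanMatrix <- function(cfg, bandAmps = NULL) {
  wl <- gridWavelengths(cfg$grid)
  shared <- rep(cfg$baseline, length(wl))
  sp <- cfg$sharedPeaks
  if (!is.null(sp) && nrow(sp))
    for (p in seq_len(nrow(sp)))
      shared <- shared +
        sp$amplitude[p] * exp(-(wl - sp$center[p])^2 / (2 * sp$width[p]^2))
  if (is.null(bandAmps)) bandAmps <- cfg$bandDelta * cfg$bandLevels
  m <- matrix(shared, length(wl), ncol(bandAmps))
  for (j in seq_along(cfg$bandCenters)) {
    shape <- exp(-(wl - cfg$bandCenters[j])^2 / (2 * cfg$bandWidths[j]^2))
    shape[abs(wl - cfg$bandCenters[j]) > 4 * cfg$bandWidths[j]] <- 0
    m <- m + outer(shape, bandAmps[j, ])
  }
  m
}

# Row-normalized Gaussian smoothing operator giving the noise its
# exp(-d^2/(2 L^2)) autocorrelation (kernel sd L/sqrt(2); see vignette).
.noiseSmoother <- function(wl, L) {
  if (L <= 0) return(NULL)
  s <- L / sqrt(2)
  D <- outer(wl, wl, "-")
  K <- exp(-D^2 / (2 * s^2))
  K[abs(D) > 6 * s] <- 0
  K / sqrt(rowSums(K * K))
}

# Shared generator core: `layout` is a data.frame with one row per bottle
# (class_label, bottle_id, n_samples).
.generateFromLayout <- function(cfg, layout, seed) {
  wl <- gridWavelengths(cfg$grid)
  W <- length(wl)
  nBands <- length(cfg$bandCenters)
  classAmps <- cfg$bandDelta * cfg$bandLevels
  classMeans <- .classMeanMatrix(cfg)
  reps <- cfg$replicatesPerSample
  nSpecPerBottle <- layout$n_samples * reps
  S <- sum(nSpecPerBottle)
  cls <- rep(layout$class_label, nSpecPerBottle)
  bid <- rep(layout$bottle_id, nSpecPerBottle)
  sid <- unlist(lapply(seq_len(nrow(layout)), function(b)
    rep(sprintf("%s.s%02d", layout$bottle_id[b],
                seq_len(layout$n_samples[b])), each = reps)))
  rid <- unlist(lapply(nSpecPerBottle / reps, function(ns)
    rep(sprintf("r%d", seq_len(reps)), ns)))
  a <- withSeed(seed, function() {
    bottleOffsets <- rnorm(nrow(layout), 0, cfg$bottleOffsetSd)
    bottleMeans <- classMeans[, layout$class_label, drop = FALSE]
    if (!is.na(cfg$interferenceClass) && nBands) {
      ib <- which(layout$class_label == cfg$interferenceClass)
      for (b in ib) {
        amps <- rnorm(nBands, classAmps[, cfg$interferenceClass],
                      cfg$interferenceSd)
        bottleMeans[, b] <- .classMeanMatrix(cfg, matrix(amps))[, 1L]
      }
    }
    base <- bottleMeans[, rep(seq_len(nrow(layout)), nSpecPerBottle),
                        drop = FALSE] +
      matrix(rep(bottleOffsets, nSpecPerBottle), W, S, byrow = TRUE)
    if (cfg$noiseSd > 0) {
      E <- matrix(rnorm(W * S), W, S)
      sm <- .noiseSmoother(wl, cfg$noiseCorrLength)
      noise <- if (is.null(sm)) E else sm %*% E
      base <- base + cfg$noiseSd * noise
    }
    base
  })
  informative <- if (nBands) {
    g <- cfg$grid
    g@start + g@step * round((cfg$bandCenters - g@start) / g@step)
  } else numeric(0)
  SpectraSet(a, wl, cls, bid, sid, rid,
             metadata = list(config = cfg, seed = seed,
                             informativeWavelengths = informative,
                             classMeans = classMeans))
}

#' Generate a synthetic spectral dataset
#'
#' Draws `bottlesPerClass x samplesPerBottle x replicatesPerSample` spectra
#' per class from the model described in [syntheticConfig()]:
#' `spectrum = shared peaks + class bands + bottle shift + correlated
#' noise`. Deterministic given `seed`; the caller's RNG state is
#' preserved. The ground-truth informative wavelengths (grid points nearest
#' each band center) and the noiseless class means are stored in the object
#' metadata.
#'
#' @param config a [syntheticConfig()]
#' @param seed integer seed
#' @return a [SpectraSet-class] with `set = "unassigned"`
#' @export
generateSpectra <- function(config, seed) {
  stopifnot(inherits(config, "SyntheticConfig"))
  layout <- do.call(rbind, lapply(seq_len(config$nClasses), function(k)
    data.frame(class_label = k,
               bottle_id = sprintf("C%d.b%02d", k,
                                   seq_len(config$bottlesPerClass)),
               n_samples = config$samplesPerBottle)))
  .generateFromLayout(config, layout, seed)
}

#' Ground-truth informative wavelengths of a synthetic dataset
#'
#' @param x a [SpectraSet-class] produced by [generateSpectra()] or
#'   [makePaperStructure()]
#' @return numeric vector of grid wavelengths (nm)
#' @export
informativeWavelengths <- function(x) metadata(x)$informativeWavelengths

#' Synthetic dataset with the full five-class study structure
#'
#' Emulates the published sample hierarchy: four identification classes of
#' 20 bottles x 5 samples x 3 replicates (300 spectra each) and an
#' interference class of 21 commercial bottles (3 samples each) plus 48
#' home-brew bottles (1 sample each), 333 spectra, for 1533 spectra in
#' total. The interference class is heterogeneous: every bottle draws its
#' own informative-band amplitude profile. [paperSplitPlan()] divides this
#' dataset 597/468/468.
#'
#' @param seed integer seed
#' @param config optional [syntheticConfig()]; defaults to the full-grid
#'   configuration with `interferenceClass = 5`
#' @return a [SpectraSet-class]
#' @export
makePaperStructure <- function(seed, config = NULL) {
  cfg <- config %||% syntheticConfig(interferenceClass = 5L)
  ident <- do.call(rbind, lapply(1:4, function(k)
    data.frame(class_label = k,
               bottle_id = sprintf("C%d.b%02d", k, 1:20),
               n_samples = 5L)))
  interf <- rbind(
    data.frame(class_label = 5L,
               bottle_id = sprintf("C5.com%02d", 1:21), n_samples = 3L),
    data.frame(class_label = 5L,
               bottle_id = sprintf("C5.home%02d", 1:48), n_samples = 1L))
  .generateFromLayout(cfg, rbind(ident, interf), seed)
}
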