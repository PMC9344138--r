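#' Bottle-grouped split plan
#'
#' Allocates whole grouping units (bottles) of each class to the
#' calibration, prediction and validation sets. A class may be covered by
#' several rows distinguished by a `bottlePattern` regular expression
#' (e.g. commercial versus home-brewed bottles inside an interference
#' class); each bottle must match exactly one plan row, and each row's
#' allocations must sum to the number of bottles it covers.
#'
#' @param classLabel integer class label per row
#' @param nCalibration,nPrediction,nValidation bottle counts per row
#' @param bottlePattern optional regex matched against bottle ids inside the
#'   class; `NA` matches all the class's bottles
#' @return a `SplitPlan` data.frame
#' @seealso [groupedSplit()], [paperSplitPlan()]
#' @export
splitPlan <- function(classLabel, nCalibration, nPrediction, nValidation,
                      bottlePattern = NA_character_) {
  plan <- data.frame(class_label = as.integer(classLabel),
                     n_calibration = as.integer(nCalibration),
                     n_prediction = as.integer(nPrediction),
                     n_validation = as.integer(nValidation),
                     bottle_pattern = as.character(bottlePattern),
                     stringsAsFactors = FALSE)
  if (any(plan$n_calibration < 0L | plan$n_prediction < 0L |
          plan$n_validation < 0L))
    stop("allocation counts must be non-negative")
  class(plan) <- c("SplitPlan", "data.frame")
  plan
}

#' The five-class study split plan
#'
#' Per identification brand (classes 1--4): 20 bottles divided 8/6/6 into
#' calibration/prediction/validation. The interference class (5) is divided
#' by stratum: 21 commercial bottles 7/7/7 and 48 home-brew bottles
#' 18/15/15. On the matching synthetic study structure this yields
#' 597/468/468 spectra.
#'
#' @return a `SplitPlan`
#' @seealso [makePaperStructure()]
#' @export
paperSplitPlan <- function() {
  rbind(splitPlan(1:4, 8, 6, 6),
        splitPlan(5, 7, 7, 7, bottlePattern = "com"),
        splitPlan(5, 18, 15, 15, bottlePattern = "home"))
}

#' Assign set tags by randomly allocating whole bottles
#'
#' Every spectrum of one bottle receives the same set tag, so replicates
#' and samples always travel together and no bottle appears in two sets.
#' The allocation is uniform random over bottles within each plan row and
#' deterministic given `seed`; the caller's RNG state is left untouched.
#'
#' @param x a [SpectraSet-class]
#' @param plan a [splitPlan()]; must cover every class present, and each
#'   row's counts must sum to the number of bottles the row covers
#' @param seed integer random seed
#' @return `x` with updated set tags
#' @export
groupedSplit <- function(x, plan, seed) {
  stopifnot(inherits(plan, "SplitPlan"))
  cls <- classLabels(x)
  missing_cls <- setdiff(unique(cls), plan$class_label)
  if (length(missing_cls))
    stop("plan does not cover class(es): ",
         paste(sort(missing_cls), collapse = ", "))
  tags <- rep(NA_character_, ncol(x))
  bid <- bottleIds(x)
  withSeed(seed, function() {
    for (r in seq_len(nrow(plan))) {
      row <- plan[r, ]
      in_class <- cls == row$class_label
      bottles <- sort(unique(bid[in_class]))
      if (!is.na(row$bottle_pattern))
        bottles <- grep(row$bottle_pattern, bottles, value = TRUE)
      want <- row$n_calibration + row$n_prediction + row$n_validation
      if (want > length(bottles))
        stop(sprintf(
          "class %d%s: plan requests %d bottles but only %d are available",
          row$class_label,
          if (is.na(row$bottle_pattern)) "" else
            sprintf(" (pattern '%s')", row$bottle_pattern),
          want, length(bottles)))
      if (want < length(bottles))
        stop(sprintf(
          "class %d%s: plan allocates %d of %d bottles; allocations must cover all bottles",
          row$class_label,
          if (is.na(row$bottle_pattern)) "" else
            sprintf(" (pattern '%s')", row$bottle_pattern),
          want, length(bottles)))
      perm <- sample(bottles)
      alloc <- rep(c("calibration", "prediction", "validation"),
                   c(row$n_calibration, row$n_prediction, row$n_validation))
      for (s in unique(alloc)) {
        chosen <- perm[alloc == s]
        tags[in_class & bid %in% chosen] <<- s
      }
    }
  })
  if (anyNA(tags))
    stop("some bottles were not covered by any plan row")
  setTags(x) <- tags
  x
}
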