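`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate fn() under a temporary RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, fn) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1L)
  old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(as.integer(seed))
  fn()
}

# write.csv preceded by "# "-prefixed comment lines (grid / seed provenance).
writeCsvCommented <- function(df, path, comments = character()) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp), add = TRUE)
  utils::write.csv(df, tmp, row.names = FALSE)
  writeLines(c(paste0("# ", comments), readLines(tmp)), path)
  invisible(path)
}
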