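# internal helpers shared across modules

# check that `df` has the given columns; `what` names the argument in errors
check_columns <- function(df, cols, what = "data") {
  if (!is.data.frame(df)) {
    abort(sprintf("`%s` must be a data frame, not %s.", what, class(df)[1]))
  }
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` is missing required column%s: %s.",
      what, if (length(missing) > 1) "s" else "", paste0("`", missing, "`", collapse = ", ")
    ))
  }
  invisible(df)
}

# an inclusive year window given as c(first, last)
check_window <- function(window, what = "window") {
  if (length(window) != 2 || anyNA(window) || window[1] > window[2]) {
    abort(sprintf("`%s` must be c(first, last) with first <= last.", what))
  }
  as.integer(window)
}

# run `expr` under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# derive a reproducible sub-seed (keeps values well inside 32-bit range)
sub_seed <- function(seed, offset) {
  (as.integer(seed) %% 1000000L) * 1000L + as.integer(offset)
}

path_extdata <- function(file) {
  system.file("extdata", file, package = "gardenring", mustWork = TRUE)
}
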