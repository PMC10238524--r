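#' @keywords internal
"_PACKAGE"

# Condition helpers: every user-facing failure carries a condition class so
# callers (and the CLI) can distinguish validation, geometry, configuration,
# I/O and degenerate-input signals.
abort_mvmar <- function(message, class) {
  stop(structure(
    class = c(class, "mvmar_error", "error", "condition"),
    list(message = message, call = sys.call(-1))
  ))
}

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    abort_mvmar(sprintf("%s contains non-finite values", what), "mvmar_validation_error")
  }
  invisible(x)
}

#' Run code with a temporary RNG seed
#'
#' Sets the RNG seed for the duration of `expr` and restores the caller's
#' RNG state afterwards, so simulations are reproducible without clobbering
#' the session RNG.
#'
#' @param seed integer seed, or `NULL` to leave the RNG untouched.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Lightweight stderr logger used across the pipeline.
log_msg <- function(fmt, ..., verbose = getOption("mvmar.verbose", TRUE)) {
  if (isTRUE(verbose)) message(sprintf(fmt, ...))
  invisible(NULL)
}
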