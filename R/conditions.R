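# Classed conditions so callers (and tests) can catch specific failure modes
# instead of matching message strings.

cyto_abort <- function(message, class, call = sys.call(-1), ...) {
  stop(structure(
    class = c(class, "cytoring_error", "error", "condition"),
    list(message = message, call = call, ...)
  ))
}

cyto_warn <- function(message, class, ...) {
  warning(structure(
    class = c(class, "cytoring_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' Evaluate an expression with a pinned, restored RNG state
#'
#' All randomness in the package (simulation only; analysis stages are
#' deterministic) flows through this helper, which pins the generator to
#' Mersenne-Twister with inversion normals so a given seed reproduces
#' bit-identically across platforms, and restores the caller's RNG state on
#' exit.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    cyto_abort("seed must be a single finite number", "cytoring_config_error")
  }
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  suppressWarnings(set.seed(as.integer(seed), kind = "Mersenne-Twister",
                            normal.kind = "Inversion", sample.kind = "Rejection"))
  expr
}

# scalar validation helpers
stopifnot_scalar_pos <- function(x, what, class = "cytoring_config_error") {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0) {
    cyto_abort(sprintf("%s must be a single positive finite number", what), class)
  }
  invisible(x)
}
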