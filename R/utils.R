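# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores the global `.Random.seed`, so seeded sampling inside the
#' package never disturbs the caller's random-number stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @noRd
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministically derive a sub-seed from an experiment seed and a stream
# index, kept within the 32-bit integer range R requires.
derive_seed <- function(seed, index) {
  as.integer((as.numeric(seed) * 7919 + as.numeric(index) * 104729) %% 2147483647L)
}

stop_platemix <- function(msg, class, ...) {
  stop(structure(
    class = c(class, "platemix_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), ...)
  ))
}

assert_numeric <- function(x, name, finite = TRUE) {
  if (!is.numeric(x)) {
    stop_platemix(sprintf("'%s' must be numeric", name), "platemix_domain_error")
  }
  if (finite && any(!is.finite(x))) {
    stop_platemix(sprintf("'%s' contains non-finite values", name),
                  "platemix_domain_error")
  }
  invisible(x)
}
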