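# Shared internal helpers.

# The 20 standard amino acids; X is tolerated on input but invalidates any
# motif window it touches.
AA_STANDARD <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "K", "L",
                 "M", "F", "P", "S", "T", "W", "Y", "V")

#' @keywords internal
#' @noRd
geometric_mean <- function(x, na.rm = FALSE) {
  if (na.rm) x <- x[!is.na(x)]
  if (any(is.na(x))) return(NA_real_)
  if (any(x <= 0)) stop("geometric mean requires strictly positive values")
  exp(mean(log(x)))
}

# Lightweight stage logging: emitted as messages so callers (tests, the CLI)
# can collect or silence them. Controlled by options(cmatools.verbose = TRUE).
#' @keywords internal
#' @noRd
cma_log <- function(fmt, ...) {
  if (isTRUE(getOption("cmatools.verbose", FALSE))) {
    message(sprintf(fmt, ...))
  }
  invisible(NULL)
}

#' @keywords internal
#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Run a generator body under a local, seeded RNG without disturbing the
# caller's RNG state. Generators are pure functions of (parameters, seed).
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer")
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
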