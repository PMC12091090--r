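# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, evaluates `expr`, and restores the caller's RNG state so
#' seeded package functions do not clobber the global random stream.
#'
#' @param seed Integer seed, or `NULL` to leave the RNG untouched.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(expr)
}

# stop() wrapper: consistent, caller-free error messages
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warn <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# check a scalar field of a configuration object, naming the field on failure
check_scalar <- function(x, field, min = -Inf, max = Inf, integer = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort("configuration error: '%s' must be a single finite number", field)
  }
  if (x < min || x > max) {
    abort("configuration error: '%s' must be in [%s, %s] (got %s)",
          field, format(min), format(max), format(x))
  }
  if (integer && x != round(x)) {
    abort("configuration error: '%s' must be an integer (got %s)", field, format(x))
  }
  invisible(x)
}

# geometric mean of strictly positive values
geometric_mean <- function(x) exp(mean(log(x)))
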