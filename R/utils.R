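# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the global RNG state so seeded generators do not
#' perturb the caller's random stream. A `NULL` seed leaves the current
#' stream untouched.
#'
#' @param seed integer seed or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("seed: must be a single finite number", call. = FALSE)
  }
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# stop() with the offending field name first, so validation errors from
# scenario constructors always name the field.
fail_field <- function(field, msg) {
  stop(sprintf("%s: %s", field, msg), call. = FALSE)
}

check_scalar <- function(x, field, positive = FALSE, nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    fail_field(field, "must be a single finite number")
  }
  if (positive && x <= 0) fail_field(field, "must be > 0")
  if (nonnegative && x < 0) fail_field(field, "must be >= 0")
  invisible(x)
}

check_ascending <- function(x, field, strictly = TRUE, positive = FALSE,
                            nonnegative = FALSE) {
  if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x))) {
    fail_field(field, "must be a finite numeric vector")
  }
  d <- diff(x)
  if (strictly && length(d) && any(d <= 0)) {
    fail_field(field, "must be strictly ascending")
  }
  if (positive && any(x <= 0)) fail_field(field, "must be > 0")
  if (nonnegative && any(x < 0)) fail_field(field, "must be >= 0")
  invisible(x)
}

#' Log-spaced grid
#'
#' @param from,to positive range limits.
#' @param n number of points.
#' @return numeric vector of `n` log-spaced values from `from` to `to`.
#' @export
log_grid <- function(from, to, n) {
  check_scalar(from, "from", positive = TRUE)
  check_scalar(to, "to", positive = TRUE)
  exp(seq(log(from), log(to), length.out = n))
}
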