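## Internal helpers shared across modules.

#' @keywords internal
"_PACKAGE"

# Evaluate `expr` under a temporary RNG state seeded with `seed`.
# Restores the caller's .Random.seed on exit. `seed = NULL` leaves RNG alone.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# error function and friends via pnorm (accurate far into the tails)
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1
erfc <- function(x) 2 * stats::pnorm(x * sqrt(2), lower.tail = FALSE)
log_erfc <- function(x) {
  log(2) + stats::pnorm(x * sqrt(2), lower.tail = FALSE, log.p = TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_bound <- function(name, value, what) {
  stop(sprintf("parameter '%s' = %g violates bound: %s", name, value, what),
       call. = FALSE)
}

# rows of m as unit vectors; zero rows kept as zero
normalize_rows <- function(m) {
  n <- sqrt(rowSums(m^2))
  ok <- n > 0
  m[ok, ] <- m[ok, , drop = FALSE] / n[ok]
  m
}

vec_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}
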