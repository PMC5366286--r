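#' Kummer confluent hypergeometric function M(a, c, z) for z <= 0
#'
#' Computes the confluent hypergeometric function of the first kind
#' \eqn{M(a, c, z) = \sum_n (a)_n / (c)_n \, z^n / n!} for non-positive
#' real arguments \eqn{z}, the case arising in the beta-distribution
#' signal model where \eqn{z = -b D_{max}}. The Kummer transformation
#' \eqn{M(a, c, z) = e^{z} M(c - a, c, -z)} is applied first so that the
#' series has all-positive terms, which avoids the catastrophic
#' cancellation of the alternating series at large \eqn{|z|}.
#'
#' @param a,c numeric scalars with `c > a > 0` (for the beta model,
#'   `a = alpha`, `c = alpha + beta`).
#' @param z numeric vector, `z <= 0`.
#' @param max_terms series length cap before the computation is abandoned.
#' @param tol relative tail tolerance for series termination.
#' @return numeric vector, `M(a, c, z)`, values in (0, 1] for this
#'   argument range.
#' @examples
#' kummer_m(2, 5, 0)      # 1
#' kummer_m(2, 5, -1.5)
#' @export
kummer_m <- function(a, c, z, max_terms = 10000L, tol = 1e-15) {
  stopifnot(length(a) == 1L, length(c) == 1L)
  if (!is.finite(a) || !is.finite(c) || a <= 0 || c <= a)
    stop("kummer_m requires c > a > 0; got a = ", a, ", c = ", c)
  if (any(z > 0)) stop("kummer_m implemented for z <= 0 only")
  x <- -z                      # x >= 0
  ap <- c - a                  # positive-series numerator parameter
  term <- rep(1, length(x))
  s <- rep(1, length(x))
  x_peak <- max(x)
  n <- 0L
  repeat {
    if (!any(term > tol * s & x > 0) && n > x_peak) break
    if (n >= max_terms) {
      i <- which.max(term / s)
      stop(sprintf(paste0("kummer_m series failed to converge in %d terms ",
                          "(a = %g, c = %g, z = %g)"), max_terms, a, c, -x[i]))
    }
    # full-vector recurrence: positive terms peak near n = x, then decay
    # geometrically
    term <- term * ((ap + n) / (c + n) / (n + 1)) * x
    s <- s + term
    n <- n + 1L
  }
  exp(-x) * s
}
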