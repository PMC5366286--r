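## Diffusion tensor estimation and the eigenframe projection of the
## diffusion weighting.

#' Linear least-squares diffusion tensor fit
#'
#' Fits \eqn{\ln S = \ln S_0 - b\, g^T D g} by ordinary least squares on
#' the log-signal. Eigenvalues are sorted descending; negative
#' eigenvalues are permitted in the output but flagged. Mean ADC is the
#' eigenvalue average and fractional anisotropy the usual normalised
#' eigenvalue dispersion
#' \eqn{FA = \sqrt{3/2 \cdot \sum(\lambda_i-\bar\lambda)^2 / \sum \lambda_i^2}}.
#'
#' @param signals measured signals, one per scheme measurement; positive.
#'   Nonpositive signals are excluded (an error is raised if fewer than 7
#'   usable measurements remain).
#' @param scheme an [acq_scheme()].
#' @param b_max largest b-value (s/mm^2) entering the fit; default 2000,
#'   the conventional regime in which the tensor model is adequate.
#' @return a `tensor_fit` object: `S0`, `tensor` (symmetric 3x3,
#'   mm^2/s), `eigenvalues` (descending), `eigenvectors` (columns),
#'   `mean_adc`, `fa`, `residual_mse` (signal domain), `n_used`,
#'   `negative_eigenvalues` flag.
#' @export
fit_dt_linear <- function(signals, scheme, b_max = 2000) {
  if (length(signals) != length(scheme$b))
    stop("signals length (", length(signals),
         ") does not match the scheme (", length(scheme$b), ")")
  keep <- scheme$b <= b_max
  sig <- signals[keep]
  b <- scheme$b[keep]
  g <- scheme$dirs[keep, , drop = FALSE]
  pos <- sig > 0
  n_dropped <- sum(!pos)
  if (sum(pos) < 7L)
    stop(sum(pos), " positive measurements below b_max (", n_dropped,
         " nonpositive excluded); at least 7 are required")
  sig <- sig[pos]; b <- b[pos]; g <- g[pos, , drop = FALSE]
  X <- cbind(1, -b * g[, 1]^2, -b * g[, 2]^2, -b * g[, 3]^2,
             -2 * b * g[, 1] * g[, 2], -2 * b * g[, 1] * g[, 3],
             -2 * b * g[, 2] * g[, 3])
  qrX <- qr(X)
  if (qrX$rank < 7L)
    stop("rank-deficient design: need measurements along at least 6 ",
         "non-collinear directions plus b = 0 (rank ", qrX$rank, ")")
  beta <- qr.coef(qrX, log(sig))
  Dm <- matrix(c(beta[2], beta[5], beta[6],
                 beta[5], beta[3], beta[7],
                 beta[6], beta[7], beta[4]), 3, 3)
  e <- eigen(Dm, symmetric = TRUE)   # eigenvalues descending
  S0 <- exp(beta[1])
  pred <- as.numeric(exp(X %*% beta))
  lam <- e$values
  structure(list(S0 = S0, tensor = Dm, eigenvalues = lam,
                 eigenvectors = e$vectors,
                 mean_adc = mean(lam),
                 fa = fa_from_eigenvalues(lam),
                 residual_mse = mean((sig - pred)^2),
                 n_used = length(sig), n_dropped = n_dropped,
                 negative_eigenvalues = any(lam < 0)),
            class = "tensor_fit")
}

fa_from_eigenvalues <- function(lam) {
  if (all(lam == 0)) return(0)
  sqrt(1.5 * sum((lam - mean(lam))^2) / sum(lam^2))
}

#' @export
print.tensor_fit <- function(x, ...) {
  cat(sprintf(paste0("Diffusion tensor fit: mean ADC = %.3e mm^2/s, ",
                     "FA = %.3f, n = %d%s\n"),
              x$mean_adc, x$fa, x$n_used,
              if (x$negative_eigenvalues) " [negative eigenvalues]" else ""))
  invisible(x)
}

#' Project diffusion weighting onto an eigenframe
#'
#' Decomposes each measurement's b-value into the weighting along the
#' three eigenvectors, \eqn{b_i = b (g \cdot v_i)^2}. Because the
#' eigenvectors are orthonormal and g has unit norm,
#' \eqn{b_1 + b_2 + b_3 = b} exactly; the factorised forward model
#' \eqn{S/S_0 = \prod_i f(b_i)} evaluates each one-dimensional model at
#' these projections.
#'
#' @param scheme an [acq_scheme()].
#' @param eigenvectors 3x3 matrix with unit-norm orthonormal columns.
#' @return n x 3 matrix of per-measurement `(b1, b2, b3)`, s/mm^2.
#' @export
project_b <- function(scheme, eigenvectors) {
  V <- as.matrix(eigenvectors)
  if (max(abs(crossprod(V) - diag(3))) > 1e-6)
    stop("eigenvectors must be orthonormal (tolerance 1e-6)")
  ip <- scheme$dirs %*% V
  scheme$b * ip^2
}
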