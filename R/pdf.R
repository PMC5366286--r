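## Diffusivity probability density functions and their moments.

# Analytic density closure and support for models with a continuous PDF.
# The kurtosis-model PDF is a Gaussian that is *not* truncated at zero, so
# its support may extend below D = 0.
pdf_fun <- function(model_id, params) {
  p <- params
  switch(model_id,
    dk = {
      sd <- p$D * sqrt(p$K / 3)
      list(f = function(D) stats::dnorm(D, mean = p$D, sd = sd),
           support = c(p$D - 10 * sd, p$D + 10 * sd), lower_open = FALSE)
    },
    truncgauss = {
      norm <- stats::pnorm(p$Dm / p$sigma)
      list(f = function(D) ifelse(D < 0, 0,
                                  stats::dnorm(D, p$Dm, p$sigma) / norm),
           support = c(0, p$Dm + 10 * p$sigma))
    },
    gamma = list(
      f = function(D) stats::dgamma(D, shape = p$k, scale = p$theta),
      support = c(0, stats::qgamma(1 - 1e-13, shape = p$k, scale = p$theta))),
    beta = list(
      f = function(D) ifelse(D <= 0 | D >= p$Dmax, 0,
                             stats::dbeta(D / p$Dmax, p$alpha, p$beta) / p$Dmax),
      support = c(0, p$Dmax)),
    stop("model '", model_id, "' has no continuous analytic PDF")
  )
}

#' Diffusivity PDF of a model
#'
#' Returns the probability density function of diffusivity implied by a
#' model's parameters, as a `diffusivity_pdf` object carrying the density
#' on the requested grid together with an exact density closure used by
#' the quadrature routines. The monoexponential model is reported as a
#' single point mass at `D`, and the biexponential model as two point
#' masses with weights `v` and `1 - v`; the stretched exponential has no
#' analytic diffusivity distribution and is refused. The kurtosis-model
#' PDF is a Gaussian with mean `D` and variance \eqn{D^2 K / 3}, not
#' truncated at zero, so it alone may be evaluated on a grid extending
#' below zero.
#'
#' @inheritParams evaluate_signal
#' @param D_grid diffusivity grid, mm^2/s; must be non-negative except
#'   for the `dk` model.
#' @return a `diffusivity_pdf` object: fields `model_id`, `params`,
#'   `support` (mm^2/s), `D` (grid), `density` (1/(mm^2/s)), and either
#'   `density_fun` (continuous models) or `point_masses` (a data frame
#'   with columns `D`, `w`).
#' @export
evaluate_pdf <- function(model_id, params, D_grid = NULL) {
  model_id <- match.arg(model_id, MODEL_IDS)
  if (model_id %in% c("dt", "monoexp")) model_id <- "monoexp"
  if (model_id == "stretched")
    stop("the stretched exponential has no analytic diffusivity PDF; ",
         "its distribution cannot be evaluated here")
  check_params_1d(model_id, params)
  p <- params
  if (model_id == "monoexp" || model_id == "biexp") {
    pm <- if (model_id == "monoexp") {
      data.frame(D = p$D, w = 1)
    } else {
      data.frame(D = c(p$Dfast, p$Dslow), w = c(p$v, 1 - p$v))
    }
    if (!is.null(D_grid) && any(D_grid < 0))
      stop("diffusivity grid must not extend below 0")
    return(structure(list(model_id = model_id, params = p,
                          support = range(pm$D), D = D_grid,
                          density = NULL, point_masses = pm),
                     class = "diffusivity_pdf"))
  }
  pf <- pdf_fun(model_id, p)
  if (!is.null(D_grid)) {
    if (model_id != "dk" && any(D_grid < 0))
      stop("diffusivity grid must not extend below 0")
    dens <- pf$f(D_grid)
  } else dens <- NULL
  structure(list(model_id = model_id, params = p, support = pf$support,
                 D = D_grid, density = dens, density_fun = pf$f,
                 point_masses = NULL),
            class = "diffusivity_pdf")
}

#' @export
print.diffusivity_pdf <- function(x, ...) {
  cat(sprintf("Diffusivity PDF (%s model), support [%g, %g] mm^2/s\n",
              x$model_id, x$support[1], x$support[2]))
  if (!is.null(x$point_masses)) {
    cat("  point masses:\n"); print(x$point_masses)
  }
  invisible(x)
}

#' Analytic mean diffusivity, kurtosis and skewness of a model
#'
#' Kurtosis throughout this package is the normalised variance of the
#' diffusivity distribution, \eqn{K = 3 \mathrm{Var}[D] / E[D]^2}, which
#' is zero for a single Gaussian diffusion environment. Closed forms:
#' monoexponential (K = 0); kurtosis model (mean `D`, kurtosis `K` by
#' definition); biexponential
#' \eqn{\bar D = v D_f + (1-v) D_s},
#' \eqn{K = 3 v (1-v) (D_f - D_s)^2 / \bar D^2}; truncated Gaussian
#' (moments of a normal truncated at zero); gamma (mean \eqn{k\theta},
#' kurtosis \eqn{3/k}, skewness \eqn{2/\sqrt k}); beta (mean
#' \eqn{\alpha/(\alpha+\beta) D_{max}}, kurtosis
#' \eqn{3\beta/(\alpha(\alpha+\beta+1))}, and the standard beta
#' skewness). Skewness is reported for the gamma and beta models only;
#' the stretched exponential admits neither a mean diffusivity nor a
#' kurtosis (its exponent has no Taylor expansion in b for non-integer
#' stretching index) and is refused.
#'
#' @inheritParams evaluate_signal
#' @return list with `mean_diffusivity` (mm^2/s), `kurtosis`
#'   (dimensionless) and `skewness` (dimensionless, `NA` where not
#'   defined by the model family).
#' @examples
#' derived_moments("biexp", list(v = 0.9, Dfast = 1.5e-3, Dslow = 0.5e-3))
#' @export
derived_moments <- function(model_id, params) {
  model_id <- match.arg(model_id, MODEL_IDS)
  if (model_id %in% c("dt", "monoexp")) model_id <- "monoexp"
  if (model_id == "stretched")
    stop("neither the mean diffusivity nor the kurtosis can be derived ",
         "from the stretched exponential model")
  check_params_1d(model_id, params)
  p <- params
  out <- switch(model_id,
    monoexp = list(mean = p$D, K = 0, skew = NA_real_),
    dk = list(mean = p$D, K = p$K, skew = NA_real_),
    biexp = {
      m <- p$v * p$Dfast + (1 - p$v) * p$Dslow
      K <- 3 * p$v * (1 - p$v) * (p$Dfast - p$Dslow)^2 / m^2
      list(mean = m, K = K, skew = NA_real_)
    },
    truncgauss = {
      t <- p$Dm / p$sigma
      lam <- exp(stats::dnorm(t, log = TRUE) -
                   stats::pnorm(t, log.p = TRUE))   # hazard of -t
      m <- p$Dm + p$sigma * lam
      v <- p$sigma^2 * (1 - t * lam - lam^2)
      list(mean = m, K = 3 * v / m^2, skew = NA_real_)
    },
    gamma = list(mean = p$k * p$theta, K = 3 / p$k, skew = 2 / sqrt(p$k)),
    beta = {
      a <- p$alpha; b <- p$beta
      m <- a / (a + b) * p$Dmax
      K <- 3 * b / (a * (a + b + 1))
      sk <- 2 * (b - a) * sqrt(a + b + 1) / ((a + b + 2) * sqrt(a * b))
      list(mean = m, K = K, skew = sk)
    })
  list(mean_diffusivity = out$mean, kurtosis = out$K, skewness = out$skew)
}

#' Signal attenuation by numeric quadrature of a diffusivity PDF
#'
#' Evaluates \eqn{S(b)/S(0) = \int P(D) e^{-bD} dD} by adaptive
#' quadrature (absolute tolerance 1e-9). This is the independent oracle
#' against which every closed-form model in [evaluate_signal()] is
#' verified. Point-mass PDFs (monoexponential, biexponential) are summed
#' exactly. Continuous PDFs are integrated through their exact density
#' closure when available, else through a spline interpolant of the
#' gridded density; a gridded density must be normalised to unit mass
#' within 1e-4 or the input is rejected.
#'
#' @param pdf a `diffusivity_pdf` from [evaluate_pdf()].
#' @param b b-values, s/mm^2.
#' @param use_grid force integration of the gridded density even when
#'   the analytic closure is available.
#' @return numeric vector of attenuations.
#' @export
signal_from_pdf_numeric <- function(pdf, b, use_grid = FALSE) {
  stopifnot(inherits(pdf, "diffusivity_pdf"))
  if (any(b < 0)) stop("negative b-values are not permitted")
  if (!is.null(pdf$point_masses)) {
    pm <- pdf$point_masses
    return(vapply(b, function(bb) sum(pm$w * exp(-bb * pm$D)), numeric(1)))
  }
  if (use_grid || is.null(pdf$density_fun)) {
    if (is.null(pdf$D) || is.null(pdf$density))
      stop("gridded density requested but the PDF carries no grid")
    f <- stats::splinefun(pdf$D, pdf$density, method = "natural")
    lo <- min(pdf$D); hi <- max(pdf$D)
    mass <- stats::integrate(f, lo, hi, rel.tol = 1e-10,
                             subdivisions = 500L)$value
    if (abs(mass - 1) > 1e-4)
      stop(sprintf("PDF is not normalised: integral = %.6f", mass))
  } else {
    if (pdf$model_id == "beta") {
      # substitute away the endpoint singularities t^(a-1), (1-t)^(b-1)
      # (integrable but steeper than QAGS handles when a or b << 1)
      p <- pdf$params
      return(vapply(b, function(bb)
        beta_laplace_quad(p$alpha, p$beta, bb * p$Dmax), numeric(1)))
    }
    f <- pdf$density_fun
    lo <- pdf$support[1]; hi <- pdf$support[2]
  }
  vapply(b, function(bb) {
    stats::integrate(function(D) f(D) * exp(-bb * D), lo, hi,
                     rel.tol = 1e-10, abs.tol = 1e-9,
                     subdivisions = 1000L)$value
  }, numeric(1))
}

# E[exp(-x t)] for t ~ Beta(a, b) by adaptive quadrature with the power
# substitutions u = t^a (left half) and u = (1-t)^b (right half), which
# absorb the endpoint singularities exactly
beta_laplace_quad <- function(a, b, x, t0 = 0.5) {
  beta_expect_quad(a, b, function(t) exp(-x * t), t0)
}

# E[g(t)] for t ~ Beta(a, b), same substitutions
beta_expect_quad <- function(a, b, g, t0 = 0.5) {
  left <- stats::integrate(function(u) {
    t <- u^(1 / a)
    (1 - t)^(b - 1) * g(t) / a
  }, 0, t0^a, rel.tol = 1e-12, subdivisions = 2000L)$value
  right <- stats::integrate(function(u) {
    t <- 1 - u^(1 / b)
    t^(a - 1) * g(t) / b
  }, 0, (1 - t0)^b, rel.tol = 1e-12, subdivisions = 2000L)$value
  (left + right) / beta(a, b)
}

# Quadrature moments (mean, kurtosis, skewness) of a continuous model PDF;
# independent oracle for derived_moments().
quadrature_moments <- function(model_id, params) {
  if (model_id == "beta") {
    # work on the unit interval (better-conditioned sign-changing
    # integrands) and rescale by Dmax analytically
    momt <- function(g) beta_expect_quad(params$alpha, params$beta, g)
    m1t <- momt(identity)
    vt <- momt(function(t) (t - m1t)^2)
    m3t <- momt(function(t) (t - m1t)^3)
    return(list(mean_diffusivity = m1t * params$Dmax,
                kurtosis = 3 * vt / m1t^2, skewness = m3t / vt^1.5))
  }
  pf <- pdf_fun(model_id, params)
  mom <- function(g) stats::integrate(function(D) g(D) * pf$f(D),
                                      pf$support[1], pf$support[2],
                                      rel.tol = 1e-13,
                                      subdivisions = 4000L)$value
  m1 <- mom(identity)
  v <- mom(function(D) (D - m1)^2)
  m3 <- mom(function(D) (D - m1)^3)
  list(mean_diffusivity = m1, kurtosis = 3 * v / m1^2,
       skewness = m3 / v^1.5)
}
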