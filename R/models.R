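## The model zoo: closed-form one-dimensional signal attenuation for the
## seven diffusion models. All shape parameters are per-eigenvector scalars
## here; the three-axis factorised forward model lives in fitting.R.

MODEL_IDS <- c("dt", "monoexp", "stretched", "dk", "biexp",
               "truncgauss", "gamma", "beta")

# Parameter counts entering AICc (P, including the error variance), the
# per-axis shape parameters, and global scalars for each model.
MODEL_REGISTRY <- list(
  dt         = list(p_fit = 8L,  axis = character(0),       global = character(0)),
  monoexp    = list(p_fit = 8L,  axis = "D",                global = character(0)),
  stretched  = list(p_fit = 14L, axis = c("Ds", "a"),       global = character(0)),
  dk         = list(p_fit = 14L, axis = c("D", "K"),        global = character(0)),
  biexp      = list(p_fit = 15L, axis = c("Dfast", "Dslow"), global = "v"),
  truncgauss = list(p_fit = 14L, axis = c("Dm", "sigma"),   global = character(0)),
  gamma      = list(p_fit = 14L, axis = c("k", "theta"),    global = character(0)),
  beta       = list(p_fit = 15L, axis = c("alpha", "beta"), global = "Dmax")
)

#' Model specification
#'
#' Identity and parameter bookkeeping for the seven diffusion models: the
#' parameter count `P` entering the corrected Akaike information
#' criterion (which includes the residual variance and, for the
#' non-Gaussian models, the six reference-frame tensor elements), the
#' per-eigenvector shape parameters, and the global scalars.
#'
#' @param model_id one of `"dt"`, `"monoexp"`, `"stretched"`, `"dk"`,
#'   `"biexp"`, `"truncgauss"`, `"gamma"`, `"beta"`. `"monoexp"` is the
#'   one-dimensional primitive whose three-axis factorisation coincides
#'   with the diffusion tensor model `"dt"` (both count P = 8).
#' @return a list with elements `model_id`, `n_params_fit`, `axis_params`,
#'   `global_params`.
#' @export
model_spec <- function(model_id) {
  model_id <- match.arg(model_id, MODEL_IDS)
  r <- MODEL_REGISTRY[[model_id]]
  list(model_id = model_id, n_params_fit = r$p_fit,
       axis_params = r$axis, global_params = r$global)
}

check_params_1d <- function(model_id, params) {
  p <- params
  chk <- function(cond, name, what) {
    if (!isTRUE(all(cond))) stop_bound(name, p[[name]][!cond][1], what)
  }
  switch(model_id,
    monoexp = chk(p$D >= 0, "D", ">= 0"),
    dt      = chk(p$D >= 0, "D", ">= 0"),
    stretched = {
      chk(p$Ds >= 0, "Ds", ">= 0")
      chk(p$a > 0 & p$a <= 1, "a", "in (0, 1]")
    },
    dk = {
      chk(p$D >= 0, "D", ">= 0")
      chk(p$K >= 0, "K", ">= 0")
    },
    biexp = {
      chk(p$Dfast >= 0, "Dfast", ">= 0")
      chk(p$Dslow >= 0, "Dslow", ">= 0")
      chk(p$v >= 0 & p$v <= 1, "v", "in [0, 1]")
      chk(p$Dfast >= p$Dslow, "Dfast", ">= Dslow")
    },
    truncgauss = {
      chk(p$Dm >= 0, "Dm", ">= 0")
      chk(p$sigma > 0, "sigma", "> 0")
    },
    gamma = {
      chk(p$k > 0, "k", "> 0")
      chk(p$theta > 0, "theta", "> 0")
    },
    beta = {
      chk(p$alpha > 0, "alpha", "> 0")
      chk(p$beta > 0, "beta", "> 0")
      chk(p$Dmax > 0, "Dmax", "> 0")
    })
  invisible(TRUE)
}

#' One-dimensional signal attenuation of a diffusion model
#'
#' Evaluates the normalised attenuation \eqn{S(b)/S(0)} of one model
#' along a single eigenvector direction. The closed forms are:
#' monoexponential \eqn{e^{-bD}}; stretched exponential
#' \eqn{e^{-b^a D_s}} (see `stretched_form`); diffusion kurtosis
#' \eqn{e^{-bD + K b^2 D^2/6}}; biexponential
#' \eqn{v e^{-b D_{fast}} + (1-v) e^{-b D_{slow}}}; truncated Gaussian
#' (error-function ratio times a Gaussian-in-b factor, evaluated in log
#' space for stability); gamma \eqn{(1 + b\theta)^{-k}}; beta
#' \eqn{M(\alpha, \alpha+\beta, -b D_{max})} with \eqn{M} the Kummer
#' confluent hypergeometric function.
#'
#' All models are the Laplace transform \eqn{\int P(D) e^{-bD} dD} of
#' their diffusivity distribution; [signal_from_pdf_numeric()] provides
#' the quadrature counterpart used as an oracle in the test suite.
#'
#' @param model_id model identifier; see [model_spec()]. `"dt"` is
#'   accepted as an alias of `"monoexp"` for one-dimensional evaluation.
#' @param params named list of one-axis parameters, e.g.
#'   `list(D = 1e-3)` for `monoexp`, `list(k = 3, theta = 4e-4)` for
#'   `gamma`, `list(alpha = 2, beta = 1.5, Dmax = 2e-3)` for `beta`.
#'   Diffusivities in mm^2/s.
#' @param b b-values, s/mm^2, `>= 0`.
#' @param stretched_form parameterisation of the stretched exponential:
#'   `"separate"` (default) evaluates \eqn{e^{-b^a D_s}} with a
#'   stretch-adjusted scale `Ds`; `"compound"` evaluates
#'   \eqn{e^{-(b D_s)^a}}. Both appear in the literature; the default
#'   follows the form in which the model is usually printed.
#' @return numeric vector of attenuations; exactly 1 at `b = 0`. All
#'   models decay monotonically in b except the kurtosis model, whose
#'   log-quadratic form turns upward beyond its minimum at
#'   \eqn{b = 3/(D K)}.
#' @examples
#' evaluate_signal("gamma", list(k = 3, theta = 4e-4), c(0, 1000, 5000))
#' @export
evaluate_signal <- function(model_id, params, b,
                            stretched_form = c("separate", "compound")) {
  model_id <- match.arg(model_id, MODEL_IDS)
  if (model_id == "dt") model_id <- "monoexp"
  stretched_form <- match.arg(stretched_form)
  if (any(b < 0)) stop("negative b-values are not permitted")
  check_params_1d(model_id, params)
  p <- params
  out <- switch(model_id,
    monoexp = exp(-b * p$D),
    stretched = if (stretched_form == "separate") {
      exp(-b^p$a * p$Ds)
    } else {
      exp(-(b * p$Ds)^p$a)
    },
    dk = exp(-b * p$D + p$K / 6 * b^2 * p$D^2),
    biexp = p$v * exp(-b * p$Dfast) + (1 - p$v) * exp(-b * p$Dslow),
    truncgauss = {
      s <- p$sigma
      z1 <- (b * s^2 - p$Dm) / (s * sqrt(2))
      z0 <- -p$Dm / (s * sqrt(2))
      exp(log_erfc(z1) - log_erfc(z0) - b * p$Dm + b^2 * s^2 / 2)
    },
    gamma = exp(-p$k * log1p(b * p$theta)),
    beta = kummer_m(p$alpha, p$alpha + p$beta, -b * p$Dmax))
  # b = 0 is exactly 1 by construction for every branch
  out
}
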