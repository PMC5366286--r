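## Voxelwise bounded nonlinear least-squares fitting of the model zoo in
## the diagonalised diffusion-tensor reference frame.

#' Fit configuration
#'
#' @param b_max largest b-value (s/mm^2) entering the fits.
#' @param dk_b_cap the kurtosis model's input data are restricted to
#'   b <= this cap (default 5000 s/mm^2) so that the truncated cubic term
#'   of its expansion stays negligible; its residuals can still be
#'   evaluated on the full measurement set for model comparison.
#' @param ftol,ptol function and step tolerances of the bounded
#'   Levenberg-Marquardt optimiser.
#' @param maxiter iteration cap; non-convergence returns the best
#'   parameters found, flagged, never an error.
#' @param seed optional integer seeding any stochastic restart.
#' @param fit_frame `"joint"` re-optimises the six reference-frame tensor
#'   elements together with the shape parameters (default); `"frozen"`
#'   keeps the eigenvectors of the initial tensor fit.
#' @param stretched_form see [evaluate_signal()].
#' @param dt_init_b_max b-value ceiling for the initial linear tensor
#'   fit, default 2000 s/mm^2.
#' @return a `fit_config` list.
#' @export
fit_config <- function(b_max = 10000, dk_b_cap = 5000,
                       ftol = 1e-10, ptol = 1e-10, maxiter = 500L,
                       seed = NULL, fit_frame = c("joint", "frozen"),
                       stretched_form = c("separate", "compound"),
                       dt_init_b_max = 2000) {
  stopifnot(b_max > 0, dk_b_cap > 0, ftol > 0, ptol > 0, maxiter > 0)
  structure(list(b_max = b_max, dk_b_cap = dk_b_cap, ftol = ftol,
                 ptol = ptol, maxiter = as.integer(maxiter), seed = seed,
                 fit_frame = match.arg(fit_frame),
                 stretched_form = match.arg(stretched_form),
                 dt_init_b_max = dt_init_b_max),
            class = "fit_config")
}

# ---- parameter vector layout -------------------------------------------

TENSOR_NAMES <- c("Txx", "Tyy", "Tzz", "Txy", "Txz", "Tyz")

par_names <- function(model_id, frame_mode) {
  r <- MODEL_REGISTRY[[model_id]]
  head <- if (model_id == "dt" || frame_mode == "joint")
    c("S0", TENSOR_NAMES) else "S0"
  axis <- if (length(r$axis))
    as.vector(t(outer(r$axis, 1:3, paste0))) else character(0)
  c(head, axis, r$global)
}

tensor_from_par <- function(p) {
  matrix(c(p[["Txx"]], p[["Txy"]], p[["Txz"]],
           p[["Txy"]], p[["Tyy"]], p[["Tyz"]],
           p[["Txz"]], p[["Tyz"]], p[["Tzz"]]), 3, 3)
}

axis_par <- function(p, name) c(p[[paste0(name, 1)]], p[[paste0(name, 2)]],
                                p[[paste0(name, 3)]])

# fitting box: positivity where physically required plus a water-ceiling
# on diffusivity-like scales
par_bounds <- function(model_id, frame_mode, s0_scale) {
  nm <- par_names(model_id, frame_mode)
  lower <- stats::setNames(rep(-Inf, length(nm)), nm)
  upper <- stats::setNames(rep(Inf, length(nm)), nm)
  set <- function(pat, lo, hi) {
    i <- grepl(pat, nm)
    lower[i] <<- lo; upper[i] <<- hi
  }
  set("^S0$", 0, 20 * s0_scale)
  set("^T(xx|yy|zz)$", 0, 5e-3)
  set("^T(xy|xz|yz)$", -5e-3, 5e-3)
  set("^Ds[123]$", 0, 5e-3)
  set("^a[123]$", 1e-3, 1)
  set("^D[123]$", 0, 5e-3)
  set("^K[123]$", 0, 10)
  set("^D(fast|slow)[123]$", 0, 5e-3)
  set("^v$", 0, 1)
  set("^Dm[123]$", 0, 5e-3)
  set("^sigma[123]$", 1e-6, 1e3)
  set("^k[123]$", 1e-6, 1e3)
  set("^theta[123]$", 1e-8, 5e-3)
  set("^alpha[123]$", 1e-6, 1e3)
  set("^beta[123]$", 1e-6, 1e3)
  set("^Dmax$", 0.5e-3, 5e-3)
  list(lower = lower, upper = upper)
}

# ---- forward model ------------------------------------------------------

# fast unvalidated 1-D attenuation along one axis (bounds guaranteed by
# the optimiser box)
eval_axis <- function(model_id, b, p, i, stretched_form) {
  switch(model_id,
    stretched = {
      Ds <- p[[paste0("Ds", i)]]; a <- p[[paste0("a", i)]]
      if (stretched_form == "separate") exp(-b^a * Ds)
      else exp(-(b * Ds)^a)
    },
    dk = {
      D <- p[[paste0("D", i)]]; K <- p[[paste0("K", i)]]
      exp(-b * D + K / 6 * b^2 * D^2)
    },
    biexp = {
      Df <- p[[paste0("Dfast", i)]]; Ds <- p[[paste0("Dslow", i)]]
      p[["v"]] * exp(-b * Df) + (1 - p[["v"]]) * exp(-b * Ds)
    },
    truncgauss = {
      Dm <- p[[paste0("Dm", i)]]; s <- p[[paste0("sigma", i)]]
      exp(log_erfc((b * s^2 - Dm) / (s * sqrt(2))) -
            log_erfc(-Dm / (s * sqrt(2))) - b * Dm + b^2 * s^2 / 2)
    },
    gamma = {
      k <- p[[paste0("k", i)]]; th <- p[[paste0("theta", i)]]
      exp(-k * log1p(b * th))
    },
    beta = {
      al <- p[[paste0("alpha", i)]]; be <- p[[paste0("beta", i)]]
      kummer_m(al, al + be, -b * p[["Dmax"]])
    })
}

predict_from_par <- function(model_id, p, scheme, config,
                             frozen_V = NULL) {
  if (model_id == "dt") {
    Tm <- tensor_from_par(p)
    q <- rowSums((scheme$dirs %*% Tm) * scheme$dirs)
    return(p[["S0"]] * exp(-scheme$b * q))
  }
  V <- if (is.null(frozen_V)) eigen(tensor_from_par(p),
                                    symmetric = TRUE)$vectors else frozen_V
  B <- scheme$b * (scheme$dirs %*% V)^2
  p[["S0"]] *
    eval_axis(model_id, B[, 1], p, 1L, config$stretched_form) *
    eval_axis(model_id, B[, 2], p, 2L, config$stretched_form) *
    eval_axis(model_id, B[, 3], p, 3L, config$stretched_form)
}

#' Predicted signal of a converged fit
#'
#' Evaluates the fitted forward model \eqn{S_0 \prod_i f(b_i)} on an
#' arbitrary scheme (e.g. to compute residuals of the b-capped kurtosis
#' fit on the full measurement set during model selection).
#'
#' @param fit a `fit_result`.
#' @param scheme an [acq_scheme()].
#' @return numeric vector of predicted signals.
#' @export
predict_signal <- function(fit, scheme) {
  # the stored eigenvectors correspond axis-by-axis to the stored
  # parameters (including after axis relabelling), so they are used
  # directly rather than re-derived from the tensor
  predict_from_par(fit$model_id, fit$par, scheme, fit$config,
                   frozen_V = fit$eigenvectors)
}

# ---- initialisation cascade ---------------------------------------------

#' Linear least-squares kurtosis-model fit in a fixed eigenframe
#'
#' Regresses the log-signal on the eigenframe projections
#' \eqn{(b_1, b_2, b_3)} and their squares, giving per-axis apparent
#' diffusivity and kurtosis in closed form. Used to initialise the
#' kurtosis model and, through its moments, the statistical-distribution
#' models. Input data are restricted to `b <= b_cap`.
#'
#' @param signals measured signals.
#' @param scheme an [acq_scheme()].
#' @param eigenvectors 3x3 eigenvector matrix from a tensor fit.
#' @param b_cap b-value ceiling, default 5000 s/mm^2.
#' @return list with `S0`, `D` (length 3), `K` (length 3).
#' @export
fit_dk_linear <- function(signals, scheme, eigenvectors, b_cap = 5000) {
  keep <- scheme$b <= b_cap & signals > 0
  sub <- subset_scheme(scheme, b_cap)
  keep2 <- signals[scheme$b <= b_cap] > 0
  B <- project_b(sub, eigenvectors)[keep2, , drop = FALSE]
  y <- log(signals[keep])
  X <- cbind(1, -B, B^2)
  co <- qr.coef(qr(X), y)
  D <- pmax(co[2:4], 1e-12)
  K <- 6 * co[5:7] / D^2
  list(S0 = exp(co[1]), D = as.numeric(D), K = as.numeric(K))
}

# Moment inversion used by the statistical models: given (mean, K) from
# the kurtosis model, produce starting shape parameters.
init_from_moments <- function(model_id, D, K, Dmax_init = 2.3e-3) {
  K <- ifelse(K <= 0, 0.01, K)
  switch(model_id,
    gamma = list(k = 3 / K, theta = D * K / 3),
    truncgauss = list(Dm = D, sigma = D * sqrt(K / 3)),
    beta = {
      m <- pmin(D / Dmax_init, 0.97)
      alpha <- pmax(3 * (1 - m) / K - m, 0.05)
      list(alpha = alpha, beta = alpha * (1 - m) / m, Dmax = Dmax_init)
    })
}

#' Initial parameter values for a model fit
#'
#' Implements the initialisation cascade: tensor and kurtosis models from
#' linear least squares on the log-signal; stretched exponential from the
#' tensor fit (stretching index 1, scale = eigenvalue); biexponential
#' from two segmented monoexponential fits (b < 1000 s/mm^2 for the fast
#' rate, b > 6000 s/mm^2 for the slow rate, volume fraction from the two
#' intercepts); truncated Gaussian, gamma and beta from the per-axis mean
#' diffusivity and kurtosis of the linear kurtosis fit (beta's `Dmax`
#' starts at the diffusivity of pure water at room temperature,
#' 2.3e-3 mm^2/s). A non-positive kurtosis at initialisation falls back
#' to K = 0.01 with a warning, since the moment inversion is undefined
#' there. All values are clipped into the fitting bounds.
#'
#' @param model_id model identifier.
#' @param signals measured signals.
#' @param scheme an [acq_scheme()].
#' @param dt_fit a `tensor_fit` (from [fit_dt_linear()]).
#' @param dk_fit optional output of [fit_dk_linear()]; computed on demand
#'   for the models that need it.
#' @param config a [fit_config()].
#' @return named numeric vector laid out for [fit_voxel()].
#' @export
initialize_params <- function(model_id, signals, scheme, dt_fit,
                              dk_fit = NULL, config = fit_config()) {
  model_id <- match.arg(model_id, setdiff(MODEL_IDS, "monoexp"))
  lam <- pmax(dt_fit$eigenvalues, 1e-6)
  Tm <- dt_fit$tensor
  head <- c(S0 = dt_fit$S0,
            Txx = Tm[1, 1], Tyy = Tm[2, 2], Tzz = Tm[3, 3],
            Txy = Tm[1, 2], Txz = Tm[1, 3], Tyz = Tm[2, 3])
  need_dk <- model_id %in% c("dk", "truncgauss", "gamma", "beta")
  if (need_dk && is.null(dk_fit))
    dk_fit <- fit_dk_linear(signals, scheme, dt_fit$eigenvectors,
                            b_cap = min(config$dk_b_cap, config$b_max))
  tail <- switch(model_id,
    dt = numeric(0),
    # stretching index starts marginally inside its upper bound: a
    # parameter initialised exactly on a box bound cannot move when the
    # local gradient points outward under projected Levenberg-Marquardt
    stretched = c(Ds1 = lam[1], Ds2 = lam[2], Ds3 = lam[3],
                  a1 = 0.99, a2 = 0.99, a3 = 0.99),
    dk = {
      K <- dk_fit$K
      if (any(K <= 0)) {
        warning("non-positive kurtosis at initialisation; using K = 0.01")
        K[K <= 0] <- 0.01
      }
      c(D1 = dk_fit$D[1], D2 = dk_fit$D[2], D3 = dk_fit$D[3],
        K1 = K[1], K2 = K[2], K3 = K[3])
    },
    biexp = init_biexp(signals, scheme, dt_fit),
    truncgauss = , gamma = , beta = {
      K <- dk_fit$K
      if (any(K <= 0)) {
        warning("non-positive kurtosis at initialisation; using K = 0.01")
      }
      ip <- init_from_moments(model_id, dk_fit$D, K)
      u <- unlist(lapply(names(ip), function(nm) {
        if (length(ip[[nm]]) == 3)
          stats::setNames(ip[[nm]], paste0(nm, 1:3))
        else stats::setNames(ip[[nm]], nm)
      }))
      u
    })
  p <- c(head, tail)
  if (config$fit_frame == "frozen" && model_id != "dt")
    p <- p[setdiff(names(p), TENSOR_NAMES)]
  bd <- par_bounds(model_id, config$fit_frame, s0_scale = dt_fit$S0)
  pmin(pmax(p[names(bd$lower)], bd$lower), bd$upper)
}

# segmented monoexponential initialisation of the biexponential model
init_biexp <- function(signals, scheme, dt_fit) {
  seg_fit <- function(lo, hi) {
    keep <- scheme$b >= lo & scheme$b < hi & signals > 0
    if (sum(keep) < 5L) return(NULL)
    B <- project_b(subset_scheme_idx(scheme, keep), dt_fit$eigenvectors)
    co <- tryCatch(qr.coef(qr(cbind(1, -B)), log(signals[keep])),
                   error = function(e) NULL)
    if (is.null(co) || anyNA(co)) NULL else co
  }
  low <- seg_fit(0, 1000)
  high <- seg_fit(6000, Inf)
  lam <- pmax(dt_fit$eigenvalues, 1e-6)
  # a noise-dominated high-b segment yields slopes near or below zero;
  # treat that as a failed segment rather than a usable slow rate
  if (!is.null(high) && any(high[2:4] < 1e-5)) high <- NULL
  Dfast <- if (!is.null(low)) pmax(low[2:4], 1e-5) else lam
  Dslow <- if (!is.null(high)) high[2:4] else lam / 4
  v <- if (!is.null(low) && !is.null(high))
    1 - exp(high[1] - low[1]) else 0.9
  v <- min(max(v, 0.05), 0.95)
  Dslow <- pmin(Dslow, Dfast * 0.99)
  c(Dfast1 = Dfast[[1]], Dfast2 = Dfast[[2]], Dfast3 = Dfast[[3]],
    Dslow1 = Dslow[[1]], Dslow2 = Dslow[[2]], Dslow3 = Dslow[[3]], v = v)
}

subset_scheme_idx <- function(scheme, keep) {
  structure(list(b = scheme$b[keep], dirs = scheme$dirs[keep, , drop = FALSE],
                 delta = scheme$delta, Delta = scheme$Delta,
                 gamma = scheme$gamma, G = scheme$G[keep],
                 n_non_dw = sum(scheme$b[keep] == 0)),
            class = "acq_scheme")
}

# ---- the voxel fit ------------------------------------------------------

#' Fit one model to one voxel by bounded nonlinear least squares
#'
#' Minimises \eqn{\sum (S_{meas} - S_0 \prod_i f(b_i))^2} over the model
#' parameters with box constraints, using Levenberg-Marquardt
#' (minpack.lm). In the default `"joint"` frame mode the six symmetric
#' tensor elements defining the eigenframe are optimised together with
#' the shape parameters; only their eigenvectors enter the forward model
#' of the non-Gaussian models. The kurtosis model is fit on measurements
#' with `b <= dk_b_cap` only. Non-convergence at the iteration cap
#' returns the best parameters found with `converged = FALSE`.
#'
#' @param model_id model identifier (any of the seven fit models; see
#'   [model_spec()]).
#' @param signals one voxel's measurements, same length as the scheme.
#' @param scheme an [acq_scheme()].
#' @param config a [fit_config()].
#' @param dt_fit,dk_fit optional precomputed initial fits; derived on
#'   demand.
#' @param init optional full named initial parameter vector.
#' @return a `fit_result`: converged parameters, per-voxel mean squared
#'   residual `epsilon2`, `rmse`, `n_used`, `converged`, `n_iter`, plus
#'   the fitted eigenframe.
#' @export
fit_voxel <- function(model_id, signals, scheme, config = fit_config(),
                      dt_fit = NULL, dk_fit = NULL, init = NULL) {
  model_id <- match.arg(model_id, setdiff(MODEL_IDS, "monoexp"))
  if (length(signals) != length(scheme$b))
    stop("signals length (", length(signals), ") does not match scheme (",
         length(scheme$b), ")")
  if (all(signals == 0))
    return(structure(list(model_id = model_id, skipped = TRUE,
                          converged = FALSE), class = "fit_result"))
  b_cap <- if (model_id == "dk") min(config$b_max, config$dk_b_cap)
           else config$b_max
  sub <- subset_scheme(scheme, b_cap)
  sig <- signals[sub$keep]
  n_par_opt <- length(par_names(model_id, config$fit_frame))
  if (length(sig) < n_par_opt)
    stop("fewer measurements (", length(sig), ") than parameters (",
         n_par_opt, ") below b_max")
  if (is.null(dt_fit))
    dt_fit <- fit_dt_linear(signals, scheme,
                            b_max = min(config$dt_init_b_max, config$b_max))
  if (is.null(init))
    init <- initialize_params(model_id, signals, scheme, dt_fit, dk_fit,
                              config)
  frozen_V <- if (config$fit_frame == "frozen" && model_id != "dt")
    dt_fit$eigenvectors else NULL
  resid_fn <- function(p) {
    p <- stats::setNames(p, names(init))
    sig - predict_from_par(model_id, p, sub, config, frozen_V)
  }
  bd <- par_bounds(model_id, config$fit_frame, s0_scale = dt_fit$S0)
  inits <- list(init)
  if (model_id == "biexp") {
    # the biexponential objective is multimodal (label switching plus a
    # shallow valley when the slow segment is noise-dominated); add a
    # deterministic second start with the fast component at the
    # free-water diffusivity and an even split
    alt <- init
    alt[paste0("Dfast", 1:3)] <- 2.3e-3
    alt[paste0("Dslow", 1:3)] <- pmax(dt_fit$eigenvalues, 1e-5) * 0.8
    alt["v"] <- 0.5
    inits <- c(inits, list(alt))
  }
  fit <- NULL
  for (ini in inits) {
    cand <- minpack.lm::nls.lm(
      par = ini, lower = bd$lower[names(init)],
      upper = bd$upper[names(init)], fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        ftol = config$ftol, ptol = config$ptol, maxiter = config$maxiter))
    if (is.null(fit) || cand$deviance < fit$deviance) fit <- cand
  }
  p <- stats::setNames(fit$par, names(init))
  # label-switching: keep the fast component fast (global v forces a
  # global relabel, applied when every axis is inverted)
  if (model_id == "biexp") {
    Df <- axis_par(p, "Dfast"); Ds <- axis_par(p, "Dslow")
    if (all(Df < Ds)) {
      p[paste0("Dfast", 1:3)] <- Ds
      p[paste0("Dslow", 1:3)] <- Df
      p["v"] <- 1 - p[["v"]]
    }
  }
  res <- resid_fn(p)
  Tm <- if (config$fit_frame == "joint" || model_id == "dt")
    tensor_from_par(p) else dt_fit$tensor
  e <- eigen(Tm, symmetric = TRUE)
  structure(list(
    model_id = model_id, par = p, S0 = p[["S0"]], tensor = Tm,
    eigenvalues = e$values, eigenvectors = e$vectors,
    epsilon2 = mean(res^2), rmse = sqrt(mean(res^2)),
    n_used = length(sig), converged = fit$info %in% 1:4,
    n_iter = fit$niter, info = fit$info, init = init,
    epsilon2_init = mean(resid_fn(init)^2),
    frame_mode = if (is.null(frozen_V)) "joint" else "frozen",
    config = config, skipped = FALSE), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  if (isTRUE(x$skipped)) {
    cat("Fit (", x$model_id, "): skipped (all-zero voxel)\n"); return(invisible(x))
  }
  cat(sprintf("Fit (%s): rmse = %.4g, n = %d, %s in %d iterations\n",
              x$model_id, x$rmse, x$n_used,
              if (x$converged) "converged" else "NOT converged", x$n_iter))
  invisible(x)
}

#' Per-axis parameters and derived moments of a fit
#'
#' @param fit a `fit_result`.
#' @return data frame with one row per eigenvector axis: shape
#'   parameters, mean diffusivity, kurtosis, skewness (where defined).
#' @export
axis_moments <- function(fit) {
  r <- MODEL_REGISTRY[[fit$model_id]]
  rows <- lapply(1:3, function(i) {
    ap <- stats::setNames(
      lapply(r$axis, function(nm) fit$par[[paste0(nm, i)]]), r$axis)
    gp <- stats::setNames(lapply(r$global, function(nm) fit$par[[nm]]),
                          r$global)
    pars <- c(ap, gp)
    mom <- if (fit$model_id %in% c("stretched", "dt")) {
      list(mean_diffusivity = if (fit$model_id == "dt")
        fit$eigenvalues[i] else NA_real_,
        kurtosis = NA_real_, skewness = NA_real_)
    } else derived_moments(fit$model_id, pars)
    cbind(data.frame(axis = paste0("v", i)),
          as.data.frame(pars, optional = TRUE),
          data.frame(mean_diffusivity = mom$mean_diffusivity,
                     kurtosis = mom$kurtosis, skewness = mom$skewness))
  })
  do.call(rbind, rows)
}

# ---- volume fitting -----------------------------------------------------

#' Fit models to every voxel of a masked volume
#'
#' @param volume 4-D array `[x, y, z, measurement]` or an
#'   `n_voxel x n_measurement` matrix.
#' @param mask logical 3-D array (for a 4-D volume) or a logical/index
#'   vector of rows (for a matrix); `NULL` fits everything.
#' @param scheme an [acq_scheme()].
#' @param models character vector of model identifiers to fit.
#' @param config a [fit_config()]; `config$seed` makes any stochastic
#'   component reproducible.
#' @return a `model_fits` object: `fits[[model]][[voxel]]` fit results,
#'   `voxels` (indices into the mask), `scheme`, `config`.
#' @export
fit_volume <- function(volume, mask = NULL, scheme,
                       models = c("dt", "beta"), config = fit_config()) {
  models <- vapply(models, function(m)
    match.arg(m, setdiff(MODEL_IDS, "monoexp")), character(1))
  if (length(dim(volume)) == 4L) {
    d <- dim(volume)
    if (d[4] != length(scheme$b))
      stop("volume has ", d[4], " measurements but the scheme has ",
           length(scheme$b), " (dimensions ", paste(d, collapse = "x"), ")")
    if (is.null(mask)) mask <- array(TRUE, d[1:3])
    if (!all(dim(mask) == d[1:3]))
      stop("mask dimensions ", paste(dim(mask), collapse = "x"),
           " do not match volume ", paste(d[1:3], collapse = "x"))
    vox <- which(mask)
    sig_mat <- matrix(volume, prod(d[1:3]), d[4])[vox, , drop = FALSE]
  } else {
    sig_mat <- as.matrix(volume)
    if (ncol(sig_mat) != length(scheme$b))
      stop("signal matrix has ", ncol(sig_mat), " columns but the scheme ",
           "has ", length(scheme$b), " measurements")
    vox <- if (is.null(mask)) seq_len(nrow(sig_mat)) else which(mask)
    sig_mat <- sig_mat[vox, , drop = FALSE]
  }
  with_seed(config$seed, {
    fits <- stats::setNames(vector("list", length(models)), models)
    for (m in models) fits[[m]] <- vector("list", length(vox))
    need_dk <- any(models %in% c("dk", "truncgauss", "gamma", "beta"))
    for (j in seq_along(vox)) {
      sig <- sig_mat[j, ]
      if (all(sig == 0)) {
        for (m in models)
          fits[[m]][[j]] <- structure(list(model_id = m, skipped = TRUE,
                                           converged = FALSE),
                                      class = "fit_result")
        next
      }
      dt0 <- fit_dt_linear(sig, scheme,
                           b_max = min(config$dt_init_b_max, config$b_max))
      dk0 <- if (need_dk)
        fit_dk_linear(sig, scheme, dt0$eigenvectors,
                      b_cap = min(config$dk_b_cap, config$b_max)) else NULL
      for (m in models)
        fits[[m]][[j]] <- suppressWarnings(
          fit_voxel(m, sig, scheme, config, dt_fit = dt0, dk_fit = dk0))
    }
    structure(list(fits = fits, voxels = vox, models = models,
                   scheme = scheme, config = config,
                   n_voxels = length(vox)),
              class = "model_fits")
  })
}

#' Disambiguate the second and third eigenvector axes against a frame
#'
#' When the secondary and tertiary eigenvalues are within noise of each
#' other — the usual situation in myocardium — descending-eigenvalue
#' sorting assigns the sheetlet and sheetlet-normal axes essentially at
#' random per voxel, mixing their per-axis parameters in ROI summaries.
#' This relabels axes 2 and 3 of every voxel fit so that the tertiary
#' eigenvector is the one better aligned with the local radial
#' (sheetlet-normal) direction, the standard cardiac convention. Axis
#' relabelling is an exact symmetry of the factorised forward model, so
#' predictions and residuals are unchanged.
#'
#' @param fits a `model_fits` from [fit_volume()].
#' @param radial n_voxel-by-3 matrix of local radial unit vectors for
#'   the full grid (rows in column-major voxel order, e.g.
#'   `wall_frame$radial`), or one row per fitted voxel.
#' @return the `model_fits` object with axes relabelled.
#' @export
relabel_axes_by_frame <- function(fits, radial) {
  stopifnot(inherits(fits, "model_fits"))
  radial <- as.matrix(radial)
  rows <- if (nrow(radial) == fits$n_voxels) seq_len(fits$n_voxels)
          else fits$voxels
  for (j in seq_len(fits$n_voxels)) {
    r <- radial[rows[j], ]
    for (m in fits$models) {
      f <- fits$fits[[m]][[j]]
      if (isTRUE(f$skipped)) next
      if (abs(sum(f$eigenvectors[, 2] * r)) <=
          abs(sum(f$eigenvectors[, 3] * r))) next
      f$eigenvectors[, 2:3] <- f$eigenvectors[, 3:2]
      f$eigenvalues[2:3] <- f$eigenvalues[3:2]
      for (nm in MODEL_REGISTRY[[m]]$axis) {
        i2 <- paste0(nm, 2); i3 <- paste0(nm, 3)
        tmp <- f$par[[i2]]
        f$par[[i2]] <- f$par[[i3]]
        f$par[[i3]] <- tmp
      }
      fits$fits[[m]][[j]] <- f
    }
  }
  fits
}

#' @export
print.model_fits <- function(x, ...) {
  cat(sprintf("Model fits: %d voxels x {%s}\n", x$n_voxels,
              paste(x$models, collapse = ", ")))
  invisible(x)
}
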