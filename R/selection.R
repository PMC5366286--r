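## AICc model comparison and the maximum-b-value sweep.

#' Corrected Akaike information criterion
#'
#' \eqn{AIC_c = n \log(\epsilon^2) + 2P + 2P(P+1)/(n - P - 1)}, with
#' natural logarithm, where \eqn{\epsilon^2} is the mean squared
#' residual, `n` the number of measurements and `P` the number of model
#' parameters including the residual variance. The correction term is
#' singular at `n = P + 1`, so `n > P + 1` is required.
#'
#' @param n number of measurements.
#' @param P parameter count including the error variance (8 for the
#'   tensor model, 14 for the stretched exponential, kurtosis, truncated
#'   Gaussian and gamma models, 15 for the biexponential and beta
#'   models).
#' @param mse mean squared residual, `> 0`.
#' @return the AICc value.
#' @examples
#' aicc(261, 8, 1) # 16 + 144/252
#' @export
aicc <- function(n, P, mse) {
  if (any(n <= P + 1))
    stop("AICc requires n > P + 1 (the finite-sample correction term is ",
         "singular at n = P + 1); got n = ", n[1], ", P = ", P[1])
  if (any(mse <= 0)) stop("mse must be positive")
  n * log(mse) + 2 * P + 2 * P * (P + 1) / (n - P - 1)
}

#' Relative likelihood of each model
#'
#' \eqn{p_i = \exp((AIC_{c,min} - AIC_{c,i})/2)}: the probability that
#' model i minimises the estimated information loss, relative to the
#' best model (which gets p = 1).
#'
#' @param aicc_values numeric vector (optionally named) of AICc values.
#' @return vector of relative likelihoods in (0, 1].
#' @export
relative_likelihood <- function(aicc_values) {
  if (length(aicc_values) == 0) stop("at least one AICc value is required")
  exp((min(aicc_values) - aicc_values) / 2)
}

#' Model comparison for one voxel
#'
#' Computes each model's mean squared residual on a common measurement
#' set (all measurements with `b <= b_max`, so that `n` is identical
#' across models even for the b-capped kurtosis fit), then AICc and
#' relative likelihood.
#'
#' @param voxel_fits named list of `fit_result`s (one per model).
#' @param signals the voxel's measurements.
#' @param scheme an [acq_scheme()].
#' @param b_max common b-value ceiling.
#' @return data frame: model, n, P, mse, rmse, aicc, delta_aicc,
#'   rel_likelihood; exactly one row has `delta_aicc == 0`.
#' @export
select_voxel <- function(voxel_fits, signals, scheme, b_max) {
  sub <- subset_scheme(scheme, b_max)
  sig <- signals[sub$keep]
  rows <- lapply(names(voxel_fits), function(m) {
    f <- voxel_fits[[m]]
    if (isTRUE(f$skipped)) return(NULL)
    P <- MODEL_REGISTRY[[m]]$p_fit
    if (length(sig) <= P + 1)
      return(data.frame(model = m, n = length(sig), P = P, mse = NA_real_,
                        rmse = NA_real_, aicc = NA_real_))
    res <- sig - predict_signal(f, sub)
    mse <- mean(res^2)
    data.frame(model = m, n = length(sig), P = P, mse = mse,
               rmse = sqrt(mse), aicc = aicc(length(sig), P, mse))
  })
  out <- do.call(rbind, rows)
  ok <- !is.na(out$aicc)
  out$delta_aicc <- out$aicc - min(out$aicc[ok])
  out$rel_likelihood <- NA_real_
  out$rel_likelihood[ok] <- relative_likelihood(out$aicc[ok])
  out
}

#' Best model per voxel
#'
#' Integer-coded map of the model with the lowest AICc per voxel. Ties
#' are broken toward the model with fewer parameters, then
#' lexicographically by model identifier.
#'
#' @param selections list of per-voxel selection tables (from
#'   [select_voxel()]).
#' @return list with `code` (integer vector, index into `legend`) and
#'   `legend` (model identifiers, sorted).
#' @export
best_model_map <- function(selections) {
  legend <- sort(unique(unlist(lapply(selections, function(s) s$model))))
  code <- vapply(selections, function(s) {
    s <- s[!is.na(s$aicc), ]
    if (nrow(s) == 0) return(NA_integer_)
    best <- s[order(s$aicc, s$P, s$model), ][1, "model"]
    match(best, legend)
  }, integer(1))
  list(code = code, legend = legend)
}

#' Maximum-b-value sweep of model performance
#'
#' For each ceiling in `b_max_grid`, refits every requested model to
#' every masked voxel using only measurements with `b <=` the ceiling
#' (the kurtosis model additionally capped at `dk_b_cap`), computes each
#' model's residuals on the common measurement subset, and averages RMSE
#' and relative likelihood over voxels. Each ceiling is fit from scratch
#' (no warm start), so the sweep is deterministic.
#'
#' @inheritParams fit_volume
#' @param b_max_grid numeric vector of b-value ceilings, s/mm^2.
#' @return tidy data frame: `b_max`, `model`, `mean_rmse`,
#'   `mean_rel_likelihood`, `n`, `n_voxels`, `valid` (FALSE where
#'   `n <= P + 1` left the cell undefined).
#' @export
bmax_sweep <- function(volume, mask = NULL, scheme,
                       models = c("dt", "beta"),
                       b_max_grid = seq(1200, 10000, by = 400),
                       config = fit_config()) {
  if (any(b_max_grid > max(scheme$b)))
    stop("b_max_grid extends beyond the scheme's largest b-value")
  out <- list()
  for (bm in b_max_grid) {
    cfg <- config
    cfg$b_max <- bm
    fits <- fit_volume(volume, mask, scheme, models, cfg)
    sig_mat <- as_signal_matrix(volume, fits$voxels)
    sel <- lapply(seq_len(fits$n_voxels), function(j)
      select_voxel(lapply(fits$fits, `[[`, j), sig_mat[j, ], scheme, bm))
    sel_all <- do.call(rbind, sel)
    agg <- do.call(rbind, lapply(models, function(m) {
      sm <- sel_all[sel_all$model == m, ]
      data.frame(b_max = bm, model = m,
                 mean_rmse = mean(sm$rmse),
                 mean_rel_likelihood = mean(sm$rel_likelihood),
                 n = sm$n[1], n_voxels = nrow(sm),
                 valid = !anyNA(sm$aicc))
    }))
    out[[length(out) + 1L]] <- agg
  }
  do.call(rbind, out)
}

as_signal_matrix <- function(volume, voxels) {
  if (length(dim(volume)) == 4L) {
    d <- dim(volume)
    matrix(volume, prod(d[1:3]), d[4])[voxels, , drop = FALSE]
  } else as.matrix(volume)[voxels, , drop = FALSE]
}
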