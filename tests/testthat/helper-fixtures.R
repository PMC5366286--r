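# Shared fixtures, built in code.

# small cached schemes (building the 514-point grid takes a moment)
scheme_257 <- make_scheme(257)
scheme_514 <- make_scheme(514, style = "grid_full")

# parameter sets spanning the per-axis ranges reported for healthy, sham
# and hypertrophic myocardium (mean diffusivity 0.87-1.40e-3 mm^2/s,
# kurtosis 0.11-0.67)
table2_like_params <- function() {
  list(
    monoexp = list(list(D = 1e-3), list(D = 1.4e-3)),
    dk = list(list(D = 1e-3, K = 0.45), list(D = 1.37e-3, K = 0.11),
              list(D = 0.87e-3, K = 0.67)),
    biexp = list(list(v = 0.86, Dfast = 1.51e-3, Dslow = 0.48e-3),
                 list(v = 0.82, Dfast = 1.02e-3, Dslow = 0.17e-3)),
    truncgauss = list(list(Dm = 1e-3, sigma = 3.9e-4),
                      list(Dm = 1.37e-3, sigma = 2.6e-4)),
    gamma = list(list(k = 6.67, theta = 1.5e-4),
                 list(k = 27.3, theta = 5e-5),
                 list(k = 4.5, theta = 1.9e-4)),
    beta = list(list(alpha = 1.32, beta = 0.57, Dmax = 1.43e-3),
                list(alpha = 2.0, beta = 1.1, Dmax = 1.5e-3),
                list(alpha = 0.54, beta = 0.031, Dmax = 1.45e-3))
  )
}

# noiseless factorised signals for a single voxel with a rotated frame
make_voxel_signal <- function(scheme, model_id, axis_params, S0 = 2.36e4,
                              angle = 40) {
  th <- angle * pi / 180
  V <- cbind(c(cos(th), sin(th), 0), c(-sin(th), cos(th), 0), c(0, 0, 1))
  B <- scheme$b * (scheme$dirs %*% V)^2
  f <- function(i) evaluate_signal(model_id, axis_params[[i]], B[, i])
  list(signal = S0 * f(1) * f(2) * f(3), V = V, S0 = S0)
}
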