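test_that("the initialisation cascade inverts kurtosis-model moments", {
  # gamma: k = 3/K, theta = mean/k
  ip <- cardiffusion:::init_from_moments("gamma", 1e-3, 0.5)
  expect_equal(ip$k, 6)
  expect_equal(ip$theta, 1e-3 / 6)
  # truncated Gaussian: location = mean, sigma^2 = mean^2 K / 3
  it <- cardiffusion:::init_from_moments("truncgauss", 1e-3, 0.3)
  expect_equal(it$Dm, 1e-3)
  expect_equal(it$sigma, 1e-3 * sqrt(0.1))
  # beta Dmax starts at the free-water diffusivity
  ib <- cardiffusion:::init_from_moments("beta", 1e-3, 0.45)
  expect_equal(ib$Dmax, 2.3e-3)
  mb <- derived_moments("beta", list(alpha = ib$alpha, beta = ib$beta,
                                     Dmax = ib$Dmax))
  expect_equal(mb$mean_diffusivity, 1e-3, tolerance = 1e-10)
  expect_equal(mb$kurtosis, 0.45, tolerance = 1e-10)
})

test_that("full initial vectors come from the cascade, clipped into bounds", {
  vx <- make_voxel_signal(scheme_514, "gamma",
                          list(list(k = 6, theta = 2e-4),
                               list(k = 6, theta = 1.6e-4),
                               list(k = 5, theta = 1.8e-4)))
  dt0 <- fit_dt_linear(vx$signal, scheme_514, 2000)
  cfg <- fit_config(b_max = 10000)
  ini_st <- initialize_params("stretched", vx$signal, scheme_514, dt0,
                              config = cfg)
  expect_equal(unname(ini_st[c("a1", "a2", "a3")]), rep(0.99, 3))
  expect_equal(unname(ini_st[c("Ds1", "Ds2", "Ds3")]),
               pmax(dt0$eigenvalues, 1e-6))
  ini_b <- initialize_params("beta", vx$signal, scheme_514, dt0,
                             config = cfg)
  expect_equal(unname(ini_b[["Dmax"]]), 2.3e-3)
  # a degenerate (non-positive) kurtosis falls back with a warning
  dkf <- list(S0 = 100, D = rep(1e-3, 3), K = c(-0.1, 0.2, 0.2))
  expect_warning(
    initialize_params("gamma", vx$signal, scheme_514, dt0, dk_fit = dkf,
                      config = cfg),
    "non-positive kurtosis")
})

test_that("noiseless voxels are recovered to high relative accuracy by every model", {
  cfg <- fit_config(b_max = 10000)
  cases <- list(
    gamma = list(list(k = 27, theta = 5.07e-5), list(k = 6.67, theta = 1.5e-4),
                 list(k = 5.36, theta = 1.72e-4)),
    truncgauss = list(list(Dm = 1.37e-3, sigma = 2.6e-4),
                      list(Dm = 1.0e-3, sigma = 3.9e-4),
                      list(Dm = 0.92e-3, sigma = 4.0e-4)),
    biexp = list(list(v = 0.86, Dfast = 1.52e-3, Dslow = 0.48e-3),
                 list(v = 0.86, Dfast = 1.13e-3, Dslow = 0.19e-3),
                 list(v = 0.86, Dfast = 1.04e-3, Dslow = 0.14e-3)),
    stretched = list(list(Ds = 1.3e-3, a = 0.95), list(Ds = 1.1e-3, a = 0.85),
                     list(Ds = 1.0e-3, a = 0.8)),
    dk = list(list(D = 1.37e-3, K = 0.11), list(D = 1.0e-3, K = 0.45),
              list(D = 0.92e-3, K = 0.56))
  )
  for (m in names(cases)) {
    vx <- make_voxel_signal(scheme_514, m, cases[[m]])
    f <- fit_voxel(m, vx$signal, scheme_514, cfg)
    expect_true(f$converged, info = m)
    spec <- model_spec(m)
    for (i in 1:3) {
      for (nm in spec$axis_params) {
        truth <- cases[[m]][[i]][[nm]]
        est <- f$par[[paste0(nm, i)]]
        expect_lt(abs(est - truth) / abs(truth), 1e-3,
                  label = paste(m, nm, i, "relative error"))
      }
    }
    for (nm in spec$global_params) {
      # biexp v is shared across axes in these cases
      truth <- cases[[m]][[1]][[nm]]
      if (!is.null(truth))
        expect_lt(abs(f$par[[nm]] - truth) / truth, 1e-3)
    }
    expect_lt(f$rmse / vx$S0, 1e-6)
  }
})

test_that("fitting a kurtosis model to monoexponential data returns K near zero", {
  vx <- make_voxel_signal(scheme_514, "monoexp",
                          list(list(D = 1.5e-3), list(D = 1.0e-3),
                               list(D = 0.5e-3)))
  f <- suppressWarnings(fit_voxel("dk", vx$signal, scheme_514,
                                  fit_config(b_max = 10000)))
  expect_lt(max(abs(cardiffusion:::axis_par(f$par, "K"))), 1e-3)
})

test_that("the fitted residual never exceeds the residual at initialisation", {
  set.seed(21)
  vx <- make_voxel_signal(scheme_514, "gamma",
                          list(list(k = 6, theta = 2e-4),
                               list(k = 6.7, theta = 1.5e-4),
                               list(k = 5.4, theta = 1.7e-4)))
  noisy <- vx$signal + rnorm(length(vx$signal), 0, 243)
  for (m in c("dt", "gamma", "beta", "biexp", "stretched")) {
    f <- suppressWarnings(fit_voxel(m, noisy, scheme_514,
                                    fit_config(b_max = 10000)))
    expect_lte(f$epsilon2, f$epsilon2_init, label = m)
  }
})

test_that("refitting from the fitted parameters is a fixed point", {
  set.seed(22)
  vx <- make_voxel_signal(scheme_514, "gamma",
                          list(list(k = 6, theta = 2e-4),
                               list(k = 6.7, theta = 1.5e-4),
                               list(k = 5.4, theta = 1.7e-4)))
  noisy <- vx$signal + rnorm(length(vx$signal), 0, 243)
  cfg <- fit_config(b_max = 10000)
  f1 <- fit_voxel("gamma", noisy, scheme_514, cfg)
  f2 <- fit_voxel("gamma", noisy, scheme_514, cfg, init = f1$par)
  expect_lt(max(abs(f2$par - f1$par) / pmax(abs(f1$par), 1e-12)), 1e-6)
})

test_that("volume fitting is deterministic, handles empty masks and validates shapes", {
  vx <- make_voxel_signal(scheme_257, "gamma",
                          list(list(k = 6, theta = 2e-4),
                               list(k = 6.7, theta = 1.5e-4),
                               list(k = 5.4, theta = 1.7e-4)))
  sig <- rbind(vx$signal, vx$signal, 0 * vx$signal)
  cfg <- fit_config(b_max = 10000, seed = 99)
  fits <- suppressWarnings(fit_volume(sig, NULL, scheme_257,
                                      c("dt", "gamma"), cfg))
  expect_equal(fits$n_voxels, 3L)
  # identical voxels give identical results
  expect_equal(fits$fits$gamma[[1]]$par, fits$fits$gamma[[2]]$par)
  # all-zero voxel is skipped, not fatal
  expect_true(fits$fits$gamma[[3]]$skipped)
  # empty mask: empty output, no error
  empty <- suppressWarnings(fit_volume(sig, rep(FALSE, 3), scheme_257,
                                       "dt", cfg))
  expect_equal(empty$n_voxels, 0L)
  # shape mismatches are named
  expect_error(fit_volume(sig[, 1:10], NULL, scheme_257, "dt", cfg),
               "10 columns")
  arr <- array(1, c(2, 2, 1, 5))
  expect_error(fit_volume(arr, NULL, scheme_257, "dt", cfg),
               "5 measurements")
  expect_error(fit_volume(array(1, c(2, 2, 1, length(scheme_257$b))),
                          array(TRUE, c(3, 3, 1)), scheme_257, "dt", cfg),
               "mask dimensions")
  expect_error(fit_voxel("gamma", vx$signal[1:20], scheme_257, cfg),
               "does not match")
})

test_that("axis relabelling against the frame is a symmetry of the forward model", {
  vx <- make_voxel_signal(scheme_257, "gamma",
                          list(list(k = 6, theta = 2e-4),
                               list(k = 8, theta = 1.2e-4),
                               list(k = 5, theta = 1.7e-4)))
  fits <- suppressWarnings(fit_volume(matrix(vx$signal, 1), NULL,
                                      scheme_257, "gamma",
                                      fit_config(b_max = 10000)))
  f0 <- fits$fits$gamma[[1]]
  # a radial reference aligned with the fitted SECOND eigenvector forces
  # a 2<->3 swap
  rad <- matrix(f0$eigenvectors[, 2], 1)
  sw <- relabel_axes_by_frame(fits, rad)
  f1 <- sw$fits$gamma[[1]]
  expect_equal(f1$par[["k2"]], f0$par[["k3"]])
  expect_equal(f1$par[["k3"]], f0$par[["k2"]])
  expect_equal(f1$eigenvalues[2:3], f0$eigenvalues[3:2])
  # predictions (and hence residuals) are unchanged by the relabelling
  expect_equal(predict_signal(f1, scheme_257),
               predict_signal(f0, scheme_257), tolerance = 1e-12)
  # a reference aligned with the third eigenvector changes nothing
  keep <- relabel_axes_by_frame(fits, matrix(f0$eigenvectors[, 3], 1))
  expect_equal(keep$fits$gamma[[1]]$par, f0$par)
})

test_that("frozen-frame fitting reproduces aligned-frame parameters", {
  cfg <- fit_config(b_max = 10000, fit_frame = "frozen")
  vx <- make_voxel_signal(scheme_514, "gamma",
                          list(list(k = 6, theta = 2e-4),
                               list(k = 6.7, theta = 1.5e-4),
                               list(k = 5.4, theta = 1.7e-4)))
  f <- fit_voxel("gamma", vx$signal, scheme_514, cfg)
  expect_equal(f$frame_mode, "frozen")
  expect_lt(abs(f$par[["k1"]] - 6) / 6, 1e-3)
  expect_lt(abs(f$par[["theta3"]] - 1.7e-4) / 1.7e-4, 1e-3)
})
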