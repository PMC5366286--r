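test_that("all closed-form signals are 1 at b = 0 and reject negative b", {
  for (m in names(table2_like_params())) {
    for (p in table2_like_params()[[m]]) {
      expect_identical(evaluate_signal(m, p, 0), 1, info = m)
      expect_error(evaluate_signal(m, p, -10), "negative b")
    }
  }
  expect_identical(evaluate_signal("stretched", list(Ds = 1e-3, a = 0.8), 0), 1)
})

test_that("closed forms agree with quadrature of their PDFs (Laplace-transform oracle)", {
  b <- c(0, 500, 2000, 5000, 10000)
  for (m in c("truncgauss", "gamma", "beta")) {
    for (p in table2_like_params()[[m]]) {
      s_closed <- evaluate_signal(m, p, b)
      s_quad <- signal_from_pdf_numeric(evaluate_pdf(m, p), b)
      expect_lt(max(abs(s_closed - s_quad) / s_quad), 1e-6)
    }
  }
  # kurtosis model: Gaussian PDF over the full real line
  for (p in table2_like_params()$dk) {
    sd <- p$D * sqrt(p$K / 3)
    s_quad <- vapply(b, function(bb)
      integrate(function(D) exp(dnorm(D, p$D, sd, log = TRUE) - bb * D),
                p$D - 15 * sd, p$D + 15 * sd,
                rel.tol = 1e-12)$value, numeric(1))
    expect_lt(max(abs(evaluate_signal("dk", p, b) - s_quad) / s_quad), 1e-6)
  }
  # point-mass models are summed exactly
  for (p in table2_like_params()$biexp) {
    expect_equal(signal_from_pdf_numeric(evaluate_pdf("biexp", p), b),
                 evaluate_signal("biexp", p, b), tolerance = 1e-12)
  }
})

test_that("degenerate and limiting parameterisations reduce to the monoexponential", {
  b <- seq(0, 10000, by = 250)
  mono <- evaluate_signal("monoexp", list(D = 1e-3), b)
  expect_equal(evaluate_signal("biexp",
                               list(v = 1, Dfast = 1e-3, Dslow = 0.5e-3), b),
               mono, tolerance = 1e-12)
  expect_equal(evaluate_signal("biexp",
                               list(v = 0, Dfast = 2e-3, Dslow = 1e-3), b),
               mono, tolerance = 1e-12)
  expect_equal(evaluate_signal("dk", list(D = 1e-3, K = 0), b), mono,
               tolerance = 1e-12)
  expect_equal(evaluate_signal("stretched", list(Ds = 1e-3, a = 1), b), mono,
               tolerance = 1e-12)
  expect_lt(max(abs(evaluate_signal("truncgauss",
                                    list(Dm = 1e-3, sigma = 1e-9), b) - mono)),
            1e-6)
  # gamma with k -> infinity at fixed k*theta
  gam <- evaluate_signal("gamma", list(k = 1e7, theta = 1e-10), b)
  expect_lt(max(abs(gam - mono) / mono), 1e-3)
})

test_that("signals decrease monotonically in b except the kurtosis model beyond its minimum", {
  b <- seq(0, 10000, by = 50)
  for (m in c("monoexp", "biexp", "truncgauss", "gamma", "beta")) {
    for (p in table2_like_params()[[m]]) {
      expect_true(all(diff(evaluate_signal(m, p, b)) < 0), info = m)
    }
  }
  p <- list(D = 1e-3, K = 1)
  s <- evaluate_signal("dk", p, b)
  b_min <- 3 / (p$D * p$K)
  expect_true(all(diff(s[b < b_min]) < 0))
  expect_true(all(diff(s[b > b_min]) > 0))
})

test_that("parameter bound violations are rejected with the bound named", {
  expect_error(evaluate_signal("gamma", list(k = -1, theta = 1e-4), 100),
               "'k'.*> 0")
  expect_error(evaluate_signal("biexp",
                               list(v = 1.2, Dfast = 1e-3, Dslow = 1e-4), 100),
               "'v'.*\\[0, 1\\]")
  expect_error(evaluate_signal("biexp",
                               list(v = 0.5, Dfast = 1e-4, Dslow = 1e-3), 100),
               "Dfast")
  expect_error(evaluate_signal("stretched", list(Ds = 1e-3, a = 1.4), 100),
               "'a'")
  expect_error(evaluate_signal("monoexp", list(D = -1e-3), 100), "'D'")
})

test_that("analytic moments match numeric quadrature moments", {
  for (m in c("dk", "truncgauss", "gamma", "beta")) {
    for (p in table2_like_params()[[m]]) {
      am <- derived_moments(m, p)
      qm <- cardiffusion:::quadrature_moments(m, p)
      expect_lt(abs(am$mean_diffusivity - qm$mean_diffusivity) /
                  qm$mean_diffusivity, 1e-6)
      expect_lt(abs(am$kurtosis - qm$kurtosis) / qm$kurtosis, 1e-6)
      if (m %in% c("gamma", "beta"))
        expect_lt(abs(am$skewness - qm$skewness) / abs(qm$skewness), 1e-6)
    }
  }
})

test_that("biexponential moments reproduce the worked mixture example", {
  m <- derived_moments("biexp", list(v = 0.9, Dfast = 1.5e-3,
                                     Dslow = 0.5e-3))
  expect_equal(m$mean_diffusivity, 1.4e-3, tolerance = 1e-12)
  expect_equal(m$kurtosis, 3 * 0.9 * 0.1 * (1e-3)^2 / (1.4e-3)^2,
               tolerance = 1e-12)
  expect_equal(round(m$kurtosis, 3), 0.138)
})

test_that("closed-form moment identities hold (gamma 3/k, 2/sqrt(k); beta analytic)", {
  expect_equal(derived_moments("gamma", list(k = 3, theta = 1e-4))$kurtosis, 1)
  expect_equal(derived_moments("gamma", list(k = 4, theta = 1e-4))$skewness, 1)
  m <- derived_moments("beta", list(alpha = 2, beta = 2, Dmax = 2e-3))
  expect_equal(m$mean_diffusivity, 1e-3)
  expect_equal(m$kurtosis, 3 * 2 / (2 * 5))
  expect_equal(m$skewness, 0)
})

test_that("the stretched exponential refuses PDF and moment queries", {
  expect_error(derived_moments("stretched", list(Ds = 1e-3, a = 0.8)),
               "mean diffusivity.*kurtosis")
  expect_error(evaluate_pdf("stretched", list(Ds = 1e-3, a = 0.8)),
               "no analytic diffusivity PDF")
})

test_that("PDF objects are valid densities", {
  # truncated Gaussian with negligible truncated mass equals the
  # untruncated Gaussian and integrates to 1
  p <- list(Dm = 1e-3, sigma = 1e-4)
  grid <- seq(0, 2e-3, length.out = 400)
  pdf <- evaluate_pdf("truncgauss", p, grid)
  expect_lt(max(abs(pdf$density - dnorm(grid, p$Dm, p$sigma))), 1e-4)
  mass <- integrate(pdf$density_fun, 0, 3e-3, rel.tol = 1e-10)$value
  expect_lt(abs(mass - 1), 1e-6)
  # symmetric beta density is symmetric about Dmax/2
  pb <- evaluate_pdf("beta", list(alpha = 2.5, beta = 2.5, Dmax = 2e-3),
                     seq(1e-5, 2e-3 - 1e-5, length.out = 101))
  expect_equal(pb$density, rev(pb$density), tolerance = 1e-10)
  # gamma mode at (k-1)*theta
  pg <- evaluate_pdf("gamma", list(k = 2, theta = 0.5e-3))
  expect_equal(optimize(pg$density_fun, c(0, 5e-3), maximum = TRUE,
                        tol = 1e-10)$maximum, 0.5e-3, tolerance = 1e-4)
  # grids below zero are rejected (except for the untruncated dk Gaussian)
  expect_error(evaluate_pdf("gamma", list(k = 2, theta = 1e-4),
                            c(-1e-4, 1e-4)), "below 0")
  expect_silent(evaluate_pdf("dk", list(D = 1e-3, K = 0.5),
                             c(-1e-4, 1e-4)))
})

test_that("gridded densities must be normalised for quadrature", {
  p <- list(k = 6, theta = 1.5e-4)
  grid <- seq(1e-7, 5e-3, length.out = 3000)
  pdf <- evaluate_pdf("gamma", p, grid)
  s <- signal_from_pdf_numeric(pdf, c(500, 2000), use_grid = TRUE)
  expect_lt(max(abs(s - evaluate_signal("gamma", p, c(500, 2000)))), 1e-5)
  bad <- pdf
  bad$density <- bad$density * 1.5
  expect_error(signal_from_pdf_numeric(bad, 500, use_grid = TRUE),
               "not normalised")
})

test_that("Kummer function matches its defining series and handles errors", {
  # direct alternating defining series (enough terms that truncation is
  # negligible; cancellation limits attainable accuracy at larger |z|)
  direct <- function(a, c, z, n = 400) {
    term <- 1; s <- 1
    for (k in 0:(n - 1)) {
      term <- term * (a + k) / (c + k) * z / (k + 1)
      s <- s + term
    }
    s
  }
  for (z in c(-0.5, -2, -7, -19)) {
    expect_equal(kummer_m(1.3, 1.87, z), direct(1.3, 1.87, z),
                 tolerance = 1e-7)
  }
  expect_equal(kummer_m(2, 5, 0), 1)
  expect_error(kummer_m(2, 5, 1), "z <= 0")
  expect_error(kummer_m(-1, 5, -1), "c > a > 0")
})
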