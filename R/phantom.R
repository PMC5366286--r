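## Synthetic phantom generation: ground-truth parameter fields with the
## statistical structure of ex-vivo rat heart acquisitions, for validating
## the fitting and model-selection pipeline.

#' Synthetic Cartesian-grid acquisition scheme
#'
#' Emulates a diffusion spectrum imaging acquisition with q-space sampled
#' on a 3-D Cartesian lattice: the half-ball of lattice radius 5 holds
#' exactly 257 q-space points and the full symmetric ball exactly 514,
#' the two direction counts used by the emulated protocols. b-values
#' scale with \eqn{|q|^2} up to `b_max`. A uniform-shells style
#' (Fibonacci-sphere directions on equally spaced b shells) is provided
#' for testing. The measurement order is pseudo-randomised over b
#' (deterministically, by golden-ratio hashing) so consecutive
#' measurements have widely different b-values.
#'
#' @param n_directions requested number of DW directions; for the grid
#'   styles the nearest achievable lattice count is used (with a warning
#'   if it differs).
#' @param b_max largest b-value, s/mm^2.
#' @param n_non_dw number of b = 0 measurements (default 4).
#' @param delta,Delta gradient duration and diffusion time, s (defaults
#'   5 and 9 ms).
#' @param style `"grid_half"` (half q-space), `"grid_full"` (symmetric
#'   q-space) or `"shells"`.
#' @return an [acq_scheme()].
#' @examples
#' length(make_scheme(257)) # 261 measurements
#' @export
make_scheme <- function(n_directions = 257, b_max = 10000, n_non_dw = 4,
                        delta = 5e-3, Delta = 9e-3,
                        style = c("grid_half", "grid_full", "shells")) {
  style <- match.arg(style)
  stopifnot(n_directions >= 6, b_max > 0)
  if (style == "shells") {
    n_shell <- 8L
    per <- ceiling(n_directions / n_shell)
    bs <- seq(b_max / n_shell, b_max, length.out = n_shell)
    dirs <- do.call(rbind, lapply(seq_len(n_shell), function(s)
      fibonacci_sphere(per, offset = s)))
    dirs <- dirs[seq_len(n_directions), , drop = FALSE]
    b <- rep(bs, each = per)[seq_len(n_directions)]
  } else {
    half <- style == "grid_half"
    r <- best_grid_radius(n_directions, half)
    q <- lattice_points(r, half)
    got <- nrow(q)
    if (got != n_directions)
      warning("grid style cannot realise ", n_directions,
              " directions; using nearest achievable count ", got)
    q2 <- rowSums(q^2)
    b <- b_max * q2 / max(q2)
    dirs <- normalize_rows(q)
  }
  ord <- order((rank(b, ties.method = "first") * (sqrt(5) - 1) / 2) %% 1)
  b <- b[ord]; dirs <- dirs[ord, , drop = FALSE]
  b <- c(rep(0, n_non_dw), b)
  dirs <- rbind(matrix(0, n_non_dw, 3), dirs)
  acq_scheme(b, dirs, delta = delta, Delta = Delta)
}

lattice_points <- function(r, half) {
  rr <- ceiling(r)
  g <- as.matrix(expand.grid(x = -rr:rr, y = -rr:rr, z = -rr:rr))
  q2 <- rowSums(g^2)
  g <- g[q2 <= r^2 & q2 > 0, , drop = FALSE]
  if (half)
    g <- g[g[, 3] > 0 | (g[, 3] == 0 & g[, 2] > 0) |
             (g[, 3] == 0 & g[, 2] == 0 & g[, 1] > 0), , drop = FALSE]
  g
}

best_grid_radius <- function(n, half) {
  radii <- seq(1.5, 12, by = 0.02)
  counts <- vapply(radii, function(r) nrow(lattice_points(r, half)),
                   integer(1))
  radii[which.min(abs(counts - n))]
}

fibonacci_sphere <- function(n, offset = 0) {
  i <- seq_len(n) - 0.5 + offset * 0.1
  z <- 1 - 2 * i / n
  phi <- pi * (1 + sqrt(5)) * i
  r <- sqrt(pmax(1 - z^2, 0))
  cbind(r * cos(phi), r * sin(phi), z)
}

# ---- group-level generating parameters ---------------------------------

# Per-group biexponential and beta-model summary parameters (mean and SD
# across hearts) of the emulated healthy / sham / TAC ex-vivo cohorts,
# plus signal and noise levels. Diffusivities in 1e-3 mm^2/s here;
# converted to mm^2/s on draw.
group_param_table <- function() {
  list(
    healthy = list(
      n_hearts = 5,
      Dfast = rbind(mean = c(1.51, 1.14, 1.04), sd = c(0.03, 0.07, 0.06)),
      Dslow = rbind(mean = c(0.48, 0.21, 0.16), sd = c(0.04, 0.01, 0.01)),
      v = c(mean = 0.86, sd = 0.004),
      kurtosis = rbind(mean = c(0.13, 0.45, 0.55), sd = c(0.02, 0.04, 0.03)),
      skewness = rbind(mean = c(-3.17, -0.85, -0.57),
                       sd = c(0.35, 0.15, 0.11)),
      Dmax = c(mean = 1.46, sd = 0.04)),
    sham = list(
      n_hearts = 4,
      Dfast = rbind(mean = c(1.52, 1.13, 1.04), sd = c(0.09, 0.06, 0.05)),
      Dslow = rbind(mean = c(0.48, 0.19, 0.14), sd = c(0.06, 0.01, 0.004)),
      v = c(mean = 0.86, sd = 0.01),
      kurtosis = rbind(mean = c(0.11, 0.45, 0.56), sd = c(0.02, 0.04, 0.04)),
      skewness = rbind(mean = c(-3.85, -0.91, -0.67),
                       sd = c(0.54, 0.04, 0.05)),
      Dmax = c(mean = 1.43, sd = 0.09)),
    tac = list(
      n_hearts = 4,
      Dfast = rbind(mean = c(1.59, 1.08, 1.02), sd = c(0.12, 0.08, 0.08)),
      Dslow = rbind(mean = c(0.55, 0.19, 0.17), sd = c(0.01, 0.01, 0.01)),
      v = c(mean = 0.82, sd = 0.01),
      kurtosis = rbind(mean = c(0.14, 0.59, 0.67), sd = c(0.04, 0.03, 0.03)),
      skewness = rbind(mean = c(-3.03, -0.49, -0.37),
                       sd = c(0.59, 0.05, 0.04)),
      Dmax = c(mean = 1.50, sd = 0.13))
  )
}

#' Phantom specification
#'
#' Describes a group of synthetic "hearts": an annular short-axis wall
#' with a linear transmural helix ramp, voxelwise generating model, and
#' the group-level distribution parameters (drawn per heart as
#' mean +/- SD). Defaults emulate the imaging conditions of the ex-vivo
#' cohorts: mean non-DW signal 2.36e4, per-channel noise SD 243 (SNR of
#' about 97), 20 x 20 x 5 voxel grid with an annular wall and regions of
#' interest of about 247 voxels.
#'
#' @param group `"healthy"`, `"sham"` or `"tac"`.
#' @param n_hearts number of hearts; default = the emulated cohort size.
#' @param generating_model `"beta"` (default, the best-fitting model at
#'   full b-range), `"gaussian"` (pure tensor), `"biexp"`, `"gamma"`, or
#'   `"two_pop"` (tissue + free-compartment partial-volume analogue).
#' @param grid_dim 3-D grid dimensions.
#' @param r_outer,r_inner wall radii in voxels.
#' @param helix_range transmural helix-angle ramp endpoints, degrees
#'   (epicardium to endocardium).
#' @param s0_mean,s0_sd non-DW signal level across hearts.
#' @param noise_sd per-channel complex noise SD.
#' @param roi_n target region-of-interest voxel count (wall voxels away
#'   from the boundary; capped at the available count).
#' @param gel_fraction free-compartment volume fraction for
#'   `"two_pop"`.
#' @return a `phantom_spec` list.
#' @export
phantom_spec <- function(group = c("healthy", "sham", "tac"),
                         n_hearts = NULL,
                         generating_model = c("beta", "gaussian", "biexp",
                                              "gamma", "two_pop"),
                         grid_dim = c(20, 20, 5),
                         r_outer = 9, r_inner = 5,
                         helix_range = c(-60, 60),
                         s0_mean = 2.36e4, s0_sd = 0.19e4,
                         noise_sd = 243, roi_n = 247,
                         gel_fraction = 0.5) {
  group <- match.arg(group)
  generating_model <- match.arg(generating_model)
  tab <- group_param_table()[[group]]
  if (is.null(n_hearts)) n_hearts <- tab$n_hearts
  stopifnot(noise_sd > 0, s0_mean > 0, r_inner < r_outer, roi_n > 0)
  structure(list(group = group, n_hearts = n_hearts,
                 generating_model = generating_model, grid_dim = grid_dim,
                 r_outer = r_outer, r_inner = r_inner,
                 helix_range = helix_range, s0_mean = s0_mean,
                 s0_sd = s0_sd, noise_sd = noise_sd, roi_n = roi_n,
                 gel_fraction = gel_fraction, params = tab),
            class = "phantom_spec")
}

# ---- beta-parameter moment matching ------------------------------------

# (alpha, beta) reproducing a target (mean, kurtosis) at fixed Dmax.
# Feasible iff Dmax > mean * (3 + K) / 3.
beta_from_mean_kurtosis <- function(mean_d, K, Dmax) {
  m <- mean_d / Dmax
  alpha <- 3 * (1 - m) / K - m
  if (alpha <= 0) return(NULL)
  list(alpha = alpha, beta = alpha * (1 - m) / m)
}

beta_skewness <- function(a, b) {
  2 * (b - a) * sqrt(a + b + 1) / ((a + b + 2) * sqrt(a * b))
}

#' Beta-model parameters from moment targets
#'
#' Solves for per-axis `(alpha, beta)` and a shared `Dmax` reproducing
#' target per-axis mean diffusivity and kurtosis exactly, with `Dmax`
#' chosen to match the skewness targets as closely as possible (three
#' moments per axis generally cannot all be matched by a two-shape
#' family with a single shared `Dmax`; the residual skewness mismatch is
#' returned). An error names the violated moment inequality if no
#' feasible `Dmax` exists.
#'
#' @param mean_d length-3 per-axis mean diffusivities, mm^2/s.
#' @param kurtosis length-3 per-axis kurtosis targets.
#' @param skewness length-3 per-axis skewness targets (or `NULL` to pin
#'   `Dmax` at `Dmax_fixed`).
#' @param Dmax_fixed optional fixed `Dmax`, mm^2/s.
#' @return list: `alpha`, `beta` (length 3), `Dmax`, `skewness_achieved`,
#'   `skewness_residual`.
#' @export
solve_beta_params <- function(mean_d, kurtosis, skewness = NULL,
                              Dmax_fixed = NULL) {
  stopifnot(length(mean_d) == 3, length(kurtosis) == 3)
  d_lo <- max(mean_d * (3 + kurtosis) / 3) * (1 + 1e-9)
  if (d_lo >= 5e-3)
    stop("infeasible moment targets: required Dmax ", signif(d_lo, 4),
         " exceeds the physical ceiling 5e-3 mm^2/s (kurtosis too large ",
         "for the mean)")
  solve_at <- function(Dmax) lapply(1:3, function(i)
    beta_from_mean_kurtosis(mean_d[i], kurtosis[i], Dmax))
  obj <- function(Dmax) {
    ab <- solve_at(Dmax)
    sum(vapply(1:3, function(i)
      (beta_skewness(ab[[i]]$alpha, ab[[i]]$beta) - skewness[i])^2,
      numeric(1)))
  }
  Dmax <- if (!is.null(Dmax_fixed)) {
    if (Dmax_fixed <= d_lo)
      stop("infeasible moment targets at fixed Dmax = ", Dmax_fixed,
           ": kurtosis requires Dmax > mean*(3+K)/3 = ", signif(d_lo, 4))
    Dmax_fixed
  } else if (is.null(skewness)) {
    stop("supply either skewness targets or Dmax_fixed")
  } else {
    stats::optimize(obj, c(d_lo, 5e-3), tol = 1e-10)$minimum
  }
  ab <- solve_at(Dmax)
  a <- vapply(ab, `[[`, numeric(1), "alpha")
  b <- vapply(ab, `[[`, numeric(1), "beta")
  sk <- beta_skewness(a, b)
  list(alpha = a, beta = b, Dmax = Dmax, skewness_achieved = sk,
       skewness_residual = if (is.null(skewness)) NULL else sk - skewness)
}

# ---- phantom construction ----------------------------------------------

#' Generate a ground-truth phantom
#'
#' Draws per-heart parameters from the group-level mean +/- SD (seeded),
#' solves the generating-model parameters from the moment targets, and
#' builds the annular wall geometry with its local frame, transmural
#' helix ramp and region of interest (wall voxels away from the wall
#' boundary and edge slices, subsampled to the target count). The
#' per-axis mean-diffusivity targets derive from the biexponential
#' summary parameters (\eqn{\bar D = v D_{fast} + (1-v) D_{slow}}).
#'
#' @param spec a [phantom_spec()].
#' @param seed RNG seed; identical spec + seed gives identical output.
#' @return a `ground_truth` object: `spec`, `geometry` (wall/ROI masks,
#'   wall frame, per-voxel eigenvector arrays, helix field) and `hearts`
#'   (per-heart generating parameters, each with the analytic moments
#'   they reproduce).
#' @export
make_phantom <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "phantom_spec"))
  geom <- build_annulus_geometry(spec)
  tab <- spec$params
  hearts <- with_seed(seed, lapply(seq_len(spec$n_hearts), function(h) {
    draw <- function(ms) stats::rnorm(length(ms["mean", ]), ms["mean", ],
                                      ms["sd", ])
    Dfast <- draw(tab$Dfast) * 1e-3
    Dslow <- pmin(draw(tab$Dslow) * 1e-3, Dfast * 0.99)
    v <- min(max(stats::rnorm(1, tab$v["mean"], tab$v["sd"]), 0.5), 0.99)
    kurt <- pmax(draw(tab$kurtosis), 0.02)
    skew <- draw(tab$skewness)
    mean_d <- v * Dfast + (1 - v) * Dslow
    S0 <- max(stats::rnorm(1, spec$s0_mean, spec$s0_sd), spec$s0_mean / 4)
    par <- switch(spec$generating_model,
      beta = solve_beta_params(mean_d, kurt, skew),
      gaussian = list(eigenvalues = mean_d),
      biexp = list(Dfast = Dfast, Dslow = Dslow, v = v),
      gamma = list(k = 3 / kurt, theta = mean_d * kurt / 3),
      two_pop = c(solve_beta_params(mean_d, kurt, skew),
                  list(D_free = 2.3e-3, f_free = spec$gel_fraction)))
    list(heart = h, model = spec$generating_model, params = par,
         targets = list(mean_d = mean_d, kurtosis = kurt, skewness = skew,
                        Dfast = Dfast, Dslow = Dslow, v = v),
         S0 = S0)
  }))
  structure(list(spec = spec, geometry = geom, hearts = hearts,
                 seed = seed),
            class = "ground_truth")
}

build_annulus_geometry <- function(spec) {
  d <- spec$grid_dim
  frame <- cylindrical_wall_frame(d)
  idx <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                               z = seq_len(d[3])))
  ctr <- (d[1:2] + 1) / 2
  r <- sqrt((idx[, 1] - ctr[1])^2 + (idx[, 2] - ctr[2])^2)
  wall <- r >= spec$r_inner & r <= spec$r_outer
  # transmural position 0 (epi) .. 1 (endo)
  tm <- pmin(pmax((spec$r_outer - r) / (spec$r_outer - spec$r_inner), 0), 1)
  helix <- spec$helix_range[1] + tm * diff(spec$helix_range)
  hr <- helix * pi / 180
  v1 <- cos(hr) * frame$circ + sin(hr) * frame$long
  v3 <- frame$radial
  v2 <- vec_cross(v3, v1)
  # ROI: interior wall voxels (one voxel off the wall boundary, inner
  # slices only), emulating tracing that avoids buffer/gel interfaces
  wall_mask <- array(wall, d)
  inner_slice <- if (d[3] > 2) idx[, 3] > 1 & idx[, 3] < d[3]
                 else rep(TRUE, nrow(idx))
  roi_idx <- integer(0)
  for (margin in c(1, 0.5, 0)) {   # relax for thin walls
    interior <- r >= spec$r_inner + margin & r <= spec$r_outer - margin &
      inner_slice
    roi_idx <- which(wall & interior)
    if (length(roi_idx) >= min(spec$roi_n, 4)) break
  }
  if (length(roi_idx) == 0) roi_idx <- which(wall)
  if (length(roi_idx) > spec$roi_n)
    roi_idx <- roi_idx[round(seq(1, length(roi_idx),
                                 length.out = spec$roi_n))]
  roi_mask <- array(FALSE, d); roi_mask[roi_idx] <- TRUE
  list(dim = d, wall_mask = wall_mask, roi_mask = roi_mask,
       frame = frame, v1 = v1, v2 = v2, v3 = v3, helix = helix,
       radius = r)
}

#' Simulate diffusion-weighted signals from a phantom
#'
#' Evaluates the factorised forward model \eqn{S_0 \prod_i f(b_i)}
#' voxelwise along the ground-truth eigenframe, then adds independent
#' complex Gaussian noise of the requested standard deviation to both
#' channels (after applying a smooth synthetic image phase). Voxels
#' outside the wall carry zero signal, providing a noise-only
#' background.
#'
#' @param gt a `ground_truth` from [make_phantom()].
#' @param scheme an [acq_scheme()].
#' @param heart which heart of the group to simulate.
#' @param noise_sd per-channel noise SD; default from the spec. Use 0
#'   for noiseless data.
#' @param seed RNG seed.
#' @param voxels `"wall"` evaluates the forward model over the whole
#'   wall (default); `"roi"` restricts it to the region of interest,
#'   leaving other wall voxels at zero signal — noise is simulated
#'   everywhere either way.
#' @return a `dwi_sim` object: `complex` (n_voxel x n_meas complex
#'   matrix including background voxels in column-major voxel order),
#'   `magnitude`, `real_corrected` is left to [phase_correct()],
#'   `noiseless`, `scheme`, masks and the true phase field.
#' @export
simulate_signals <- function(gt, scheme, heart = 1L,
                             noise_sd = gt$spec$noise_sd, seed = 1L,
                             voxels = c("wall", "roi")) {
  stopifnot(inherits(gt, "ground_truth"))
  voxels <- match.arg(voxels)
  if (noise_sd < 0) stop("noise SD must be non-negative")
  g <- gt$geometry
  h <- gt$hearts[[heart]]
  n_vox <- prod(g$dim)
  n_meas <- length(scheme$b)
  noiseless <- matrix(0, n_vox, n_meas)
  wall <- which(if (voxels == "wall") g$wall_mask else g$roi_mask)
  for (jv in wall) {
    V <- cbind(g$v1[jv, ], g$v2[jv, ], g$v3[jv, ])
    B <- scheme$b * (scheme$dirs %*% V)^2
    noiseless[jv, ] <- h$S0 * forward_axes(h$model, h$params, B)
  }
  d <- g$dim
  xy <- as.matrix(expand.grid(x = seq_len(d[1]), y = seq_len(d[2]),
                              z = seq_len(d[3])))
  phase <- 0.4 * xy[, 1] / d[1] + 0.25 * xy[, 2] / d[2]  # radians, smooth
  cplx <- with_seed(seed, {
    noisy <- noiseless * exp(1i * phase) +
      matrix(complex(real = stats::rnorm(n_vox * n_meas, 0, noise_sd),
                     imaginary = stats::rnorm(n_vox * n_meas, 0, noise_sd)),
             n_vox, n_meas)
    noisy
  })
  structure(list(complex = cplx, magnitude = Mod(cplx),
                 noiseless = noiseless, phase_true = phase,
                 scheme = scheme, dim = d, wall_mask = g$wall_mask,
                 roi_mask = g$roi_mask, heart = heart,
                 noise_sd = noise_sd),
            class = "dwi_sim")
}

# noiseless per-voxel attenuation product for each generating model
forward_axes <- function(model, par, B) {
  switch(model,
    beta = kummer_m(par$alpha[1], par$alpha[1] + par$beta[1],
                    -B[, 1] * par$Dmax) *
           kummer_m(par$alpha[2], par$alpha[2] + par$beta[2],
                    -B[, 2] * par$Dmax) *
           kummer_m(par$alpha[3], par$alpha[3] + par$beta[3],
                    -B[, 3] * par$Dmax),
    gaussian = exp(-(B %*% par$eigenvalues)),
    gamma = exp(-par$k[1] * log1p(B[, 1] * par$theta[1])) *
            exp(-par$k[2] * log1p(B[, 2] * par$theta[2])) *
            exp(-par$k[3] * log1p(B[, 3] * par$theta[3])),
    biexp = {
      fast <- exp(-(B %*% par$Dfast))
      slow <- exp(-(B %*% par$Dslow))
      par$v * fast + (1 - par$v) * slow
    },
    two_pop = {
      # non-Gaussian (beta-model) tissue plus a free compartment at the
      # diffusivity of gel/buffer
      tissue <- forward_axes("beta", par, B)
      free <- exp(-par$D_free * rowSums(B))
      (1 - par$f_free) * tissue + par$f_free * free
    })
}

#' Phase-corrected real-valued measurements of a simulation
#'
#' Convenience wrapper: applies [phase_correct()] using the simulated
#' non-DW measurements as the phase reference and returns the real-valued
#' signal matrix.
#'
#' @param sim a `dwi_sim`.
#' @return n_voxel x n_meas real matrix.
#' @export
corrected_signals <- function(sim) {
  non_dw <- sim$scheme$b == 0
  pc <- phase_correct(sim$complex[, non_dw, drop = FALSE],
                      sim$complex[, !non_dw, drop = FALSE])
  out <- matrix(0, nrow(sim$complex), ncol(sim$complex))
  out[, non_dw] <- pc$non_dw
  out[, !non_dw] <- pc$dw
  out
}
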