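test_that("ROI statistics summarise maps and handle degenerate input", {
  mask <- array(c(TRUE, TRUE, FALSE, TRUE), c(2, 2, 1))
  maps <- list(const = array(3, c(2, 2, 1)),
               mixed = array(c(1, NA, 2, 4), c(2, 2, 1)))
  st <- roi_stats(maps, mask)
  expect_equal(st$mean[st$parameter == "const"], 3)
  expect_equal(st$sd[st$parameter == "const"], 0)
  expect_equal(st$n[st$parameter == "mixed"], 2)
  expect_equal(st$n_excluded[st$parameter == "mixed"], 1)
  expect_error(roi_stats(maps, array(FALSE, c(2, 2, 1))), "empty")
})

test_that("an ROI of the emulated cohort size is processed without subsampling", {
  mask <- array(FALSE, c(10, 10, 3))
  mask[1:247] <- TRUE
  vals <- array(rnorm(300), c(10, 10, 3))
  st <- roi_stats(list(x = vals), mask)
  expect_equal(st$n, 247)
  expect_equal(st$mean, mean(vals[1:247]))
})

test_that("exact Mann-Whitney U matches enumeration and the reference implementation", {
  r <- mann_whitney_exact(1:4, 5:8)
  expect_equal(r$U, 0)
  expect_equal(r$p_two_tailed, 2 / 70)
  # identical groups
  expect_equal(mann_whitney_exact(c(1, 2, 3), c(1, 2, 3))$p_two_tailed, 1)
  # symmetry under group swap: p equal, U reflected
  a <- c(0.3, 1.2, 0.7, 2.2); b <- c(0.9, 1.5, 2.0)
  r1 <- mann_whitney_exact(a, b); r2 <- mann_whitney_exact(b, a)
  expect_equal(r1$p_two_tailed, r2$p_two_tailed)
  expect_equal(r1$U, length(a) * length(b) - r2$U)
  # full agreement with the reference exact test for all n1, n2 <= 8
  set.seed(51)
  for (n1 in 2:8) for (n2 in 2:8) {
    x <- rnorm(n1); y <- rnorm(n2)
    ours <- mann_whitney_exact(x, y)
    ref <- wilcox.test(x, y, exact = TRUE)
    expect_equal(ours$U, unname(ref$statistic))
    expect_equal(ours$p_two_tailed, ref$p.value, tolerance = 1e-12)
  }
  # ties fall back to the permutation-exact mid-rank distribution
  rt <- mann_whitney_exact(c(1, 2, 2, 3), c(2, 4, 5, 6))
  expect_true(rt$p_two_tailed > 0 && rt$p_two_tailed <= 1)
  expect_equal(rt$method, "exact enumeration")
  expect_error(mann_whitney_exact(1, 1:3), "at least 2")
  # large groups switch to the normal approximation, recorded
  big <- mann_whitney_exact(rnorm(13), rnorm(13))
  expect_equal(big$method, "normal approximation")
})

test_that("group comparison reports both percent-difference conventions and exact p", {
  df <- expand.grid(heart = 1:4, group = c("tac", "sham"),
                    parameter = c("k_v2", "k_v3"),
                    stringsAsFactors = FALSE)
  set.seed(52)
  df$value <- ifelse(df$group == "tac", 0.59, 0.45) + rnorm(16, 0, 0.01)
  gc <- group_compare(df, "tac", "sham")
  expect_equal(nrow(gc), 2L)
  expect_equal(gc$pct_diff_signed,
               (gc$mean_a - gc$mean_b) / gc$mean_b * 100)
  expect_true(all(gc$p == 2 / 70))     # complete separation
  expect_true(all(gc$significant))
  expect_true(all(gc$p_holm >= gc$p))
  # negative-valued parameters: signed and magnitude conventions differ
  df2 <- data.frame(heart = rep(1:4, 2),
                    group = rep(c("tac", "sham"), each = 4),
                    parameter = "skew",
                    value = c(-0.49, -0.50, -0.48, -0.51,
                              -0.91, -0.90, -0.93, -0.92))
  g2 <- group_compare(df2, "tac", "sham")
  expect_lt(g2$pct_diff_signed, 0)       # (-0.49 - -0.91)/-0.91 < 0
  expect_lt(g2$pct_diff_magnitude, 0)    # |tac| smaller than |sham|
  # equal groups, zero spread: 0% difference
  df3 <- data.frame(heart = rep(1:3, 2),
                    group = rep(c("a", "b"), each = 3),
                    parameter = "x", value = rep(2, 6))
  expect_equal(group_compare(df3, "a", "b")$pct_diff_signed, 0)
  # mismatched parameter sets are named
  df4 <- rbind(df, data.frame(heart = 1, group = "tac",
                              parameter = "extra", value = 1))
  expect_error(group_compare(df4, "tac", "sham"), "extra")
})

test_that("group-average PDF reconstruction yields normalised profiles", {
  avg <- data.frame(axis = c("v1", "v2"),
                    alpha = c(2.0, 1.3), beta = c(0.6, 0.6),
                    Dmax = c(1.5e-3, 1.45e-3))
  grid <- seq(1e-6, 1.5e-3 - 1e-6, length.out = 2000)
  pd <- reconstruct_pdfs(avg, "beta", grid)
  expect_equal(unique(pd$axis), c("v1", "v2"))
  v1 <- pd[pd$axis == "v1", ]
  mass <- sum(v1$density) * diff(grid[1:2])
  expect_lt(abs(mass - 1), 0.05)  # trapezoid on a singular density
  expect_error(reconstruct_pdfs(data.frame(axis = "v1", Ds = 1e-3,
                                           a = 0.8), "stretched"),
               "PDF")
})

test_that("the pipeline bundle is reproducible and schema-stable", {
  cfg <- pipeline_config(groups = c("tac", "sham"), models = c("dt", "beta"),
                         b_max_grid = 10000, n_hearts = 2, roi_n = 4,
                         grid_dim = c(12, 12, 3), seed = 77)
  out1 <- run_pipeline(cfg)
  out2 <- run_pipeline(cfg, out_dir = file.path(tempdir(), "bundle"))
  expect_identical(out1$sweep, out2$sweep)
  expect_identical(out1$comparison, out2$comparison)
  expect_equal(names(out1$sweep),
               c("group", "heart", "b_max", "model", "mean_rmse",
                 "mean_rel_likelihood", "n"))
  expect_true(all(c("sweep.tsv", "roi_summaries.tsv", "comparison.tsv",
                    "manifest.json") %in%
                    list.files(file.path(tempdir(), "bundle"))))
  man <- jsonlite::read_json(file.path(tempdir(), "bundle",
                                       "manifest.json"))
  expect_equal(man$seed, 77L)
  expect_error(pipeline_config(models = "nosuchmodel"), "unknown model")
})
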