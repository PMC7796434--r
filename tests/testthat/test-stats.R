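test_that("ICC is 1 for perfect agreement and NA for zero variance", {
  y <- cbind(c(1, 2, 3), c(1, 2, 3))
  expect_equal(icc_two_way_random(y), 1, tolerance = 1e-12)
  expect_true(is.na(icc_two_way_random(matrix(5, 4, 2))))
  expect_error(icc_two_way_random(matrix(1:2, 1, 2)), ">= 2")
})

test_that("ICC matches a two-way ANOVA mean-squares oracle to 1e-12", {
  set.seed(50)
  for (rep in 1:200) {
    y <- matrix(rnorm(20, 100, 1), 10, 2) + rnorm(10, 0, 3)
    n <- nrow(y); k <- ncol(y)
    df <- data.frame(v = as.vector(y), knee = factor(rep(seq_len(n), k)),
                     rpt = factor(rep(seq_len(k), each = n)))
    ms <- anova(stats::aov(v ~ knee + rpt, df))[["Mean Sq"]]
    oracle <- (ms[1] - ms[3]) /
      (ms[1] + (k - 1) * ms[3] + (k / n) * (ms[2] - ms[3]))
    expect_equal(icc_two_way_random(y), oracle, tolerance = 1e-12)
  }
})

test_that("ICC estimates converge to the variance-component ratio", {
  set.seed(51)
  n_rep <- 2000
  iccs <- replicate(n_rep, {
    knee <- rnorm(6, 0, 3)             # between-knee SD 3 (variance 9)
    icc_two_way_random(matrix(knee, 6, 2) + rnorm(12, 0, 1))
  })
  # the ICC(2,1) estimator is slightly biased down at 6 knees x 2 repeats
  expect_lt(abs(mean(iccs, na.rm = TRUE) - 0.9), 0.05)
})

test_that("ICC classification uses the published thresholds", {
  expect_identical(classify_icc(c(0.45, 0.5, 0.74, 0.75, 0.80, 0.89, 0.9, 0.95)),
                   c("poor", "moderate", "moderate", "good", "good", "good",
                     "excellent", "excellent"))
  expect_true(is.na(classify_icc(NA_real_)))
})

test_that("ICC and RMSSD scaling invariances hold", {
  set.seed(52)
  y <- matrix(rnorm(20, 100, 10), 10, 2)
  expect_equal(icc_two_way_random(y + 37), icc_two_way_random(y), tolerance = 1e-9)
  expect_equal(icc_two_way_random(y * 2.5), icc_two_way_random(y), tolerance = 1e-9)
  expect_equal(rmssd(y + 37), rmssd(y), tolerance = 1e-9)
  expect_equal(rmssd(y * 2.5), 2.5 * rmssd(y), tolerance = 1e-9)
})

test_that("RMSSD reproduces hand-computed values and is unbiased for sigma^2", {
  expect_equal(rmssd(matrix(c(5, 5), 1, 2)), 0)
  expect_equal(rmssd(matrix(c(100, 102), 1, 2)), sqrt(2), tolerance = 1e-12)
  set.seed(53)
  r2 <- replicate(2000, rmssd(matrix(rnorm(20, 200, 10), 10, 2))^2)
  expect_lt(abs(mean(r2) - 100) / 100, 0.05)
})

test_that("the signed-rank comparison handles degenerate and textbook cases", {
  v <- runif(20)
  cmp <- compare_settings(v, v)
  expect_equal(cmp$z, 0)
  expect_equal(cmp$p_adjusted, 1)
  expect_equal(cmp$effect_size, 0)
  # Bonferroni arithmetic: p = 0.01 with 3 comparisons -> 0.03
  set.seed(54)
  a <- rnorm(40); b <- a - 0.5
  cmp2 <- compare_settings(a, b)
  expect_equal(cmp2$p_adjusted, min(1, 3 * cmp2$p_raw), tolerance = 1e-12)
  # matches R's normal-approximation Wilcoxon (no continuity correction)
  wt <- stats::wilcox.test(a, b, paired = TRUE, exact = FALSE, correct = FALSE)
  expect_equal(cmp2$p_raw, wt$p.value, tolerance = 1e-9)
  expect_equal(cmp2$effect_size, abs(cmp2$z) / sqrt(40), tolerance = 1e-12)
})

test_that("exact signed-rank p equals exhaustive enumeration for n <= 12", {
  set.seed(55)
  for (n in c(6, 10, 12)) {
    a <- rnorm(n); b <- rnorm(n)
    cmp <- compare_settings(a, b, exact = TRUE)
    d <- a - b
    r <- rank(abs(d))
    W <- sum(r[d > 0]); mu <- n * (n + 1) / 4
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Ws <- signs %*% r
    p_bf <- mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
    expect_equal(cmp$p_raw, p_bf, tolerance = 1e-12)
  }
  # with ties (duplicated differences)
  a <- c(1, 2, 3, 4, 5, 6); b <- c(0, 1, 1, 2, 7, 8)
  d <- a - b; r <- rank(abs(d)); W <- sum(r[d > 0]); mu <- length(d) * 7 / 4
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), 6)))
  p_bf <- mean(abs(signs %*% r - mu) >= abs(W - mu) - 1e-9)
  expect_equal(compare_settings(a, b, exact = TRUE)$p_raw, p_bf,
               tolerance = 1e-12)
})

test_that("evaluate_settings summarizes settings and orders noise correctly", {
  ds <- make_repeated_dataset(1200, n_knees = 10, n_repeats = 2,
                              sigma_between = 30,
                              per_setting_sigmas = c(low = 4, mid = 7, high = 10),
                              seed = 56)
  ev <- evaluate_settings(ds$settings)
  med <- ev$summary$rmssd_median
  expect_true(med[1] < med[2] && med[2] < med[3])
  expect_true(all(ev$summary$icc_median > 0.8))
  expect_equal(nrow(ev$comparisons), 6L)
  expect_true(all(ev$comparisons$p_adjusted >=
                    pmin(1, ev$comparisons$p_raw * 3) - 1e-12))

  # identical settings: degenerate cells flagged, RMSSD 0, nothing significant
  const <- array(rep(c(100, 150, 200), 4 * 2), dim = c(3, 4, 2))
  same <- list(s1 = const, s2 = const)
  ev2 <- evaluate_settings(same)
  expect_true(all(ev2$per_cell$rmssd_s1 == 0))
  expect_true(all(is.na(ev2$per_cell$icc_s1)))
  expect_true(all(ev2$comparisons$p_adjusted == 1))
})

test_that("grid mismatches between settings are rejected", {
  ds <- make_repeated_dataset(100, seed = 57)
  other <- make_repeated_dataset(90, seed = 57)
  expect_error(evaluate_settings(list(a = ds$settings[[1]],
                                      b = other$settings[[1]])),
               "cell")
})

test_that("repeated_measures_from_maps stacks interior cells consistently", {
  cube <- cube_mesh(8)
  grid <- build_cell_grid(cube, 2)
  mk <- function(seed) {
    set.seed(seed)
    pts <- matrix(runif(240, 0.1, 7.9), ncol = 3)
    aggregate_bmd(bmd_point_cloud(pts, runif(80, 100, 300)), grid)
  }
  maps <- list(list(mk(1), mk(2)), list(mk(3), mk(4)))   # 2 knees x 2 repeats
  rm <- repeated_measures_from_maps(maps)
  expect_equal(rm$n_cells, sum(grid$interior_mask))
  expect_equal(rm$n_knees, 2L)
  expect_equal(rm$n_repeats, 2L)
  expect_equal(rm$values[, 2, 1], mk(3)$mean[which(grid$interior_mask)])
  # mismatched grid errors
  grid2 <- build_cell_grid(cube, 4)
  bad <- aggregate_bmd(bmd_point_cloud(matrix(4, 1, 3), 100), grid2)
  expect_error(repeated_measures_from_maps(list(list(mk(1), bad))), "grid")
})
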