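test_that("first-moment replications are weighted means of the data", {
  # constant data: every replication equals the constant, for any scheme
  # whose columns sum to 1
  for (w in list(draw_multinomial_weights(6, 300, seed = 1),
                 draw_dirichlet_weights(6, 300, seed = 1))) {
    r <- boot_first_moment(rep(3.5, 6), w)
    expect_true(all(abs(r$replications - 3.5) < 1e-12))
    expect_identical(r$nan_count, 0L)
  }

  # a column with all mass on observation 1 reproduces x_1
  x <- c(2, 5, 9)
  w <- manual_weights(cbind(c(1, 0, 0), c(0, 0, 1)), "multinomial")
  r <- boot_first_moment(x, w)
  expect_equal(r$replications, c(2, 9))
})

test_that("bootstrap mean of x = (0,1) matches the exact enumeration", {
  # exact bootstrap distribution at N = 2: {0: 1/4, 0.5: 1/2, 1: 1/4}
  # -> mean 0.5, variance 0.125
  b <- 100000
  w <- draw_multinomial_weights(2, b, seed = 7)
  r <- boot_first_moment(c(0, 1), w)
  expect_lt(abs(mean(r$replications) - 0.5), 3 * sqrt(0.125 / b))
  exact_sd_se <- exact_se_sd(c(0, 0.5, 1), c(0.25, 0.5, 0.25), b)
  expect_lt(abs(stats::sd(r$replications) - sqrt(0.125)), 3 * exact_sd_se)
  # closed form: boot SE of the mean -> sqrt(plugin variance / N)
  expect_lt(abs(r$se - sqrt(plugin_var(c(0, 1)) / 2)), 3 * exact_sd_se)
})

test_that("boot_statistic generalizes boot_first_moment via transforms", {
  x <- rnorm(12)
  w <- draw_multinomial_weights(12, 500, seed = 2)
  ident <- statistic_spec("mean", list(function(x) x),
                          function(M) M[1, ])
  expect_identical(boot_statistic(x, w, ident)$replications,
                   boot_first_moment(x, w)$replications)
  # named route matches the explicit spec
  expect_identical(boot_statistic(x, w, "mean")$replications,
                   boot_first_moment(x, w)$replications)
})

test_that("plug-in variance replications follow the enumeration oracle", {
  w <- draw_multinomial_weights(5, 400, seed = 3)
  r <- boot_statistic(rep(2, 5), w, "variance")
  expect_true(all(abs(r$replications) <= 1e-12))

  # exact expectation of the variance replication at N=2, x=(0,1):
  # counts (2,0) -> 0, (1,1) -> 0.25, (0,2) -> 0, weighted 1/4,1/2,1/4
  b <- 100000
  w2 <- draw_multinomial_weights(2, b, seed = 4)
  r2 <- boot_statistic(c(0, 1), w2, "variance")
  expect_true(all(r2$replications %in% c(0, 0.25)))
  mc_se <- sqrt(0.015625 / b)  # Var of the replication = 1/2 * 0.125^2 * 2
  expect_lt(abs(mean(r2$replications) - 0.125), 3 * mc_se)
})

test_that("sd replications are the square root of variance replications", {
  x <- rnorm(9)
  w <- draw_multinomial_weights(9, 300, seed = 5)
  v <- boot_statistic(x, w, "variance")$replications
  s <- boot_statistic(x, w, "sd")$replications
  expect_equal(s, sqrt(v))
})

test_that("correlation under uniform weights is the plug-in correlation", {
  z <- rnorm(8); y <- rnorm(8)
  w <- manual_weights(matrix(1 / 8, 8, 3), "multinomial")
  r <- boot_correlation(z, y, w)
  expect_true(all(abs(r$replications - stats::cor(z, y)) < 1e-12))
})

test_that("perfect correlation is weight-invariant", {
  z <- rnorm(10)
  for (w in list(draw_multinomial_weights(10, 400, seed = 6),
                 draw_dirichlet_weights(10, 400, seed = 6))) {
    r <- boot_correlation(z, z, w)
    finite <- r$replications[is.finite(r$replications)]
    expect_true(all(abs(finite - 1) < 1e-12))
  }
})

test_that("vectorized correlation equals Pearson's r on expanded resamples", {
  # the resampling/weighting identity, on random instances
  set.seed(8)
  for (case in 1:20) {
    n <- sample(2:30, 1)
    b <- sample(1:50, 1)
    z <- rnorm(n); y <- rnorm(n)
    w <- draw_multinomial_weights(n, b, seed = 100 + case)
    vec <- boot_correlation(z, y, w)$replications
    loop <- vapply(seq_len(b), function(j) {
      counts <- round(w$values[, j] * n)
      rs <- counts_to_resample(boot_sample(z, y), counts)
      if (stats::sd(rs$x) == 0 || stats::sd(rs$y) == 0) return(NaN)
      stats::cor(rs$x, rs$y)
    }, numeric(1))
    same_nan <- is.nan(vec) == is.nan(loop)
    expect_true(all(same_nan))
    ok <- is.finite(vec)
    expect_true(all(abs(vec[ok] - loop[ok]) <=
                      1e-10 * pmax(1, abs(loop[ok]))))
  }
})

test_that("degenerate correlation resamples become NaN, never errors", {
  z <- c(0, 1); y <- c(1, 0)
  # column (1, 0): resample is two copies of observation 1 -> zero variance
  w <- manual_weights(cbind(c(1, 0), c(0.5, 0.5)), "multinomial")
  r <- boot_correlation(z, y, w)
  expect_true(is.nan(r$replications[1]))
  expect_false(is.nan(r$replications[2]))
  expect_identical(r$nan_count, 1L)
  expect_identical(r$nan_count + sum(is.finite(r$replications)), 2L)
})

test_that("stats functions validate their inputs", {
  w <- draw_multinomial_weights(5, 10, seed = 9)
  expect_error(boot_first_moment(rnorm(4), w), "mismatch")
  expect_error(boot_correlation(1, 2, draw_multinomial_weights(1, 5)),
               "N < 2")
  expect_error(boot_correlation(rnorm(5), rnorm(4), w), "equal length")
  f <- draw_poisson_frequencies(5, 10, seed = 9)
  expect_error(boot_first_moment(rnorm(5), f), "poisson_boot_mean")
  expect_error(poisson_boot_mean(rnorm(5), w), "poisson")
  expect_error(boot_sample(c(1, NA, 3)), "non-finite")
  bad <- statistic_spec("log", list(function(x) log(x)), function(M) M[1, ])
  suppressWarnings(
    expect_error(boot_statistic(c(-1, 2, 3),
                                draw_multinomial_weights(3, 5), bad),
                 "non-finite"))
})

test_that("poisson ratio estimator handles empty columns as NaN", {
  f <- manual_weights(cbind(c(2, 1, 0), c(0, 0, 0), c(1, 1, 1)), "poisson")
  r <- poisson_boot_mean(c(4, 4, 4), f)
  expect_equal(r$replications[c(1, 3)], c(4, 4))
  expect_true(is.nan(r$replications[2]))
  expect_identical(r$nan_count, 1L)
})

test_that("summaries use finite replications and a fixed quantile rule", {
  r0 <- vecboot:::new_boot_result(c(0, 0, 0, 0), "multinomial", "mean",
                                  2L, NULL)
  s <- boot_summary(r0, 0.95)
  expect_identical(s$se, 0)
  expect_equal(unname(s$interval), c(0, 0))

  r <- vecboot:::new_boot_result(c(1, 2, NaN, 3, 4, 5), "multinomial",
                                 "mean", 2L, NULL)
  expect_error(boot_summary(r, 1.0), "level")
  expect_error(boot_summary(r, 0), "level")
  s2 <- boot_summary(r, 0.5)
  expect_identical(s2$nan_count, 1L)
  expect_identical(s2$n_finite, 5L)
  expect_equal(unname(s2$interval),
               unname(stats::quantile(1:5, c(0.25, 0.75), type = 7)))
  expect_equal(s2$se, stats::sd(1:5))
  rbad <- vecboot:::new_boot_result(c(1, NaN), "multinomial", "mean",
                                    2L, NULL)
  expect_error(boot_summary(rbad), "at least 2")
})

test_that("NaN accounting always balances", {
  set.seed(10)
  for (case in 1:10) {
    n <- sample(2:5, 1)
    w <- draw_multinomial_weights(n, 200, seed = 200 + case)
    r <- boot_correlation(rnorm(n), rnorm(n), w)
    expect_identical(r$nan_count + sum(is.finite(r$replications)),
                     r$n_reps)
  }
})
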