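# Synthetic bivariate data with the correlation structure used in the
# timing study, so every module is testable without external data.

#' Simulate paired additive-noise data
#'
#' Generates the bivariate model
#' \eqn{x_{1i} = \epsilon_{1i}}, \eqn{x_{2i} = x_{1i} + \epsilon_{2i}} with
#' \eqn{\epsilon_{ji} \sim N(0,1)} i.i.d. Under this model
#' \eqn{\mathrm{Cov}(x_1, x_2) = 1} and \eqn{\mathrm{Var}(x_2) = 2}, so the
#' population correlation is \eqn{1/\sqrt{2} \approx 0.7071}.
#'
#' @param n_obs number of observation pairs (N >= 2).
#' @param seed integer seed; same seed, same data.
#' @return A bivariate `boot_sample` (`$x` = x1, `$y` = x2).
#' @examples
#' s <- simulate_paired_additive(100, seed = 1)
#' cor(s$x, s$y)  # near 1/sqrt(2)
#' @export
simulate_paired_additive <- function(n_obs, seed = NULL) {
  if (length(n_obs) != 1L || !is.finite(n_obs) || n_obs < 2) {
    stop("`n_obs` must be a single integer >= 2", call. = FALSE)
  }
  n_obs <- as.integer(n_obs)
  with_local_seed(seed, {
    e1 <- stats::rnorm(n_obs)
    e2 <- stats::rnorm(n_obs)
    boot_sample(e1, e1 + e2)
  })
}

#' Simulate bivariate normal data with a chosen correlation
#'
#' Standard linear construction: \eqn{x \sim N(0,1)},
#' \eqn{y = \rho x + \sqrt{1-\rho^2}\,\epsilon} with
#' \eqn{\epsilon \sim N(0,1)}, giving unit variances and correlation
#' \eqn{\rho}. Generalizes [simulate_paired_additive()] (whose correlation
#' is fixed at \eqn{1/\sqrt 2}) for parameter-recovery tests.
#'
#' @param n_obs number of observation pairs (N >= 2).
#' @param rho target correlation, strictly inside (-1, 1).
#' @param seed integer seed.
#' @return A bivariate `boot_sample`.
#' @export
simulate_custom_correlation <- function(n_obs, rho, seed = NULL) {
  if (length(n_obs) != 1L || !is.finite(n_obs) || n_obs < 2) {
    stop("`n_obs` must be a single integer >= 2", call. = FALSE)
  }
  if (length(rho) != 1L || !is.finite(rho) || abs(rho) >= 1) {
    stop("`rho` must satisfy |rho| < 1", call. = FALSE)
  }
  n_obs <- as.integer(n_obs)
  with_local_seed(seed, {
    x <- stats::rnorm(n_obs)
    y <- rho * x + sqrt(1 - rho^2) * stats::rnorm(n_obs)
    boot_sample(x, y)
  })
}

#' Default sample-size grid for the benchmark harness
#'
#' Ten sample sizes from 15 to 915 in steps of 100, the grid used by the
#' packaged timing study.
#'
#' @return Integer vector of length 10.
#' @export
default_n_grid <- function() {
  seq.int(15L, 915L, by = 100L)
}

#' Write a sample to a two-column CSV fixture
#'
#' @param sample a `boot_sample`.
#' @param path output path. Univariate samples get one column `x`;
#'   bivariate samples get `x` and `y`.
#' @return `path`, invisibly.
#' @export
write_sample_csv <- function(sample, path) {
  sample <- as_boot_sample(sample)
  df <- if (is.null(sample$y)) {
    data.frame(x = sample$x)
  } else {
    data.frame(x = sample$x, y = sample$y)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
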