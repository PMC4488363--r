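# Independent verification oracles: the classical data-resampling loop
# bootstrap and the exact exhaustive bootstrap for tiny N.

# Classical plug-in evaluation of a statistic on one concrete dataset.
# Deliberately uses centered, two-pass formulas (and stats::cor) rather than
# the moment parameterization used by the vectorized path, so the two routes
# are numerically independent.
eval_plugin <- function(statistic, x, y = NULL) {
  if (inherits(statistic, "statistic_spec")) {
    m <- vapply(statistic$transforms, function(f) {
      mean(if (statistic$bivariate) f(x, y) else f(x))
    }, numeric(1))
    return(as.numeric(statistic$combiner(matrix(m, ncol = 1L))))
  }
  switch(statistic,
    mean = mean(x),
    variance = mean((x - mean(x))^2),
    sd = sqrt(mean((x - mean(x))^2)),
    correlation = {
      if (is.null(y)) stop("correlation needs two variables", call. = FALSE)
      if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NaN)
      stats::cor(x, y)
    },
    stop("unknown statistic: ", statistic, call. = FALSE)
  )
}

#' Loop-based non-parametric bootstrap (reference implementation)
#'
#' The classical data-resampling bootstrap: for each of `n_reps`
#' replications, draw N observations with replacement from the data and
#' evaluate the statistic on the resampled dataset directly. This is the
#' "for loop" baseline; it produces the same bootstrap distribution as the
#' vectorized multinomial-weight route and serves as its independent oracle
#' in tests and benchmarks.
#'
#' @param sample a `boot_sample`, numeric vector, or two-column data frame.
#' @param statistic a registered statistic name (`"mean"`, `"variance"`,
#'   `"sd"`, `"correlation"`) or a [statistic_spec()].
#' @param n_reps number of bootstrap replications B.
#' @param seed integer seed (caller's RNG state is preserved).
#' @param level percentile-interval level.
#' @return A `boot_result` with scheme `"resampling"`.
#' @examples
#' loop_bootstrap(rnorm(10), "mean", n_reps = 500, seed = 1)
#' @export
loop_bootstrap <- function(sample, statistic = "mean", n_reps = 1000L,
                           seed = NULL, level = 0.95) {
  sample <- as_boot_sample(sample)
  if (length(n_reps) != 1L || !is.finite(n_reps) || n_reps < 1) {
    stop("`n_reps` must be a positive integer", call. = FALSE)
  }
  n <- sample$n_obs
  stat_name <- if (inherits(statistic, "statistic_spec")) {
    statistic$name
  } else statistic
  needs_y <- identical(stat_name, "correlation") ||
    (inherits(statistic, "statistic_spec") && statistic$bivariate)
  if (needs_y && is.null(sample$y)) {
    stop("statistic '", stat_name, "' needs a bivariate sample",
         call. = FALSE)
  }
  reps <- with_local_seed(seed, {
    out <- numeric(n_reps)
    for (b in seq_len(n_reps)) {
      idx <- sample.int(n, n, replace = TRUE)
      out[b] <- eval_plugin(statistic, sample$x[idx],
                            if (is.null(sample$y)) NULL else sample$y[idx])
    }
    out
  })
  reps[is.na(reps)] <- NaN
  new_boot_result(reps, "resampling", stat_name, n, seed, level)
}

#' Expand a bootstrap count vector into the resampled dataset
#'
#' Given the category counts \eqn{n^*} of a bootstrap sample, returns the
#' concrete resampled dataset in which observation i appears
#' \eqn{n_i^*} times (ascending index order). This is the bridge between
#' the resampling and weighting formulations: any moment of the expanded
#' data equals the corresponding count-weighted moment of the original
#' data.
#'
#' @param sample a `boot_sample` or numeric vector.
#' @param counts integer vector of length N of non-negative counts summing
#'   to N.
#' @return A `boot_sample` of the same size N.
#' @examples
#' counts_to_resample(c(10, 20, 30), c(2, 0, 1))
#' @export
counts_to_resample <- function(sample, counts) {
  sample <- as_boot_sample(sample)
  counts <- as.integer(round(counts))
  if (length(counts) != sample$n_obs) {
    stop("`counts` must have one entry per observation", call. = FALSE)
  }
  if (any(counts < 0) || sum(counts) != sample$n_obs) {
    stop("`counts` must be non-negative and sum to N = ", sample$n_obs,
         call. = FALSE)
  }
  boot_sample(rep(sample$x, counts),
              if (is.null(sample$y)) NULL else rep(sample$y, counts))
}

# All compositions of n into k non-negative parts, as a k x C(n+k-1, k-1)
# integer matrix, in colexicographic column order (last part varies
# slowest). Recursive; guarded by the exhaustive_bootstrap size limit.
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, nrow = 1L))
  blocks <- lapply(0:n, function(last) {
    rbind(compositions(n - last, k - 1L),
          matrix(last, nrow = 1L, ncol = choose(n - last + k - 2L, k - 2L)))
  })
  do.call(cbind, blocks)
}

#' Exact exhaustive bootstrap for tiny samples
#'
#' Enumerates all \eqn{\binom{2N-1}{N-1}} bootstrap count vectors, weights
#' each by its exact multinomial probability under
#' \eqn{\mathrm{Multinomial}(N, N^{-1}\mathbf{1}_N)}, and evaluates the
#' statistic on each count-expanded resample. The result is the exact
#' bootstrap distribution — the B -> infinity limit that Monte-Carlo
#' bootstrap estimates converge to — usable as a gold standard for N up to
#' about 8.
#'
#' @inheritParams loop_bootstrap
#' @param max_n enumeration guard (default 8); the number of count vectors
#'   grows combinatorially in N.
#' @return A list with `distribution` (data frame of `value`,
#'   `probability`, NaN values allowed), `mean`, `variance` and `se` (exact
#'   moments over the finite-valued outcomes), and `n_outcomes`.
#' @examples
#' eb <- exhaustive_bootstrap(c(0, 1), "mean")
#' eb$distribution   # values 0, 0.5, 1 with probabilities 1/4, 1/2, 1/4
#' @export
exhaustive_bootstrap <- function(sample, statistic = "mean", max_n = 8L) {
  sample <- as_boot_sample(sample)
  n <- sample$n_obs
  if (n > max_n) {
    stop("exhaustive enumeration limited to N <= ", max_n,
         " (", choose(2L * n - 1L, n - 1L), " count vectors at N = ", n,
         ")", call. = FALSE)
  }
  comps <- compositions(n, n)
  prob <- apply(comps, 2L, stats::dmultinom, prob = rep(1 / n, n))
  value <- apply(comps, 2L, function(cnt) {
    rs <- counts_to_resample(sample, cnt)
    eval_plugin(statistic, rs$x, rs$y)
  })
  value[is.na(value)] <- NaN
  if (abs(sum(prob) - 1) > 1e-12) {
    stop("internal error: enumeration probabilities do not sum to 1",
         call. = FALSE)
  }
  finite <- is.finite(value)
  pf <- prob[finite] / sum(prob[finite])
  mu <- sum(pf * value[finite])
  va <- sum(pf * (value[finite] - mu)^2)
  list(
    distribution = data.frame(value = value, probability = prob),
    mean = mu,
    variance = va,
    se = sqrt(va),
    n_outcomes = ncol(comps)
  )
}

#' Write an exact bootstrap distribution to CSV
#'
#' @param exact result of [exhaustive_bootstrap()].
#' @param path output path; two columns, `value` and `probability`.
#' @return `path`, invisibly.
#' @export
write_exact_distribution <- function(exact, path) {
  utils::write.csv(exact$distribution, path, row.names = FALSE)
  invisible(path)
}
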