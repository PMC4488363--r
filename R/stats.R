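# Vectorized evaluation of bootstrap replications from a weight matrix.
#
# The central identity: for any transformation f,
#   sum_i f(x_i^*) = sum_i n_i^* f(x_i),
# so a bootstrap replication of a weighted first moment is sum_i w_i^* f(x_i)
# and the whole replication vector is the product f(x)^t W*.

#' Construct a bootstrap sample
#'
#' Bundles one or two aligned numeric observation vectors. Most functions
#' also accept a bare numeric vector and coerce it with [as_boot_sample()].
#'
#' @param x numeric vector of N finite observations.
#' @param y optional second variable of the same length, for bivariate
#'   statistics such as the correlation.
#' @param labels optional per-observation identifiers.
#' @return An object of class `boot_sample`.
#' @export
boot_sample <- function(x, y = NULL, labels = NULL) {
  x <- as.numeric(x)
  if (length(x) < 1L) stop("`x` must contain at least one observation",
                           call. = FALSE)
  if (!all(is.finite(x))) stop("`x` contains non-finite values",
                               call. = FALSE)
  if (!is.null(y)) {
    y <- as.numeric(y)
    if (length(y) != length(x)) stop("`x` and `y` must have equal length",
                                     call. = FALSE)
    if (!all(is.finite(y))) stop("`y` contains non-finite values",
                                 call. = FALSE)
  }
  if (!is.null(labels) && length(labels) != length(x)) {
    stop("`labels` must match the number of observations", call. = FALSE)
  }
  structure(list(x = x, y = y, labels = labels, n_obs = length(x)),
            class = "boot_sample")
}

#' Coerce to a bootstrap sample
#' @param x a `boot_sample`, numeric vector, or two-column data frame.
#' @return A `boot_sample`.
#' @export
as_boot_sample <- function(x) {
  if (inherits(x, "boot_sample")) return(x)
  if (is.data.frame(x)) {
    if (ncol(x) == 1L) return(boot_sample(x[[1L]]))
    if (ncol(x) >= 2L) return(boot_sample(x[[1L]], x[[2L]]))
  }
  if (is.numeric(x)) return(boot_sample(x))
  stop("cannot coerce to boot_sample", call. = FALSE)
}

#' @export
print.boot_sample <- function(x, ...) {
  cat(sprintf("<boot_sample> N=%d %s\n", x$n_obs,
              if (is.null(x$y)) "(univariate)" else "(bivariate)"))
  invisible(x)
}

#' Define a moment-based statistic
#'
#' A statistic is declared by `m` transformations \eqn{f_1,\dots,f_m} of an
#' observation (or observation pair) together with a combiner mapping the
#' `m` weighted first moments \eqn{M_k = \sum_i w_i f_k(x_i)} to the value
#' of the statistic. Any statistic of this form inherits the resampling /
#' weighting equivalence and can be bootstrapped by matrix products.
#'
#' @param name statistic name (string).
#' @param transforms list of vectorized functions; each takes the
#'   observation vector `x` (and, for bivariate statistics, `y`) and returns
#'   a numeric vector of per-observation transform values.
#' @param combiner function taking the `m x B` matrix of weighted moments
#'   (row `k` = the B replications of moment `k`) and returning the
#'   length-`B` vector of statistic replications; singular inputs must map
#'   to `NaN`, not raise.
#' @param bivariate logical; does the statistic need a second variable?
#' @return A `statistic_spec` object.
#' @examples
#' # plug-in variance: M2 - M1^2
#' vr <- statistic_spec("variance",
#'   transforms = list(function(x, y) x, function(x, y) x^2),
#'   combiner = function(M) M[2, ] - M[1, ]^2)
#' @seealso [boot_statistic()], [named_statistic()]
#' @export
statistic_spec <- function(name, transforms, combiner, bivariate = FALSE) {
  stopifnot(is.character(name), length(transforms) >= 1L,
            all(vapply(transforms, is.function, logical(1))),
            is.function(combiner))
  structure(list(name = name, transforms = transforms, combiner = combiner,
                 bivariate = isTRUE(bivariate)),
            class = "statistic_spec")
}

# Weighted first moment of one transform vector for every column of W:
# row vector v^t W. Implemented as colSums(W * v) rather than a BLAS
# product because colSums accumulates each column independently, making the
# result bitwise invariant to how W is split into column blocks.
moment_row <- function(v, W) colSums(W * v)

# Numerical guard for variance-like quantities: a weighted variance below
# `tol` (on data scaled to unit max-abs) is treated as exactly zero, because
# the moment form M2 - M1^2 is a difference of products and loses precision.
VAR_TOL <- 1e-12

#' Built-in moment statistics by name
#'
#' Returns the `statistic_spec` for one of the registered statistics:
#' `"mean"`, `"variance"` (plug-in, denominator N), `"sd"` (square root of
#' the plug-in variance) or `"correlation"` (Pearson, bivariate).
#'
#' @param name statistic name.
#' @return A `statistic_spec`.
#' @export
named_statistic <- function(name) {
  switch(name,
    mean = statistic_spec("mean",
      transforms = list(function(x, y = NULL) x),
      combiner = function(M) M[1L, ]),
    variance = statistic_spec("variance",
      transforms = list(function(x, y = NULL) x,
                        function(x, y = NULL) x^2),
      combiner = function(M) {
        v <- M[2L, ] - M[1L, ]^2
        ifelse(v < 0, ifelse(v > -VAR_TOL, 0, NaN), v)
      }),
    sd = statistic_spec("sd",
      transforms = list(function(x, y = NULL) x,
                        function(x, y = NULL) x^2),
      combiner = function(M) {
        v <- M[2L, ] - M[1L, ]^2
        sqrt(ifelse(v < 0, ifelse(v > -VAR_TOL, 0, NaN), v))
      }),
    correlation = statistic_spec("correlation",
      transforms = list(
        function(x, y) x,
        function(x, y) y,
        function(x, y) x^2,
        function(x, y) y^2,
        function(x, y) x * y
      ),
      combiner = function(M) {
        vz <- M[3L, ] - M[1L, ]^2
        vy <- M[4L, ] - M[2L, ]^2
        cz <- M[5L, ] - M[1L, ] * M[2L, ]
        den <- vz * vy
        ifelse(vz <= VAR_TOL | vy <= VAR_TOL | den <= 0,
               NaN, cz / sqrt(den))
      },
      bivariate = TRUE),
    stop("unknown statistic: ", name,
         " (registered: mean, variance, sd, correlation)", call. = FALSE)
  )
}

new_boot_result <- function(replications, scheme, statistic, n_obs, seed,
                            level = 0.95) {
  finite <- is.finite(replications)
  nan_count <- sum(!finite)
  n_finite <- sum(finite)
  se <- if (n_finite >= 2L) stats::sd(replications[finite]) else NA_real_
  interval <- if (n_finite >= 2L) {
    percentile_interval(replications[finite], level)
  } else c(NA_real_, NA_real_)
  structure(
    list(replications = replications, scheme = scheme, statistic = statistic,
         n_obs = n_obs, n_reps = length(replications), seed = seed,
         nan_count = nan_count, se = se, level = level,
         percentile_interval = interval),
    class = "boot_result"
  )
}

# Empirical percentile interval: linear interpolation of order statistics
# (quantile type 7), fixed for reproducibility.
percentile_interval <- function(reps, level) {
  if (length(level) != 1L || !is.finite(level) || level <= 0 || level >= 1) {
    stop("`level` must be a single number in (0, 1)", call. = FALSE)
  }
  alpha <- (1 - level) / 2
  unname(stats::quantile(reps, probs = c(alpha, 1 - alpha), type = 7))
}

#' @export
print.boot_result <- function(x, ...) {
  cat(sprintf("<boot_result> statistic=%s scheme=%s N=%d B=%d\n",
              x$statistic, x$scheme, x$n_obs, x$n_reps))
  cat(sprintf("  se=%.6g  %.0f%% percentile interval=[%.6g, %.6g]  NaN=%d\n",
              x$se, 100 * x$level, x$percentile_interval[1],
              x$percentile_interval[2], x$nan_count))
  invisible(x)
}

check_compatible <- function(sample, weights,
                             schemes = c("multinomial", "dirichlet")) {
  stopifnot(inherits(weights, "weight_matrix"))
  if (sample$n_obs != weights$n_obs) {
    stop(sprintf("dimension mismatch: sample has N=%d, weights have N=%d",
                 sample$n_obs, weights$n_obs), call. = FALSE)
  }
  if (!(weights$scheme %in% schemes)) {
    if (weights$scheme == "poisson") {
      stop("poisson frequencies are unnormalized; use poisson_boot_mean()",
           call. = FALSE)
    }
    stop("scheme ", weights$scheme, " not supported here", call. = FALSE)
  }
  invisible(NULL)
}

#' Bootstrap replications of the first sample moment
#'
#' Computes all B bootstrap replications of the mean,
#' \eqn{\hat\theta^* = \sum_i w_i^* x_i}, as the single vector-matrix
#' product \eqn{x^t W^*}.
#'
#' @param sample a `boot_sample` or numeric vector.
#' @param weights a `weight_matrix` with scheme `"multinomial"` or
#'   `"dirichlet"` (for raw Poisson frequencies use [poisson_boot_mean()]).
#' @param level percentile-interval level (default 0.95).
#' @return A `boot_result` with the B replications, their standard
#'   deviation (`$se`) and percentile interval.
#' @examples
#' w <- draw_multinomial_weights(10, 1000, seed = 1)
#' boot_first_moment(rnorm(10), w)
#' @export
boot_first_moment <- function(sample, weights, level = 0.95) {
  sample <- as_boot_sample(sample)
  check_compatible(sample, weights)
  reps <- moment_row(sample$x, weights$values)
  new_boot_result(reps, weights$scheme, "mean", sample$n_obs,
                  weights$seed, level)
}

#' Bootstrap replications of a moment-based statistic
#'
#' Evaluates the `m` transform vectors once as an `m x N` matrix `F`,
#' obtains all weighted moments as the product `F W*` (an `m x B` matrix),
#' and applies the statistic's combiner columnwise. Combiner singularities
#' (e.g. zero weighted variance) yield `NaN` replications, which are counted
#' in `$nan_count` and excluded from `$se` and the percentile interval.
#'
#' @inheritParams boot_first_moment
#' @param spec a [statistic_spec()], or the name of a registered statistic.
#' @param chunk_size maximum weight-matrix entries processed per block; the
#'   result is identical for any value.
#' @return A `boot_result`.
#' @examples
#' s <- boot_sample(rnorm(20))
#' w <- draw_multinomial_weights(20, 2000, seed = 2)
#' boot_statistic(s, w, "variance")
#' @export
boot_statistic <- function(sample, weights, spec, level = 0.95,
                           chunk_size = 1e8) {
  sample <- as_boot_sample(sample)
  if (is.character(spec)) spec <- named_statistic(spec)
  stopifnot(inherits(spec, "statistic_spec"))
  check_compatible(sample, weights)
  if (spec$bivariate && is.null(sample$y)) {
    stop("statistic '", spec$name, "' needs a bivariate sample",
         call. = FALSE)
  }
  tvals <- lapply(spec$transforms, function(f) {
    v <- if (spec$bivariate) f(sample$x, sample$y) else f(sample$x)
    if (length(v) != sample$n_obs || !all(is.finite(v))) {
      stop("transform produced non-finite or wrong-length values on the ",
           "observed data", call. = FALSE)
    }
    as.numeric(v)
  })
  reps <- numeric(weights$n_reps)
  for (idx in chunk_plan(weights$n_reps, weights$n_obs, chunk_size)) {
    W <- weights$values[, idx, drop = FALSE]
    moments <- do.call(rbind, lapply(tvals, moment_row, W = W))  # m x |idx|
    reps[idx] <- spec$combiner(moments)
  }
  new_boot_result(reps, weights$scheme, spec$name, sample$n_obs,
                  weights$seed, level)
}

#' Bootstrap replications of the Pearson correlation
#'
#' Vectorized bootstrap of the Pearson sample correlation between `z` and
#' `y`, evaluated in moment form: with weight matrix \eqn{W^*},
#' \deqn{\hat\theta^* = \frac{(z \bullet y)^t W^* - (z^t W^*) \bullet
#'   (y^t W^*)}{\sqrt{[(z^2)^t W^* - (z^t W^*)^2] \bullet
#'   [(y^2)^t W^* - (y^t W^*)^2]}},}
#' where \eqn{\bullet} is the Hadamard (elementwise) product and all squares
#' and square roots are entrywise. Replications whose weighted variance in
#' either variable is numerically zero (below `1e-12` after scaling each
#' variable to unit max-abs) are degenerate resamples and are set to `NaN`,
#' counted in `$nan_count`.
#'
#' @param z,y numeric vectors of equal length (N >= 2).
#' @inheritParams boot_first_moment
#' @return A `boot_result` with statistic `"correlation"`.
#' @examples
#' z <- rnorm(15); y <- z + rnorm(15)
#' w <- draw_multinomial_weights(15, 5000, seed = 3)
#' boot_correlation(z, y, w)
#' @export
boot_correlation <- function(z, y, weights, level = 0.95,
                             chunk_size = 1e8) {
  sample <- boot_sample(z, y)
  if (sample$n_obs < 2L) {
    stop("correlation is undefined for N < 2", call. = FALSE)
  }
  check_compatible(sample, weights)
  # scale to unit max-abs so the degenerate-variance tolerance is absolute
  sz <- max(abs(sample$x)); sz <- if (sz > 0) sz else 1
  sy <- max(abs(sample$y)); sy <- if (sy > 0) sy else 1
  z <- sample$x / sz
  y <- sample$y / sy
  B <- weights$n_reps
  reps <- numeric(B)
  for (idx in chunk_plan(B, weights$n_obs, chunk_size)) {
    W <- weights$values[, idx, drop = FALSE]
    mz  <- moment_row(z, W)
    my  <- moment_row(y, W)
    mzz <- moment_row(z^2, W)
    myy <- moment_row(y^2, W)
    mzy <- moment_row(z * y, W)
    vz <- mzz - mz^2
    vy <- myy - my^2
    num <- mzy - mz * my
    den <- vz * vy
    reps[idx] <- ifelse(vz <= VAR_TOL | vy <= VAR_TOL | den <= 0,
                        NaN, num / sqrt(den))
  }
  new_boot_result(reps, weights$scheme, "correlation", sample$n_obs,
                  weights$seed, level)
}

#' Poisson-frequency bootstrap of the mean
#'
#' The approximate frequency bootstrap replaces multinomial counts by i.i.d.
#' Poisson(1) frequencies \eqn{p_i^*}; because the frequencies do not sum to
#' N, the mean becomes the ratio estimator
#' \eqn{\bar y^* = (\sum_i p_i^* y_i) / (\sum_i p_i^*)}. Columns whose total
#' frequency is zero (an empty bootstrap sample, probability \eqn{e^{-N}})
#' yield `NaN` and are counted in `$nan_count`.
#'
#' @param y numeric observation vector.
#' @param frequencies a `weight_matrix` with scheme `"poisson"`.
#' @inheritParams boot_first_moment
#' @return A `boot_result` with statistic `"mean"` and scheme `"poisson"`.
#' @examples
#' f <- draw_poisson_frequencies(10, 1000, seed = 4)
#' poisson_boot_mean(rnorm(10), f)
#' @export
poisson_boot_mean <- function(y, frequencies, level = 0.95) {
  sample <- as_boot_sample(y)
  stopifnot(inherits(frequencies, "weight_matrix"))
  if (frequencies$scheme != "poisson") {
    stop("`frequencies` must use the poisson scheme; for multinomial or ",
         "dirichlet weights use boot_first_moment()", call. = FALSE)
  }
  if (sample$n_obs != frequencies$n_obs) {
    stop("dimension mismatch between `y` and `frequencies`", call. = FALSE)
  }
  num <- moment_row(sample$x, frequencies$values)
  den <- colSums(frequencies$values)
  reps <- ifelse(den == 0, NaN, num / den)
  new_boot_result(reps, "poisson", "mean", sample$n_obs,
                  frequencies$seed, level)
}

#' Summarize a bootstrap result
#'
#' Recomputes the bootstrap standard error (standard deviation of the finite
#' replications, denominator \eqn{B_{finite} - 1}) and the empirical
#' percentile interval at a chosen level (linear interpolation of order
#' statistics, quantile type 7).
#'
#' @param result a `boot_result`.
#' @param level interval level in (0, 1).
#' @return A list with elements `se`, `interval`, `nan_count`, `n_finite`.
#' @export
boot_summary <- function(result, level = 0.95) {
  stopifnot(inherits(result, "boot_result"))
  if (length(level) != 1L || !is.finite(level) || level <= 0 || level >= 1) {
    stop("`level` must be a single number in (0, 1)", call. = FALSE)
  }
  finite <- result$replications[is.finite(result$replications)]
  if (length(finite) < 2L) {
    stop("need at least 2 finite replications to summarize", call. = FALSE)
  }
  list(
    se = stats::sd(finite),
    interval = percentile_interval(finite, level),
    nan_count = result$nan_count,
    n_finite = length(finite)
  )
}
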