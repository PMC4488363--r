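#' vecboot: vectorized non-parametric bootstrap for moment statistics
#'
#' Generates an N x B matrix of bootstrap weights once (multinomial counts
#' over N, Dirichlet weights, or raw Poisson frequencies) and computes all B
#' bootstrap replications of any weighted-moment statistic with a few matrix
#' products. See [vec_boot()] for the one-call interface,
#' [draw_multinomial_weights()] / [boot_statistic()] for the two-step
#' interface, and [loop_bootstrap()] / [exhaustive_bootstrap()] for the
#' independent reference oracles.
#'
#' @keywords internal
"_PACKAGE"

#' One-call vectorized bootstrap
#'
#' Draws the bootstrap weight matrix for the chosen scheme and evaluates the
#' statistic, streaming over column blocks so the full N x B matrix never
#' needs to be held in memory. For a fixed `(scheme, statistic, seed)` the
#' replications are bitwise identical for any `chunk_size`.
#'
#' @param x numeric observation vector (or a `boot_sample`).
#' @param y optional second variable, required for `statistic =
#'   "correlation"`.
#' @param statistic `"mean"`, `"variance"`, `"sd"`, `"correlation"`, or a
#'   [statistic_spec()].
#' @param scheme `"multinomial"` (classical bootstrap), `"dirichlet"`
#'   (Bayesian bootstrap) or `"poisson"` (approximate frequency bootstrap;
#'   mean only).
#' @param n_reps number of bootstrap replications B.
#' @param seed integer seed (required for reproducible output).
#' @param level percentile-interval level.
#' @param chunk_size maximum weight-matrix entries generated per block.
#' @return A `boot_result`.
#' @examples
#' s <- simulate_paired_additive(15, seed = 1)
#' r <- vec_boot(s$x, s$y, statistic = "correlation", n_reps = 10000,
#'               seed = 2)
#' r$se
#' @export
vec_boot <- function(x, y = NULL, statistic = "mean",
                     scheme = c("multinomial", "dirichlet", "poisson"),
                     n_reps = 10000L, seed = NULL, level = 0.95,
                     chunk_size = 1e8) {
  scheme <- match.arg(scheme)
  sample <- if (inherits(x, "boot_sample")) x else boot_sample(x, y)
  stat_name <- if (inherits(statistic, "statistic_spec")) {
    statistic$name
  } else statistic
  if (scheme == "poisson" && !identical(stat_name, "mean")) {
    stop("the poisson frequency scheme implements only the mean ",
         "(ratio estimator)", call. = FALSE)
  }
  check_draw_args(sample$n_obs, n_reps, chunk_size)
  n_reps <- as.integer(n_reps)
  reps <- with_local_seed(seed, {
    out <- numeric(n_reps)
    for (idx in chunk_plan(n_reps, sample$n_obs, chunk_size)) {
      block <- new_weight_matrix(
        draw_block(scheme, sample$n_obs, length(idx)), scheme)
      r <- if (scheme == "poisson") {
        poisson_boot_mean(sample, block)
      } else if (identical(stat_name, "correlation") &&
                 !inherits(statistic, "statistic_spec")) {
        boot_correlation(sample$x, sample$y, block)
      } else {
        boot_statistic(sample, block, statistic)
      }
      out[idx] <- r$replications
    }
    out
  })
  new_boot_result(reps, scheme, stat_name, sample$n_obs, seed, level)
}
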