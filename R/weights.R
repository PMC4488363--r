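# Bootstrap weight / frequency matrices for the three sampling schemes.
#
# Orientation is fixed as N rows (observations) x B columns (replications):
# every downstream product is of the form x^t W.

#' Construct a weight-matrix object
#'
#' Internal constructor; validates the invariants of each sampling scheme.
#'
#' @param values numeric N x B matrix.
#' @param scheme one of `"multinomial"`, `"dirichlet"`, `"poisson"`.
#' @param seed the seed used to generate `values`, or `NULL`.
#' @return An object of class `weight_matrix`.
#' @keywords internal
#' @noRd
new_weight_matrix <- function(values, scheme, seed = NULL) {
  stopifnot(is.matrix(values))
  structure(
    list(
      values = values,
      scheme = scheme,
      n_obs = nrow(values),
      n_reps = ncol(values),
      seed = seed
    ),
    class = "weight_matrix"
  )
}

#' @export
print.weight_matrix <- function(x, ...) {
  cat(sprintf(
    "<weight_matrix> scheme=%s  N=%d  B=%d  seed=%s\n",
    x$scheme, x$n_obs, x$n_reps,
    if (is.null(x$seed)) "<none>" else format(x$seed)
  ))
  invisible(x)
}

check_draw_args <- function(n_obs, n_reps, chunk_size) {
  if (length(n_obs) != 1L || !is.finite(n_obs) || n_obs < 1 ||
      n_obs != round(n_obs)) {
    stop("`n_obs` must be a single positive integer", call. = FALSE)
  }
  if (length(n_reps) != 1L || !is.finite(n_reps) || n_reps < 1 ||
      n_reps != round(n_reps)) {
    stop("`n_reps` must be a single positive integer", call. = FALSE)
  }
  if (length(chunk_size) != 1L || !is.finite(chunk_size) || chunk_size < 1) {
    stop("`chunk_size` must be a single positive number", call. = FALSE)
  }
  invisible(NULL)
}

# Run `code` under a locally-set RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

# Split 1..n_reps into consecutive column blocks of at most `cols` columns.
chunk_plan <- function(n_reps, n_obs, chunk_size) {
  cols <- max(1L, as.integer(min(n_reps, floor(chunk_size / n_obs))))
  starts <- seq.int(1L, n_reps, by = cols)
  lapply(starts, function(s) seq.int(s, min(s + cols - 1L, n_reps)))
}

# Draw one column block for a scheme from the *current* RNG stream.
# Blocks drawn consecutively from one stream concatenate to the same matrix
# as a single draw, which makes results chunk-size invariant for a fixed
# seed (rmultinom / rgamma / rpois all consume the stream column-wise).
draw_block <- function(scheme, n_obs, n_cols) {
  switch(scheme,
    multinomial = rmultinom(n_cols, size = n_obs,
                            prob = rep(1 / n_obs, n_obs)) / n_obs,
    dirichlet = {
      g <- matrix(rgamma(n_obs * n_cols, shape = 1), nrow = n_obs)
      sweep(g, 2L, colSums(g), "/")
    },
    poisson = matrix(as.numeric(rpois(n_obs * n_cols, lambda = 1)),
                     nrow = n_obs),
    stop("unknown scheme: ", scheme, call. = FALSE)
  )
}

draw_weights <- function(scheme, n_obs, n_reps, seed, chunk_size) {
  check_draw_args(n_obs, n_reps, chunk_size)
  n_obs <- as.integer(n_obs)
  n_reps <- as.integer(n_reps)
  values <- with_local_seed(seed, {
    blocks <- chunk_plan(n_reps, n_obs, chunk_size)
    out <- matrix(0, nrow = n_obs, ncol = n_reps)
    for (idx in blocks) out[, idx] <- draw_block(scheme, n_obs, length(idx))
    out
  })
  new_weight_matrix(values, scheme, seed)
}

#' Draw multinomial bootstrap weights
#'
#' Draws `n_reps` independent bootstrap count vectors
#' \eqn{n^* \sim \mathrm{Multinomial}(N, N^{-1}\mathbf{1}_N)} and returns the
#' weights \eqn{w_i^* = n_i^*/N} as an \eqn{N \times B} matrix, one column
#' per bootstrap replication. Weighting observation \eqn{i} by \eqn{w_i^*} is
#' equivalent to resampling the data with replacement, which is what makes
#' the bootstrap vectorizable: the full replication vector of a moment
#' statistic is a single matrix product with this matrix.
#'
#' Each column sums to exactly 1 and every entry times `n_obs` is an integer
#' count. Generation proceeds in column blocks from a single sequential RNG
#' stream, so the result depends only on `(n_obs, n_reps, seed)`, not on
#' `chunk_size`.
#'
#' @param n_obs number of observations \eqn{N} (positive integer).
#' @param n_reps number of bootstrap replications \eqn{B} (positive integer).
#' @param seed integer seed; the caller's RNG state is left untouched. Use
#'   `NULL` to consume the current RNG stream.
#' @param chunk_size maximum number of matrix entries generated per block
#'   (default `1e8`); controls peak memory of generation, never the result.
#' @return A `weight_matrix` object with `scheme = "multinomial"`, whose
#'   `$values` field holds the \eqn{N \times B} weight matrix.
#' @examples
#' w <- draw_multinomial_weights(5, 10, seed = 1)
#' colSums(w$values)  # all exactly 1
#' @seealso [draw_dirichlet_weights()], [draw_poisson_frequencies()],
#'   [boot_first_moment()]
#' @export
draw_multinomial_weights <- function(n_obs, n_reps, seed = NULL,
                                     chunk_size = 1e8) {
  draw_weights("multinomial", n_obs, n_reps, seed, chunk_size)
}

#' Draw Dirichlet (Bayesian bootstrap) weights
#'
#' Draws each column independently from a
#' \eqn{\mathrm{Dirichlet}(\mathbf{1}_N)} distribution (uniform on the
#' simplex), the weight distribution of the Bayesian bootstrap. Columns sum
#' to 1 up to floating-point rounding; marginally each weight is
#' \eqn{\mathrm{Beta}(1, N-1)} with mean \eqn{1/N} and variance
#' \eqn{\frac{1}{N}\left(1-\frac{1}{N}\right)/(N+1)}.
#'
#' @inheritParams draw_multinomial_weights
#' @return A `weight_matrix` with `scheme = "dirichlet"`.
#' @examples
#' w <- draw_dirichlet_weights(4, 5, seed = 1)
#' colSums(w$values)
#' @export
draw_dirichlet_weights <- function(n_obs, n_reps, seed = NULL,
                                   chunk_size = 1e8) {
  draw_weights("dirichlet", n_obs, n_reps, seed, chunk_size)
}

#' Draw Poisson bootstrap frequencies
#'
#' Draws an \eqn{N \times B} matrix of i.i.d. Poisson(1) frequencies
#' \eqn{p_i^*}, the approximate frequency bootstrap. Unlike multinomial
#' counts the column totals are random — each bootstrap "sample size"
#' \eqn{\sum_i p_i^*} is Poisson(\eqn{N}), equal to \eqn{N} only in
#' expectation — so frequencies are stored raw (unnormalized) and statistics
#' become ratio estimators; see [poisson_boot_mean()]. A column may be all
#' zero (probability \eqn{e^{-N}}), in which case the ratio statistic is
#' undefined and reported as `NaN` downstream.
#'
#' @inheritParams draw_multinomial_weights
#' @return A `weight_matrix` with `scheme = "poisson"` holding raw
#'   non-negative integer frequencies.
#' @examples
#' f <- draw_poisson_frequencies(3, 5, seed = 1)
#' colSums(f$values)  # random, E = 3
#' @export
draw_poisson_frequencies <- function(n_obs, n_reps, seed = NULL,
                                     chunk_size = 1e8) {
  draw_weights("poisson", n_obs, n_reps, seed, chunk_size)
}

#' Write a weight matrix to a CSV file
#'
#' Writes the matrix (rows = observations, columns = replications) with a
#' `#`-prefixed header line recording scheme, N, B and seed, for debugging
#' and external inspection.
#'
#' @param w a `weight_matrix`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_weight_matrix <- function(w, path) {
  stopifnot(inherits(w, "weight_matrix"))
  header <- sprintf("# scheme=%s n_obs=%d n_reps=%d seed=%s",
                    w$scheme, w$n_obs, w$n_reps,
                    if (is.null(w$seed)) "NA" else format(w$seed))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  utils::write.table(w$values, con, sep = ",", row.names = FALSE,
                     col.names = paste0("b", seq_len(w$n_reps)))
  invisible(path)
}
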