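# Timing harness: loop vs vectorized bootstrap across (N, B) grids, and the
# weight-generation vs matrix-operations decomposition.
#
# All wall-clock numbers are hardware-dependent; the harness records and
# reports them but the package asserts nothing about their magnitudes.

BENCH_METHODS <- c("loop", "vectorized_multinomial", "vectorized_dirichlet",
                   "vectorized_poisson")

# Monotonic elapsed seconds for one expression evaluation.
time_once <- function(expr) {
  t0 <- proc.time()[["elapsed"]]
  force(expr)
  proc.time()[["elapsed"]] - t0
}

run_one_method <- function(method, sample, statistic, n_reps, seed) {
  switch(method,
    loop = loop_bootstrap(sample, statistic, n_reps, seed = seed),
    vectorized_multinomial = vec_boot(sample, statistic = statistic,
                                      scheme = "multinomial",
                                      n_reps = n_reps, seed = seed),
    vectorized_dirichlet = vec_boot(sample, statistic = statistic,
                                    scheme = "dirichlet",
                                    n_reps = n_reps, seed = seed),
    vectorized_poisson = vec_boot(sample, statistic = statistic,
                                  scheme = "poisson",
                                  n_reps = n_reps, seed = seed),
    stop("unknown method: ", method, call. = FALSE)
  )
}

#' Time bootstrap methods across a sample-size / replication grid
#'
#' For every combination of method, sample size N and replication count B,
#' simulates fresh paired additive-noise data, runs the bootstrap `reps`
#' times and records the total wall-clock time of each run. A discarded
#' warm-up run precedes the timed runs of each cell. All methods in a cell
#' see the same simulated dataset.
#'
#' @param methods subset of `"loop"`, `"vectorized_multinomial"`,
#'   `"vectorized_dirichlet"`, `"vectorized_poisson"`.
#' @param n_grid sample sizes N to test.
#' @param b_grid replication counts B to test.
#' @param statistic statistic name passed to each method (the
#'   `"vectorized_poisson"` method supports only `"mean"`).
#' @param reps timed repetitions per cell (default 3; medians are taken at
#'   report time).
#' @param seed integer seed controlling both the simulated data and the
#'   bootstrap draws.
#' @return A data frame of timing records with columns `method`, `phase`
#'   (always `"total"` here), `n_obs`, `n_reps`, `replicate_index`,
#'   `elapsed_seconds`.
#' @seealso [run_component_split()], [write_bench_report()]
#' @export
run_method_grid <- function(methods = c("loop", "vectorized_multinomial"),
                            n_grid = default_n_grid(),
                            b_grid = c(10000L, 100000L, 1000000L),
                            statistic = "correlation", reps = 3L,
                            seed = 1L) {
  if (length(methods) < 1L || length(n_grid) < 1L || length(b_grid) < 1L ||
      reps < 1L) {
    stop("grids must be non-empty and reps >= 1", call. = FALSE)
  }
  bad <- setdiff(methods, BENCH_METHODS)
  if (length(bad)) stop("unknown method: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if ("vectorized_poisson" %in% methods && statistic != "mean") {
    stop("the vectorized_poisson method supports only statistic = \"mean\"",
         call. = FALSE)
  }
  records <- list()
  k <- 0L
  for (n in n_grid) {
    sample <- simulate_paired_additive(n, seed = seed + n)
    for (b in b_grid) {
      for (method in methods) {
        run_one_method(method, sample, statistic,
                       min(b, 1000L), seed)          # warm-up, discarded
        for (r in seq_len(reps)) {
          el <- time_once(run_one_method(method, sample, statistic, b,
                                         seed + r))
          k <- k + 1L
          records[[k]] <- data.frame(
            method = method, phase = "total", n_obs = n, n_reps = b,
            replicate_index = r, elapsed_seconds = el
          )
        }
      }
    }
  }
  do.call(rbind, records)
}

#' Decompose vectorized bootstrap time into weights vs matrix operations
#'
#' For each (N, B) grid point, separately times the generation of the
#' multinomial weight matrix (`phase = "weights"`) and all remaining
#' matrix/vector operations of the vectorized correlation bootstrap
#' (`phase = "statistic"`), plus their sum (`phase = "total"`). Weight
#' generation dominates at large N, which is why the loop implementation
#' can catch up there.
#'
#' @inheritParams run_method_grid
#' @return A data frame of timing records (method
#'   `"vectorized_multinomial"`, three phases per timed repetition).
#' @export
run_component_split <- function(n_grid = default_n_grid(),
                                b_grid = c(10000L, 100000L, 1000000L),
                                reps = 3L, seed = 1L) {
  if (length(n_grid) < 1L || length(b_grid) < 1L || reps < 1L) {
    stop("grids must be non-empty and reps >= 1", call. = FALSE)
  }
  records <- list()
  k <- 0L
  for (n in n_grid) {
    sample <- simulate_paired_additive(n, seed = seed + n)
    for (b in b_grid) {
      draw_multinomial_weights(n, min(b, 1000L), seed = seed)  # warm-up
      for (r in seq_len(reps)) {
        w <- NULL
        t_w <- time_once(w <- draw_multinomial_weights(n, b,
                                                       seed = seed + r))
        t_s <- time_once(boot_correlation(sample$x, sample$y, w))
        for (ph in c("weights", "statistic", "total")) {
          k <- k + 1L
          records[[k]] <- data.frame(
            method = "vectorized_multinomial", phase = ph, n_obs = n,
            n_reps = b, replicate_index = r,
            elapsed_seconds = switch(ph, weights = t_w, statistic = t_s,
                                     total = t_w + t_s)
          )
        }
      }
    }
  }
  do.call(rbind, records)
}

#' Correspondence between log time ratios and speed gains
#'
#' The benchmark report plots time ratios on the log scale; this table maps
#' reference log-ratios to the raw speed-up factors (`exp(log_ratio)`),
#' e.g. a log-ratio of 4 is a 54.60-fold speed gain.
#'
#' @param log_ratios reference log-ratio values.
#' @return Data frame with columns `log_ratio` and `speed_ratio`.
#' @export
ratio_legend <- function(log_ratios = c(4, 3, 2, 1, 0.5)) {
  data.frame(log_ratio = log_ratios, speed_ratio = exp(log_ratios))
}

#' Write the benchmark report
#'
#' Writes raw timings as CSV, the log-ratio/speed-ratio legend mapping as
#' CSV, and two plots: median total time versus B per method, and the log
#' time ratio of each resampling method against the vectorized multinomial
#' implementation versus N, with a horizontal reference line at zero (the
#' threshold below which the resampling method is faster).
#'
#' @param records timing data frame from [run_method_grid()] and/or
#'   [run_component_split()] (row-bound records are fine).
#' @param dir output directory, created if needed.
#' @return Invisibly, a list with the written `paths` and the ggplot
#'   objects (`time_plot`, `ratio_plot`; `NULL` when not derivable from
#'   the records).
#' @importFrom ggplot2 .data
#' @export
write_bench_report <- function(records, dir) {
  if (is.null(records) || nrow(records) == 0L) {
    stop("no timing records to report", call. = FALSE)
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(timings = file.path(dir, "timings.csv"),
                legend = file.path(dir, "ratio_legend.csv"))
  utils::write.csv(records, paths$timings, row.names = FALSE)
  utils::write.csv(ratio_legend(), paths$legend, row.names = FALSE)

  med <- stats::aggregate(elapsed_seconds ~ method + phase + n_obs + n_reps,
                          data = records, FUN = stats::median)
  tot <- med[med$phase == "total", ]

  time_plot <- ggplot2::ggplot(
    tot, ggplot2::aes(x = .data$n_reps, y = .data$elapsed_seconds,
                      colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::facet_wrap(~n_obs, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "bootstrap replications B",
                  y = "median elapsed time (s)",
                  title = "Bootstrap timing by method")
  paths$time_plot <- file.path(dir, "time_vs_b.png")
  ggplot2::ggsave(paths$time_plot, time_plot, width = 8, height = 5,
                  dpi = 120)

  ratio_plot <- NULL
  base <- tot[tot$method == "vectorized_multinomial", ]
  others <- tot[tot$method != "vectorized_multinomial", ]
  if (nrow(base) > 0L && nrow(others) > 0L) {
    merged <- merge(others, base, by = c("n_obs", "n_reps"),
                    suffixes = c("", "_vec"))
    merged$log_ratio <- log(merged$elapsed_seconds /
                              merged$elapsed_seconds_vec)
    ratio_plot <- ggplot2::ggplot(
      merged, ggplot2::aes(x = .data$n_obs, y = .data$log_ratio,
                           colour = .data$method)) +
      ggplot2::geom_hline(yintercept = 0) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::facet_wrap(~n_reps, labeller = ggplot2::label_both) +
      ggplot2::labs(x = "sample size N",
                    y = "log time ratio (method / vectorized)",
                    title = "Speed of resampling methods relative to the vectorized bootstrap")
    paths$ratio_plot <- file.path(dir, "log_ratio_vs_n.png")
    ggplot2::ggsave(paths$ratio_plot, ratio_plot, width = 8, height = 5,
                    dpi = 120)
  }
  invisible(list(paths = paths, time_plot = time_plot,
                 ratio_plot = ratio_plot))
}
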