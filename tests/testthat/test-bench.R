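test_that("method grid records one total-phase row per timed run", {
  recs <- run_method_grid(methods = c("loop", "vectorized_multinomial"),
                          n_grid = 10, b_grid = 500,
                          statistic = "correlation", reps = 2, seed = 1)
  expect_identical(nrow(recs), 2L * 1L * 1L * 2L)   # methods x N x B x reps
  expect_true(all(recs$phase == "total"))
  expect_true(all(recs$elapsed_seconds >= 0))
  expect_setequal(unique(recs$method), c("loop", "vectorized_multinomial"))
})

test_that("all four schemes run through the harness for the mean", {
  recs <- run_method_grid(
    methods = c("loop", "vectorized_multinomial", "vectorized_dirichlet",
                "vectorized_poisson"),
    n_grid = 10, b_grid = 300, statistic = "mean", reps = 1, seed = 2)
  expect_identical(nrow(recs), 4L)
})

test_that("invalid harness configurations error", {
  expect_error(run_method_grid(methods = "turbo", n_grid = 10,
                               b_grid = 100), "unknown method")
  expect_error(run_method_grid(methods = "vectorized_poisson",
                               n_grid = 10, b_grid = 100,
                               statistic = "correlation"), "poisson")
  expect_error(run_method_grid(methods = character(0), n_grid = 10,
                               b_grid = 100), "non-empty")
  expect_error(write_bench_report(data.frame(), tempfile()), "no timing")
})

test_that("component split times both phases at every grid point", {
  recs <- run_component_split(n_grid = c(10, 20), b_grid = c(300, 600),
                              reps = 1, seed = 3)
  expect_identical(nrow(recs), 2L * 2L * 3L)   # N x B x phases
  for (n in c(10, 20)) for (b in c(300, 600)) {
    cell <- recs[recs$n_obs == n & recs$n_reps == b, ]
    expect_setequal(cell$phase, c("weights", "statistic", "total"))
    # the split is exhaustive: phases add up to the recorded total
    expect_equal(cell$elapsed_seconds[cell$phase == "total"],
                 sum(cell$elapsed_seconds[cell$phase != "total"]))
    # the weights/statistic ratio is computable and finite
    ratio <- cell$elapsed_seconds[cell$phase == "weights"] /
      max(cell$elapsed_seconds[cell$phase == "statistic"], 1e-9)
    expect_true(is.finite(ratio))
  }
})

test_that("timing does not perturb bootstrap results", {
  s <- simulate_paired_additive(12, seed = 4)
  before <- vec_boot(s$x, s$y, "correlation", n_reps = 500, seed = 5)
  invisible(run_method_grid(methods = "vectorized_multinomial",
                            n_grid = 12, b_grid = 200, reps = 1, seed = 6))
  after <- vec_boot(s$x, s$y, "correlation", n_reps = 500, seed = 5)
  expect_identical(before$replications, after$replications)
})

test_that("the report writes timings, the ratio legend, and plots", {
  recs <- rbind(
    run_method_grid(methods = c("loop", "vectorized_multinomial"),
                    n_grid = c(10, 15), b_grid = 400, reps = 1, seed = 7),
    run_component_split(n_grid = c(10, 15), b_grid = 400, reps = 1,
                        seed = 7))
  dir <- withr::local_tempdir()
  rep <- write_bench_report(recs, dir)

  back <- utils::read.csv(rep$paths$timings)
  expect_equal(nrow(back), nrow(recs))
  expect_equal(back$elapsed_seconds, recs$elapsed_seconds)

  legend <- utils::read.csv(rep$paths$legend)
  expect_equal(legend$speed_ratio[legend$log_ratio == 4], exp(4),
               tolerance = 1e-12)
  expect_equal(round(legend$speed_ratio, 2), c(54.60, 20.09, 7.39, 2.72,
                                               1.65))

  # log-ratio panel carries the zero reference line
  expect_false(is.null(rep$ratio_plot))
  hline <- Filter(function(l) inherits(l$geom, "GeomHline"),
                  rep$ratio_plot$layers)
  expect_length(hline, 1L)
  expect_identical(hline[[1]]$data$yintercept, 0)
  expect_true(file.exists(rep$paths$ratio_plot))
  expect_true(file.exists(rep$paths$time_plot))
})
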