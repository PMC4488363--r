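# Tabular input and replication/summary output used by the CLI.

#' Read a numeric sample from a delimited file
#'
#' Reads a CSV or TSV file (delimiter auto-detected from the header line, a
#' header row is required) and returns the selected columns as a
#' `boot_sample`. Missing or non-numeric values are rejected: the bootstrap
#' assumes complete numeric data.
#'
#' @param path input file path.
#' @param columns column names (character) or positions (integer) to use;
#'   one column for univariate statistics, two for bivariate. Default: all
#'   columns (at most two).
#' @return A `boot_sample`.
#' @export
read_sample <- function(path, columns = NULL) {
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          comment.char = "#", check.names = FALSE)
  if (!is.null(columns)) {
    if (is.character(columns) && !all(columns %in% names(df))) {
      stop("column(s) not found in ", path, ": ",
           paste(setdiff(columns, names(df)), collapse = ", "),
           call. = FALSE)
    }
    df <- df[, columns, drop = FALSE]
  }
  if (ncol(df) > 2L) df <- df[, 1:2, drop = FALSE]
  for (nm in names(df)) {
    v <- df[[nm]]
    if (!is.numeric(v)) {
      stop("column '", nm, "' is not numeric", call. = FALSE)
    }
    if (anyNA(v) || !all(is.finite(v))) {
      stop("column '", nm, "' contains missing or non-finite values",
           call. = FALSE)
    }
  }
  if (ncol(df) == 1L) boot_sample(df[[1L]]) else boot_sample(df[[1L]], df[[2L]])
}

boot_result_header <- function(result) {
  sprintf("# statistic=%s scheme=%s n_obs=%d n_reps=%d seed=%s nan_count=%d",
          result$statistic, result$scheme, result$n_obs, result$n_reps,
          if (is.null(result$seed)) "NA" else format(result$seed),
          result$nan_count)
}

#' Write bootstrap replications to a single-column CSV
#'
#' The file starts with a `#`-prefixed metadata line (statistic, scheme, N,
#' B, seed, NaN count) followed by a `replication` column holding all B
#' values, `NaN` included.
#'
#' @param result a `boot_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_boot_result <- function(result, path) {
  stopifnot(inherits(result, "boot_result"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(boot_result_header(result), con)
  writeLines("replication", con)
  writeLines(format(result$replications, digits = 17, trim = TRUE,
                    scientific = FALSE), con)
  invisible(path)
}

#' Write a bootstrap summary as JSON
#'
#' @param result a `boot_result`.
#' @param path output path.
#' @param level percentile-interval level.
#' @return `path`, invisibly.
#' @export
write_boot_summary <- function(result, path, level = 0.95) {
  s <- boot_summary(result, level)
  out <- list(
    statistic = result$statistic,
    scheme = result$scheme,
    n_obs = result$n_obs,
    n_reps = result$n_reps,
    seed = if (is.null(result$seed)) NA else result$seed,
    level = level,
    se = s$se,
    interval_lower = s$interval[1],
    interval_upper = s$interval[2],
    nan_count = s$nan_count,
    n_finite = s$n_finite
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
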