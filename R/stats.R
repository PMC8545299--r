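# Percentile bootstrap confidence intervals for summary statistics.

#' Percentile bootstrap confidence interval
#'
#' Resamples the values with replacement `n_boot` times, computes the
#' statistic on each resample, and returns the interval between the
#' (1-level)/2 and 1-(1-level)/2 empirical quantiles (equal tail
#' probabilities). Fully seeded: the same seed gives a bit-identical result,
#' and the caller's RNG stream is untouched.
#'
#' @param values non-empty numeric (or logical, for proportions) vector.
#' @param statistic `"mean"` or `"proportion"` (the mean of a 0/1 vector).
#' @param n_boot number of bootstrap resamples.
#' @param level confidence level in (0, 1).
#' @param seed integer seed.
#' @return A `bootstrap_result` list: `point`, `lower`, `upper`, `n_boot`,
#'   `level`, `seed`.
#' @export
bootstrap_ci <- function(values, statistic = c("mean", "proportion"),
                         n_boot = 1000, level = 0.95, seed = 1) {
  statistic <- match.arg(statistic)
  if (length(values) == 0L) stop("cannot bootstrap an empty sample", call. = FALSE)
  x <- as.numeric(values)
  if (statistic == "proportion" && !all(x %in% c(0, 1)))
    stop("proportion statistic requires 0/1 (or logical) values", call. = FALSE)
  stopifnot(n_boot >= 1, level > 0, level < 1)
  point <- mean(x)
  n <- length(x)
  reps <- with_seed(seed,
    colMeans(matrix(x[sample.int(n, n * n_boot, replace = TRUE)], nrow = n)))
  a <- (1 - level) / 2
  q <- stats::quantile(reps, c(a, 1 - a), names = FALSE, type = 7)
  structure(list(point = point, lower = q[1L], upper = q[2L],
                 n_boot = as.integer(n_boot), level = level, seed = seed),
            class = "bootstrap_result")
}

#' @export
print.bootstrap_result <- function(x, ...) {
  cat(sprintf("%.4g  %g%% CI [%.4g, %.4g]  (%d bootstrap resamples, seed %d)\n",
              x$point, 100 * x$level, x$lower, x$upper, x$n_boot, x$seed))
  invisible(x)
}
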