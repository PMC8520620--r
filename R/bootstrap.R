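#' Bootstrap controls
#'
#' @param B number of bootstrap replicates.
#' @param seed integer seed making the resampling reproducible.
#' @return A list used as the \code{boot} argument of [cc_fit()].
#' @export
cc_boot_control <- function(B = 1000L, seed = NULL) {
  B <- as.integer(B)
  if (is.na(B) || B < 1L) stop("B must be a positive integer", call. = FALSE)
  list(B = B, seed = seed)
}

#' Percentile bootstrap over cases
#'
#' Resamples cases (multiplicity-expanded) with replacement and recomputes a
#' statistic in each replicate, returning the empirical percentiles.  This
#' is the recommended interval for the weighting method, since the
#' model-based variance treats the estimated weights as constants; each
#' replicate re-estimates \eqn{\pi_{10}} along with the fit.  Replicates in
#' which the statistic fails (for example, a resample with no discordant
#' cases in one direction) are skipped and counted; a warning diagnostic is
#' attached when more than 10\% fail.
#'
#' @param data a [cc_data] object.
#' @param statistic function taking a [cc_data] and returning a scalar
#'   (typically an odds ratio).
#' @param B number of replicates.
#' @param seed integer seed; the same seed yields the identical interval.
#' @param probs percentiles to report (default 2.5\% and 97.5\%).
#' @return An object of class \code{"cc_boot"}: list with \code{low},
#'   \code{high}, \code{replicates} (numeric vector with \code{NA} for
#'   failures), \code{n_failed}, \code{B}, \code{seed}, \code{probs},
#'   \code{warning}.
#' @examples
#' d <- cc_expected_cases(cc_population(n_control_periods = 3))
#' cc_bootstrap(d, function(x) cc_fit(x, "mh")$or, B = 50, seed = 1)
#' @export
cc_bootstrap <- function(data, statistic, B = 1000L, seed = NULL,
                         probs = c(0.025, 0.975)) {
  stopifnot(inherits(data, "cc_data"))
  B <- as.integer(B)
  if (is.na(B) || B < 1L) stop("B must be a positive integer", call. = FALSE)
  idx <- expand_index(data)
  n <- length(idx)
  nrow_data <- nrow(data$exposure)
  reps <- local_rng(seed, {
    vapply(seq_len(B), function(b) {
      take <- sample.int(n, n, replace = TRUE)
      counts <- tabulate(idx[take], nbins = nrow_data)
      tryCatch(as.numeric(statistic(reweight_cc_data(data, counts))),
               error = function(e) NA_real_)
    }, numeric(1L))
  })
  ok <- reps[is.finite(reps)]
  n_failed <- B - length(ok)
  if (length(ok) == 0L)
    stop("every bootstrap replicate failed", call. = FALSE)
  q <- stats::quantile(ok, probs = probs, type = 6, names = FALSE)
  structure(
    list(low = q[1L], high = q[2L], replicates = reps,
         n_failed = n_failed, B = B, seed = seed, probs = probs,
         warning = if (n_failed > 0.10 * B)
           sprintf("more than 10%% of replicates failed (%d of %d)",
                   n_failed, B)),
    class = "cc_boot"
  )
}

#' @export
print.cc_boot <- function(x, ...) {
  cat(sprintf("Percentile bootstrap (%d replicates%s): [%.4g, %.4g] at (%g, %g)%%\n",
              x$B, if (!is.null(x$seed)) paste0(", seed ", x$seed) else "",
              x$low, x$high, 100 * x$probs[1L], 100 * x$probs[2L]))
  if (x$n_failed > 0) cat(sprintf("  %d replicates failed\n", x$n_failed))
  if (!is.null(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}
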