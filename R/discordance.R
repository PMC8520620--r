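#' Discordant person-time summary
#'
#' Computes the sufficient statistics of the weighting method.  A case is
#' discordant when its case-period exposure differs from at least one control
#' period.  Writing \eqn{a_1} for the number of discordant cases exposed at
#' the case period and \eqn{a_0} for those unexposed at the case period,
#' \eqn{PT_{10,i}} counts the unexposed control periods of an
#' exposed-at-case case and \eqn{PT_{01,i}} the exposed control periods of an
#' unexposed-at-case case.  Under pairwise exchangeability (stationary
#' exposure, no time trend) the relative probability of being exposed at the
#' case period is estimated by
#' \deqn{\pi_{10} = \overline{PT_{01}} / \overline{PT_{10}},}
#' the ratio of the mean exposed control person-time of unexposed-at-case
#' cases to the mean unexposed control person-time of exposed-at-case cases.
#' Concordant cases (all periods exposed, or all unexposed) carry no
#' information and are counted in \code{n_concordant_dropped}.
#' Multiplicities act as frequency weights throughout.
#'
#' @param x a [cc_data] object.
#' @param require_pi10 if \code{TRUE} (default), error when \eqn{\pi_{10}} is
#'   undefined (\code{a1 == 0} or \code{a0 == 0}); if \code{FALSE} return the
#'   counts with \code{pi10 = NA}.
#' @return An object of class \code{"cc_discordance"}: a list with elements
#'   \code{a1}, \code{a0}, \code{sum_PT10}, \code{sum_PT01},
#'   \code{mean_PT10}, \code{mean_PT01}, \code{pi10} and
#'   \code{n_concordant_dropped}.
#' @examples
#' d <- cc_data(rbind(c(1, 0, 1), c(0, 1, 0), c(1, 0, 0)))
#' s <- cc_discordance(d)
#' s$pi10  # 2/3
#' @export
cc_discordance <- function(x, require_pi10 = TRUE) {
  stopifnot(inherits(x, "cc_data"))
  mult <- x$multiplicity
  x0 <- x$exposure[, 1L]
  ctrl_exposed <- rowSums(x$exposure[, -1L, drop = FALSE])
  ctrl_unexposed <- x$M - ctrl_exposed
  is_a1 <- x0 == 1L & ctrl_unexposed > 0L
  is_a0 <- x0 == 0L & ctrl_exposed > 0L
  concordant <- !is_a1 & !is_a0
  a1 <- sum(mult[is_a1])
  a0 <- sum(mult[is_a0])
  sum_PT10 <- sum(mult[is_a1] * ctrl_unexposed[is_a1])
  sum_PT01 <- sum(mult[is_a0] * ctrl_exposed[is_a0])
  if (require_pi10 && (a1 == 0L || a0 == 0L))
    stop(paste0("degenerate data: pi10 is undefined (a1 = ", a1,
                ", a0 = ", a0, "); no discordant information in both ",
                "exposure directions"), call. = FALSE)
  mean_PT10 <- if (a1 > 0L) sum_PT10 / a1 else NA_real_
  mean_PT01 <- if (a0 > 0L) sum_PT01 / a0 else NA_real_
  pi10 <- if (a1 > 0L && a0 > 0L && sum_PT10 > 0 && sum_PT01 > 0)
    mean_PT01 / mean_PT10 else NA_real_
  structure(
    list(a1 = a1, a0 = a0, sum_PT10 = sum_PT10, sum_PT01 = sum_PT01,
         mean_PT10 = mean_PT10, mean_PT01 = mean_PT01, pi10 = pi10,
         n_concordant_dropped = sum(mult[concordant])),
    class = "cc_discordance"
  )
}

#' @export
print.cc_discordance <- function(x, ...) {
  cat("Discordant person-time summary\n")
  cat(sprintf("  exposed at case period   : a1 = %d, total unexposed control periods = %g (mean %.4g)\n",
              x$a1, x$sum_PT10, x$mean_PT10))
  cat(sprintf("  unexposed at case period : a0 = %d, total exposed control periods = %g (mean %.4g)\n",
              x$a0, x$sum_PT01, x$mean_PT01))
  cat(sprintf("  concordant cases dropped : %d\n", x$n_concordant_dropped))
  cat(sprintf("  pi10 = %.6g\n", x$pi10))
  invisible(x)
}

#' Period weights of the weighting method
#'
#' For each discordant case with \eqn{m^1_i} exposed and \eqn{m^0_i}
#' unexposed periods (case period included), every exposed period receives
#' weight \eqn{w_{i1} = \pi_{10} / m^1_i} and every unexposed period weight
#' \eqn{w_{i0} = 1 / m^0_i}, so that the weighted denominator of the
#' conditional likelihood equals \eqn{1 + \pi_{10} e^\beta} for a binary
#' exposure.  Concordant cases receive no weights and are excluded.
#'
#' @param x a [cc_data] object.
#' @param summary optionally a precomputed [cc_discordance] summary (e.g.
#'   from a larger dataset); defaults to \code{cc_discordance(x)}.
#' @return A data frame with one row per discordant case history:
#'   \code{case_id}, \code{m1}, \code{m0}, \code{w1}, \code{w0}.
#' @examples
#' d <- cc_data(rbind(c(1, 0, 1), c(0, 1, 0), c(1, 0, 0)))
#' cc_weights(d)
#' @export
cc_weights <- function(x, summary = cc_discordance(x)) {
  stopifnot(inherits(x, "cc_data"))
  pi10 <- summary$pi10
  if (!is.finite(pi10))
    stop("pi10 is undefined; cannot compute weights", call. = FALSE)
  m1 <- rowSums(x$exposure)
  m0 <- x$M + 1L - m1
  keep <- m1 > 0L & m0 > 0L
  data.frame(case_id = x$case_id[keep],
             m1 = m1[keep], m0 = m0[keep],
             w1 = pi10 / m1[keep], w0 = 1 / m0[keep],
             stringsAsFactors = FALSE)
}
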