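#' Collapse daily histories into multi-day analysis periods
#'
#' Divides each case's daily history into analysis periods of
#' \code{days_per_period} days, counting backward from the case day, and
#' assigns each period a binary exposure under one of four definitions:
#' \describe{
#'   \item{I}{case and control periods take the exposure status of their
#'     last (most recent) day;}
#'   \item{II}{the case period takes its last day; a control period is
#'     exposed if at least half of its days are exposed;}
#'   \item{III}{the case period takes its last day; a control period is
#'     exposed if any of its days is exposed;}
#'   \item{IV}{every period is exposed if any of its days is exposed.}
#' }
#' Only complete periods are kept: with T daily periods and d days per
#' period, the \code{floor(T / d)} newest complete periods survive and the
#' oldest leftover days are dropped, so the case day is always the last day
#' of period 0.  The confounder, when present, is aggregated by the same
#' rule as the exposure.  "Half" is read inclusively: a period with exactly
#' d/2 exposed days (even d) is exposed under Definition II.
#'
#' @param data a [cc_data] object whose periods are single days.
#' @param days_per_period number of days collapsed into one analysis period.
#' @param definition one of \code{"I"}, \code{"II"}, \code{"III"},
#'   \code{"IV"}.
#' @return A [cc_data] object with \code{floor((M + 1) / days_per_period)}
#'   periods.
#' @examples
#' daily <- cc_expected_cases(cc_population())   # 22 daily periods
#' cc_aggregate(daily, 7, "I")                   # M = 2, three 7-day periods
#' @export
cc_aggregate <- function(data, days_per_period,
                         definition = c("I", "II", "III", "IV")) {
  stopifnot(inherits(data, "cc_data"))
  definition <- match.arg(definition)
  d <- as.integer(days_per_period)
  if (is.na(d) || d < 1L) stop("days_per_period must be >= 1", call. = FALSE)
  total_days <- data$M + 1L
  n_periods <- total_days %/% d
  if (n_periods < 2L)
    stop(sprintf(paste("days_per_period = %d leaves fewer than 2 complete",
                       "periods out of %d days"), d, total_days),
         call. = FALSE)
  if (d == 1L) return(data)

  collapse <- function(mat) {
    out <- matrix(0L, nrow(mat), n_periods)
    for (j in seq_len(n_periods)) {
      block <- mat[, ((j - 1L) * d + 1L):(j * d), drop = FALSE]
      last_day <- block[, 1L]              # most recent day of the period
      count <- rowSums(block)
      out[, j] <- switch(definition,
        I = last_day,
        II = if (j == 1L) last_day else as.integer(count >= d / 2),
        III = if (j == 1L) last_day else as.integer(count > 0L),
        IV = as.integer(count > 0L))
    }
    out
  }
  cc_data(collapse(data$exposure),
          if (!is.null(data$confounder)) collapse(data$confounder),
          data$multiplicity, data$case_id)
}
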