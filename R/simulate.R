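#' Build a stationary cyclic-exposure population
#'
#' Constructs the dynamic population used throughout the package's
#' simulations: patients take a drug on fixed days of a treatment cycle
#' (default: days 1 and 4 of a 7-day cycle), observed over one case period
#' (\code{m = 0}) and \code{n_control_periods} daily control periods counted
#' backward in time.  One subgroup is generated per cycle phase; to keep the
#' population's exposure prevalence identical on every day (stationarity,
#' hence pairwise exchangeability) while allowing treatment churn, one of the
#' phases exposed at the case period is realised twice -- once as an ongoing
#' user and once as a new user ("starter") exposed only at the case period --
#' and a second case-period-exposed phase is realised as a "stopper" whose
#' case period is forced unexposed.  With the defaults this yields the
#' familiar eight subgroups (stopper, six ongoing phases, starter), each of
#' size \code{n_per_subgroup}, with exactly one quarter of the population
#' exposed on every day.
#'
#' @param cycle_length days per treatment cycle.
#' @param exposed_days within-cycle day indices (1-based) on drug.
#' @param n_per_subgroup number of patients per subgroup.
#' @param n_control_periods number of daily control periods M.
#' @param include_stopper,include_starter include the stopper/starter
#'   subgroups.  Both or neither must be requested: including only one breaks
#'   stationarity and is an error.
#' @return An object of class \code{"cc_population"}: a list with
#'   \code{exposure} (matrix, one row per subgroup, columns \code{m = 0..M}),
#'   \code{label} (subgroup labels; the stopper is labelled \code{"A"} and
#'   the starter the last letter), \code{size}, and the generating
#'   settings.
#' @examples
#' pop <- cc_population()            # 8 subgroups, M = 21
#' colMeans(pop$exposure)            # exactly 0.25 on every day
#' cc_population(cycle_length = 3, exposed_days = c(1, 2),
#'               n_control_periods = 3, include_stopper = FALSE,
#'               include_starter = FALSE)
#' @export
cc_population <- function(cycle_length = 7L, exposed_days = c(1L, 4L),
                          n_per_subgroup = 10000L, n_control_periods = 21L,
                          include_stopper = TRUE, include_starter = TRUE) {
  cycle_length <- as.integer(cycle_length)
  exposed_days <- sort(unique(as.integer(exposed_days)))
  M <- as.integer(n_control_periods)
  if (cycle_length < 2L)
    stop("cycle_length must be at least 2", call. = FALSE)
  if (length(exposed_days) == 0L || any(exposed_days < 1L) ||
      any(exposed_days > cycle_length))
    stop("exposed_days must be a nonempty subset of 1..cycle_length",
         call. = FALSE)
  if (length(exposed_days) == cycle_length)
    stop("exposed_days covering the whole cycle leaves no unexposed periods",
         call. = FALSE)
  if (M < 1L) stop("n_control_periods must be >= 1", call. = FALSE)
  if (xor(include_stopper, include_starter))
    stop(paste("no stationary assignment exists with only one of the",
               "stopper/starter subgroups; include both or neither"),
         call. = FALSE)

  # ongoing phase p in 0..(cycle_length-1): exposed at period m iff the
  # cycle day ((p + m) mod cycle_length) + 1 is an exposed day
  phase_history <- function(p)
    as.integer((((p + 0:M) %% cycle_length) + 1L) %in% exposed_days)
  phases <- 0:(cycle_length - 1L)
  hist_mat <- t(vapply(phases, phase_history, integer(M + 1L)))
  exposed_at_case <- which(hist_mat[, 1L] == 1L)

  if (include_stopper) {
    if (length(exposed_at_case) < 1L)
      stop("no phase is exposed at the case period; cannot place starter/stopper",
           call. = FALSE)
    # the stopper takes the last case-period-exposed phase, case period
    # forced unexposed; the starter is exposed at m = 0 only; when a single
    # phase is exposed at the case period it is consumed by the pair, which
    # is stationary only if exactly one phase is exposed per day
    stopper_phase <- exposed_at_case[length(exposed_at_case)]
    stopper <- hist_mat[stopper_phase, ]
    stopper[1L] <- 0L
    starter <- c(1L, integer(M))
    ongoing <- hist_mat[-stopper_phase, , drop = FALSE]
    out <- rbind(stopper, ongoing, starter)
    labels <- LETTERS[seq_len(nrow(out))]
  } else {
    out <- hist_mat
    labels <- paste0("phase_", phases + 1L)
  }
  dimnames(out) <- NULL
  pop <- structure(
    list(exposure = out, label = labels,
         size = rep(as.integer(n_per_subgroup), nrow(out)),
         cycle_length = cycle_length, exposed_days = exposed_days,
         M = M),
    class = "cc_population"
  )
  frac <- colSums(out * pop$size) / sum(pop$size)
  if (max(abs(frac - frac[1L])) > 1e-12)
    stop("no stationary assignment exists for this cycle specification",
         call. = FALSE)
  pop
}

#' @export
print.cc_population <- function(x, ...) {
  cat(sprintf("Cyclic-exposure population: %d subgroups x %d patients, M = %d\n",
              nrow(x$exposure), x$size[1L], x$M))
  cat(sprintf("  cycle of %d days, drug on day(s) %s; exposed fraction %.4g on every day\n",
              x$cycle_length, paste(x$exposed_days, collapse = ", "),
              sum(x$exposure[, 1L] * x$size) / sum(x$size)))
  invisible(x)
}

check_integer_count <- function(k, what) {
  if (abs(k - round(k)) > 1e-8)
    stop(sprintf(paste("expected case count %s = %g is not an integer;",
                       "change n_per_subgroup or r0 so that all expected",
                       "counts are whole numbers"), what, k), call. = FALSE)
  as.integer(round(k))
}

#' Expected cases from a cyclic population (binary exposure only)
#'
#' Deterministic expected-count case generation: the expected number of cases
#' in a subgroup depends only on exposure at the case period and equals
#' \code{N * r0} when unexposed and \code{N * rr * r0} when exposed.  Each
#' subgroup becomes one case history with the expected count as frequency
#' multiplicity, so the resulting dataset is exactly reproducible.
#'
#' @param population a [cc_population].
#' @param r0 baseline event rate per period in an unexposed period.
#' @param rr rate ratio of the exposure.
#' @return A [cc_data] object with one history per subgroup.
#' @examples
#' cases <- cc_expected_cases(cc_population())
#' sum(cases$multiplicity)  # 140
#' @export
cc_expected_cases <- function(population, r0 = 0.001, rr = 4) {
  stopifnot(inherits(population, "cc_population"))
  if (r0 <= 0 || r0 >= 1) stop("r0 must be in (0, 1)", call. = FALSE)
  if (rr <= 0) stop("rr must be positive", call. = FALSE)
  x0 <- population$exposure[, 1L]
  counts <- vapply(seq_along(x0), function(i) {
    k <- population$size[i] * r0 * if (x0[i] == 1L) rr else 1
    check_integer_count(k, sprintf("for subgroup %s", population$label[i]))
  }, integer(1L))
  cc_data(population$exposure, multiplicity = counts,
          case_id = population$label)
}

#' Expected cases with a binary time-varying confounder
#'
#' Extends [cc_expected_cases()] with a binary time-varying confounder z.
#' Each subgroup contributes two case strata defined by the confounder state
#' at the case period, with expected counts
#' \code{N*r0*(1-f0)}, \code{N*rr_z*r0*f0} for unexposed-at-case subgroups
#' (z0 = 0, 1) and \code{N*rr*r0*(1-f1)}, \code{N*rr*rr_z*r0*f1} for
#' exposed-at-case subgroups.  Strata are expanded into individual cases and
#' the confounder state at each control period is drawn independently as
#' Bernoulli(\code{f1}) when the period is exposed and Bernoulli(\code{f0})
#' when unexposed, so z has no within-subject dependency of its own.
#'
#' @inheritParams cc_expected_cases
#' @param rr_z rate ratio of the confounder.
#' @param f0,f1 probability that the confounder is positive in an unexposed
#'   (resp. exposed) period.
#' @param seed integer seed for the control-period confounder draws; the
#'   caller's random-number state is left untouched.
#' @return A [cc_data] object with one row per case (multiplicity 1) and a
#'   confounder matrix.
#' @examples
#' cases <- cc_expected_cases_confounded(cc_population(), seed = 1)
#' sum(cases$multiplicity)  # 184
#' @export
cc_expected_cases_confounded <- function(population, r0 = 0.001, rr = 4,
                                         rr_z = 2, f0 = 0.2, f1 = 0.4,
                                         seed = NULL) {
  stopifnot(inherits(population, "cc_population"))
  if (r0 <= 0 || r0 >= 1) stop("r0 must be in (0, 1)", call. = FALSE)
  if (rr <= 0 || rr_z <= 0) stop("rr and rr_z must be positive", call. = FALSE)
  if (f0 < 0 || f0 > 1 || f1 < 0 || f1 > 1)
    stop("f0 and f1 must be probabilities", call. = FALSE)
  M <- population$M
  x0 <- population$exposure[, 1L]
  strata <- do.call(rbind, lapply(seq_along(x0), function(i) {
    N <- population$size[i]
    if (x0[i] == 1L) {
      n0 <- check_integer_count(N * rr * r0 * (1 - f1),
                                sprintf("(z0 = 0) for subgroup %s",
                                        population$label[i]))
      n1 <- check_integer_count(N * rr * rr_z * r0 * f1,
                                sprintf("(z0 = 1) for subgroup %s",
                                        population$label[i]))
    } else {
      n0 <- check_integer_count(N * r0 * (1 - f0),
                                sprintf("(z0 = 0) for subgroup %s",
                                        population$label[i]))
      n1 <- check_integer_count(N * rr_z * r0 * f0,
                                sprintf("(z0 = 1) for subgroup %s",
                                        population$label[i]))
    }
    data.frame(subgroup = i, z0 = c(0L, 1L), n = c(n0, n1))
  }))
  strata <- strata[strata$n > 0L, , drop = FALSE]
  row_sub <- rep(strata$subgroup, strata$n)
  z0 <- rep(strata$z0, strata$n)
  exposure <- population$exposure[row_sub, , drop = FALSE]
  n <- nrow(exposure)
  z <- matrix(0L, n, M + 1L)
  z[, 1L] <- z0
  ctrl <- exposure[, -1L, drop = FALSE]
  local_rng(seed, {
    draws <- matrix(stats::runif(n * M), n, M)
  })
  z[, -1L] <- ifelse(draws < ifelse(ctrl == 1L, f1, f0), 1L, 0L)
  cc_data(exposure, z,
          case_id = sprintf("%s_z%d_%03d", population$label[row_sub], z0,
                            stats::ave(seq_len(n), row_sub, z0,
                                       FUN = seq_along)))
}

# evaluate expr under a temporary RNG state seeded with `seed`
local_rng <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  eval.parent(substitute(expr))
}

#' Exposure-sequence probabilities of a population
#'
#' Maps each distinct full exposure history of the population to its
#' population share.  Histories shared by several subgroups are merged and
#' their shares summed.  The resulting table provides the permutation
#' probabilities required by the Vines-Farrington estimator.
#'
#' @param population a [cc_population].
#' @return A [cc_patterns] object.
#' @examples
#' cc_pattern_table(cc_population())  # 8 sequences, probability 1/8 each
#' @export
cc_pattern_table <- function(population) {
  stopifnot(inherits(population, "cc_population"))
  seqs <- apply(population$exposure, 1L, paste, collapse = "")
  share <- tapply(population$size, seqs, sum) / sum(population$size)
  cc_patterns(names(share), as.numeric(share))
}
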