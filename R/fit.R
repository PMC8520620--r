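#' Fit a case-crossover estimator
#'
#' Fits one of four estimators of the exposure odds ratio for a
#' case-crossover dataset:
#' \describe{
#'   \item{\code{"scl"}}{standard conditional logistic regression, the
#'     likelihood \eqn{\prod_i \exp(\beta x_{i0}) / \sum_j \exp(\beta
#'     x_{ij})}.  Unbiased only under global exchangeability; biased when
#'     the within-subject exposure history is autocorrelated.}
#'   \item{\code{"greenland"}}{the weighting method: \eqn{\pi_{10}}, the
#'     relative probability of being exposed at the case period, is
#'     estimated from discordant person-time ([cc_discordance()]) and the
#'     periods are weighted ([cc_weights()]) so that the Greenland
#'     conditional likelihood \eqn{\prod_i \exp(\beta x_{i0}) / \sum_j
#'     w_{ij} \exp(\beta x_{ij})} yields an estimate free of
#'     within-subject-dependency bias.  For a binary exposure without
#'     confounder the maximum is available in closed form,
#'     \eqn{OR_G = (a_1/a_0) / \pi_{10}}, with variance
#'     \eqn{1/a_0 + 1/a_1} treating \eqn{\pi_{10}} as fixed; the
#'     closed form and the weighted Newton-Raphson fit are cross-checked
#'     internally.  With \code{adjust_confounder = TRUE} the weights are
#'     still computed from the exposure alone and the weighted model is fit
#'     in \eqn{(\beta, \gamma)} with linear predictor
#'     \eqn{\beta x + \gamma z}.}
#'   \item{\code{"mh"}}{the matched Mantel-Haenszel odds ratio: each case is
#'     a stratum with one case period and M control periods, giving
#'     \eqn{OR_{MH} = \sum_i PT_{10,i} / \sum_i PT_{01,i}} for a common M.
#'     Equal to the weighting-method point estimate for a binary exposure.
#'     With \code{stratify_by_confounder = TRUE} control periods whose
#'     confounder state differs from the case period's are deleted first
#'     (Maclure stratification), which can itself introduce bias.}
#'   \item{\code{"vf"}}{the Vines-Farrington estimator, which weights each
#'     permutation of a case's observed periods by its population
#'     probability (supplied as a [cc_patterns] table).  Cases whose
#'     exposure count admits support in only one case-period class fail the
#'     positivity condition and are dropped; if every case fails, an error
#'     of class \code{"cc_no_informative_cases"} is thrown.}
#' }
#'
#' @param data a [cc_data] object.
#' @param method one of \code{"scl"}, \code{"greenland"}, \code{"mh"},
#'   \code{"vf"}.
#' @param adjust_confounder include the binary time-varying confounder with
#'   coefficient \eqn{\gamma} (methods \code{"scl"}, \code{"greenland"},
#'   \code{"vf"}).
#' @param stratify_by_confounder Maclure stratification (method
#'   \code{"mh"} only).
#' @param patterns a [cc_patterns] table (method \code{"vf"} only).
#' @param conf_level confidence level for intervals.
#' @param boot a [cc_boot_control()] list to request percentile-bootstrap
#'   intervals (cases resampled with replacement, every quantity including
#'   \eqn{\pi_{10}} recomputed in each replicate), or \code{NULL} for the
#'   model-based Wald interval.
#' @param max_iter,tol Newton-Raphson controls.
#' @return An object of class \code{"cc_fit"} with methods
#'   \code{print}, \code{summary}, \code{coef}, \code{vcov} and
#'   \code{confint}.  Components include \code{coefficients} (log odds
#'   ratios), \code{or} (the exposure odds ratio), \code{ci} (matrix of
#'   interval endpoints on the odds-ratio scale), \code{ci_kind},
#'   \code{n_informative}, \code{n_dropped}, \code{converged},
#'   \code{diagnostics}, and for the weighting method \code{pi10} and the
#'   [cc_discordance] summary.
#' @examples
#' pop <- cc_population()
#' cases <- cc_expected_cases(pop)
#' cc_fit(cases, "scl")        # biased upward (6.02 at M = 21)
#' cc_fit(cases, "greenland")  # recovers the true odds ratio 4
#' cc_fit(cases, "mh")
#' @export
cc_fit <- function(data,
                   method = c("scl", "greenland", "mh", "vf"),
                   adjust_confounder = FALSE,
                   stratify_by_confounder = FALSE,
                   patterns = NULL,
                   conf_level = 0.95,
                   boot = NULL,
                   max_iter = 100L, tol = 1e-10) {
  stopifnot(inherits(data, "cc_data"))
  method <- match.arg(method)
  if (conf_level <= 0 || conf_level >= 1)
    stop("conf_level must be in (0, 1)", call. = FALSE)
  if ((adjust_confounder || stratify_by_confounder) && is.null(data$confounder))
    stop("dataset has no confounder column", call. = FALSE)
  if (stratify_by_confounder && method != "mh")
    stop("stratify_by_confounder applies to method = 'mh' only",
         call. = FALSE)
  fit <- switch(method,
    scl = fit_scl(data, adjust_confounder, conf_level, max_iter, tol),
    greenland = fit_greenland(data, adjust_confounder, conf_level,
                              max_iter, tol),
    mh = fit_mh(data, stratify_by_confounder, conf_level),
    vf = fit_vf(data, patterns, adjust_confounder, conf_level,
                max_iter, tol))
  fit$call <- match.call()
  if (!is.null(boot)) {
    refit <- function(d) {
      f <- cc_fit(d, method = method, adjust_confounder = adjust_confounder,
                  stratify_by_confounder = stratify_by_confounder,
                  patterns = patterns, conf_level = conf_level,
                  max_iter = max_iter, tol = tol)
      if (!is.finite(f$or) || (!f$converged && f$method != "mh"))
        stop("replicate did not yield a finite estimate", call. = FALSE)
      f$or
    }
    bs <- cc_bootstrap(data, refit, B = boot$B, seed = boot$seed,
                       probs = c((1 - conf_level) / 2,
                                 1 - (1 - conf_level) / 2))
    fit$ci["exposure", ] <- c(bs$low, bs$high)
    fit$ci_kind <- "bootstrap_percentile"
    fit$boot <- bs
    if (bs$n_failed > 0)
      fit$diagnostics <- c(fit$diagnostics,
                           sprintf("%d of %d bootstrap replicates failed",
                                   bs$n_failed, bs$B))
  }
  fit
}

wald_ci <- function(beta, var, conf_level) {
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  exp(beta + c(-1, 1) * z * sqrt(var))
}

new_cc_fit <- function(method, beta, gamma = NULL, vcov = NULL,
                       ci = NULL, ci_kind = "wald", conf_level = 0.95,
                       n_informative, n_dropped, converged = TRUE,
                       diagnostics = character(), extra = list()) {
  coefs <- c(exposure = beta)
  if (!is.null(gamma)) coefs <- c(coefs, confounder = gamma)
  if (!is.null(vcov)) dimnames(vcov) <- list(names(coefs), names(coefs))
  structure(
    c(list(method = method, coefficients = coefs, or = exp(beta),
           vcov = vcov, ci = ci, ci_kind = ci_kind, conf_level = conf_level,
           n_informative = n_informative, n_dropped = n_dropped,
           converged = converged, diagnostics = diagnostics, boot = NULL),
      extra),
    class = "cc_fit"
  )
}

# ---- standard conditional logistic regression --------------------------

fit_scl <- function(data, adjust_confounder, conf_level, max_iter, tol) {
  p <- data$M + 1L
  n <- nrow(data$exposure)
  informative <- if (adjust_confounder) {
    apply(data$exposure, 1L, function(r) length(unique(r)) > 1L) |
      apply(data$confounder, 1L, function(r) length(unique(r)) > 1L)
  } else {
    apply(data$exposure, 1L, function(r) length(unique(r)) > 1L)
  }
  if (!any(informative))
    stop("no informative (discordant) cases", call. = FALSE)
  d <- subset_cc_data(data, informative)
  nn <- nrow(d$exposure)
  U <- matrix(as.numeric(t(d$exposure)), ncol = 1L)
  if (adjust_confounder) U <- cbind(U, as.numeric(t(d$confounder)))
  case <- rep(seq_len(nn), each = p)
  is_case_row <- rep(c(TRUE, rep(FALSE, p - 1L)), nn)
  nr <- nr_clogit(U, case, is_case_row, mult = d$multiplicity,
                  tol = tol, max_iter = max_iter)
  diagnostics <- character()
  if (nr$separated)
    diagnostics <- "separation: score monotone in the parameter, estimate unbounded"
  if (!is.null(nr$note)) diagnostics <- c(diagnostics, nr$note)
  beta <- nr$theta[1L]
  gamma <- if (adjust_confounder) nr$theta[2L]
  ci <- matrix(if (all(is.finite(nr$vcov)))
                 wald_ci(beta, nr$vcov[1L, 1L], conf_level)
               else c(NA_real_, NA_real_),
               1L, 2L, dimnames = list("exposure", c("low", "high")))
  if (adjust_confounder && all(is.finite(nr$vcov)))
    ci <- rbind(ci, confounder = wald_ci(gamma, nr$vcov[2L, 2L], conf_level))
  new_cc_fit("scl", beta, gamma, nr$vcov, ci, "wald", conf_level,
             n_informative = sum(d$multiplicity),
             n_dropped = n_cases(data) - sum(d$multiplicity),
             converged = nr$converged, diagnostics = diagnostics,
             extra = list(loglik = nr$loglik, iter = nr$iter))
}

# ---- weighting method (Greenland likelihood) ---------------------------

fit_greenland <- function(data, adjust_confounder, conf_level,
                          max_iter, tol) {
  disc <- cc_discordance(data)
  pi10 <- disc$pi10
  diagnostics <- character()
  p <- data$M + 1L

  # weighted conditional logistic route: offset log(w) on every period
  m1 <- rowSums(data$exposure)
  m0 <- p - m1
  informative <- if (adjust_confounder) {
    (m1 > 0L & m0 > 0L) |
      apply(data$confounder, 1L, function(r) length(unique(r)) > 1L)
  } else {
    m1 > 0L & m0 > 0L
  }
  d <- subset_cc_data(data, informative)
  nn <- nrow(d$exposure)
  dm1 <- rowSums(d$exposure)
  dm0 <- p - dm1
  # weight pi10/m1 on exposed periods, 1/m0 on unexposed; for a case with a
  # single exposure class the weight is constant and cancels, so use 1
  w1 <- ifelse(dm1 > 0L, pi10 / dm1, 1)
  w0 <- ifelse(dm0 > 0L, 1 / dm0, 1)
  xt <- t(d$exposure)
  logw <- as.numeric(ifelse(xt == 1L, log(w1)[col(xt)], log(w0)[col(xt)]))
  U <- matrix(as.numeric(xt), ncol = 1L)
  if (adjust_confounder) U <- cbind(U, as.numeric(t(d$confounder)))
  case <- rep(seq_len(nn), each = p)
  is_case_row <- rep(c(TRUE, rep(FALSE, p - 1L)), nn)
  nr <- nr_clogit(U, case, is_case_row, offset = logw,
                  mult = d$multiplicity, tol = tol, max_iter = max_iter)

  if (!adjust_confounder) {
    # closed form for the binary-exposure model, variance with pi10 fixed
    beta <- log((disc$a1 / disc$a0) / pi10)
    var_beta <- 1 / disc$a0 + 1 / disc$a1
    if (abs(nr$theta[1L] - beta) > 1e-6)
      diagnostics <- c(diagnostics, sprintf(
        "weighted-likelihood route (%.8f) and closed form (%.8f) disagree",
        nr$theta[1L], beta))
    vc <- matrix(var_beta, 1L, 1L)
    ci <- matrix(wald_ci(beta, var_beta, conf_level), 1L, 2L,
                 dimnames = list("exposure", c("low", "high")))
    gamma <- NULL
  } else {
    beta <- nr$theta[1L]
    gamma <- nr$theta[2L]
    vc <- nr$vcov
    if (!nr$converged)
      diagnostics <- c(diagnostics, "weighted fit did not converge")
    ci <- matrix(if (all(is.finite(vc))) wald_ci(beta, vc[1L, 1L], conf_level)
                 else c(NA_real_, NA_real_),
                 1L, 2L, dimnames = list("exposure", c("low", "high")))
    if (all(is.finite(vc)))
      ci <- rbind(ci, confounder = wald_ci(gamma, vc[2L, 2L], conf_level))
  }
  new_cc_fit("greenland", beta, gamma, vc, ci, "wald", conf_level,
             n_informative = sum(d$multiplicity),
             n_dropped = n_cases(data) - sum(d$multiplicity),
             converged = if (adjust_confounder) nr$converged else TRUE,
             diagnostics = diagnostics,
             extra = list(pi10 = pi10, discordance = disc,
                          beta_weighted_fit = nr$theta[1L]))
}

# ---- Mantel-Haenszel ----------------------------------------------------

fit_mh <- function(data, stratify_by_confounder, conf_level) {
  mult <- data$multiplicity
  x0 <- data$exposure[, 1L]
  ctrl <- data$exposure[, -1L, drop = FALSE]
  if (stratify_by_confounder) {
    zc <- data$confounder[, 1L]
    keep <- data$confounder[, -1L, drop = FALSE] == zc
    c_exp <- rowSums(ctrl * keep)
    n_ctrl <- rowSums(keep)
  } else {
    c_exp <- rowSums(ctrl)
    n_ctrl <- rep(ncol(ctrl), nrow(ctrl))
  }
  c_unexp <- n_ctrl - c_exp
  # per-case 2x2 stratum: case row (x0, 1 - x0), control row (c_exp, c_unexp)
  n_i <- n_ctrl + 1L
  has_ctrl <- n_ctrl > 0L
  R <- ifelse(has_ctrl, x0 * c_unexp / n_i, 0)          # a_i d_i / n_i
  S <- ifelse(has_ctrl, (1 - x0) * c_exp / n_i, 0)      # b_i c_i / n_i
  sumR <- sum(mult * R)
  sumS <- sum(mult * S)
  informative <- (R + S) > 0
  diagnostics <- character()
  if (sumS == 0) {
    beta <- Inf
    diagnostics <- "zero denominator: no unexposed-at-case discordant person-time; odds ratio unbounded"
  } else if (sumR == 0) {
    beta <- -Inf
    diagnostics <- "zero numerator: no exposed-at-case discordant person-time; odds ratio zero"
  } else {
    beta <- log(sumR / sumS)
  }
  # Robins-Breslow-Greenland variance on the per-case strata; reduces to
  # 1/a1 + 1/a0 at M = 1
  if (is.finite(beta)) {
    P <- (x0 + c_unexp) / n_i
    Q <- (1 - x0 + c_exp) / n_i
    var_beta <- sum(mult * P * R) / (2 * sumR^2) +
      sum(mult * (P * S + Q * R)) / (2 * sumR * sumS) +
      sum(mult * Q * S) / (2 * sumS^2)
    ci <- matrix(wald_ci(beta, var_beta, conf_level), 1L, 2L,
                 dimnames = list("exposure", c("low", "high")))
    vc <- matrix(var_beta, 1L, 1L)
  } else {
    ci <- matrix(NA_real_, 1L, 2L,
                 dimnames = list("exposure", c("low", "high")))
    vc <- matrix(NA_real_, 1L, 1L)
  }
  new_cc_fit("mh", beta, NULL, vc, ci, "wald", conf_level,
             n_informative = sum(mult[informative]),
             n_dropped = sum(mult[!informative]),
             converged = is.finite(beta), diagnostics = diagnostics,
             extra = list(stratified = stratify_by_confounder,
                          sum_PT10_over_n = sumR, sum_PT01_over_n = sumS))
}

# ---- Vines-Farrington ---------------------------------------------------

fit_vf <- function(data, patterns, adjust_confounder, conf_level,
                   max_iter, tol) {
  if (is.null(patterns))
    stop("method = 'vf' needs a pattern probability table", call. = FALSE)
  stopifnot(inherits(patterns, "cc_patterns"))
  p <- data$M + 1L
  if (nchar(patterns$sequence[1L]) != p)
    stop(sprintf("pattern sequences have length %d but the dataset has %d periods",
                 nchar(patterns$sequence[1L]), p), call. = FALSE)
  S <- do.call(rbind, lapply(strsplit(patterns$sequence, ""), as.integer))
  prob <- patterns$probability
  k_pat <- rowSums(S)
  s0 <- S[, 1L]
  # population probability of an exposed / unexposed case period among
  # support sequences with k exposed periods
  Wx <- function(k, x) sum(prob[k_pat == k & s0 == x])

  k_case <- rowSums(data$exposure)
  rows <- list(); case_idx <- integer(); is_case_row <- logical()
  offs <- numeric(); kept <- logical(nrow(data$exposure))
  nc <- 0L
  for (i in seq_len(nrow(data$exposure))) {
    k <- k_case[i]
    W1 <- Wx(k, 1L); W0 <- Wx(k, 0L)
    if (!adjust_confounder) {
      cats <- data.frame(x = c(1, 0), W = c(W1, W0))
      obs <- match(data$exposure[i, 1L], cats$x)
    } else {
      n1 <- k; n0 <- p - k
      z <- data$confounder[i, ]
      x <- data$exposure[i, ]
      n11 <- sum(x == 1L & z == 1L); n10 <- n1 - n11
      n01 <- sum(x == 0L & z == 1L); n00 <- n0 - n01
      # every permutation of the observed (x, z) pairs carries the same
      # confounder-given-exposure probability factor, so only the exposure
      # sequence probability and the share of pairs eligible for the case
      # period differ between arrangements
      cats <- data.frame(
        x = c(1, 1, 0, 0), z = c(1, 0, 1, 0),
        W = c(if (n1 > 0L) W1 * c(n11, n10) / n1 else c(0, 0),
              if (n0 > 0L) W0 * c(n01, n00) / n0 else c(0, 0)))
      obs <- match(paste(x[1L], z[1L]), paste(cats$x, cats$z))
    }
    if (cats$W[obs] <= 0 || sum(cats$W[-obs]) <= 0) next  # positivity fails
    use <- cats$W > 0
    cats <- cats[use, , drop = FALSE]
    obs <- sum(use[seq_len(obs)])
    nc <- nc + 1L
    kept[i] <- TRUE
    rows[[nc]] <- if (adjust_confounder) cbind(cats$x, cats$z)
                  else matrix(cats$x, ncol = 1L)
    case_idx <- c(case_idx, rep(nc, nrow(cats)))
    flag <- rep(FALSE, nrow(cats)); flag[obs] <- TRUE
    is_case_row <- c(is_case_row, flag)
    offs <- c(offs, log(cats$W))
  }
  if (nc == 0L)
    stop(structure(
      class = c("cc_no_informative_cases", "error", "condition"),
      list(message = paste("positivity condition not satisfied for any case;",
                           "the odds ratio cannot be estimated from this",
                           "pattern table"),
           call = NULL)))
  U <- do.call(rbind, rows)
  nr <- nr_clogit(U, case_idx, is_case_row, offset = offs,
                  mult = data$multiplicity[kept], tol = tol,
                  max_iter = max_iter)
  diagnostics <- character()
  n_fail <- n_cases(data) - sum(data$multiplicity[kept])
  if (n_fail > 0)
    diagnostics <- sprintf("%d cases failed the positivity condition and were excluded",
                           n_fail)
  if (nr$separated)
    diagnostics <- c(diagnostics, "separation: estimate unbounded")
  beta <- nr$theta[1L]
  gamma <- if (adjust_confounder) nr$theta[2L]
  ci <- matrix(if (all(is.finite(nr$vcov)))
                 wald_ci(beta, nr$vcov[1L, 1L], conf_level)
               else c(NA_real_, NA_real_),
               1L, 2L, dimnames = list("exposure", c("low", "high")))
  if (adjust_confounder && all(is.finite(nr$vcov)))
    ci <- rbind(ci, confounder = wald_ci(gamma, nr$vcov[2L, 2L], conf_level))
  new_cc_fit("vf", beta, gamma, nr$vcov, ci, "wald", conf_level,
             n_informative = sum(data$multiplicity[kept]),
             n_dropped = n_fail, converged = nr$converged,
             diagnostics = diagnostics,
             extra = list(loglik = nr$loglik))
}
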