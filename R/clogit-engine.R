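# Newton-Raphson maximiser for conditional (multinomial) logit likelihoods
# of the form  prod_i [ exp(eta_{i,case}) / sum_r exp(eta_{ir}) ]  with
# eta = U theta + offset, frequency weight mult_i per case.  Shared by the
# standard, weighted and permutation-probability estimators.
#
# U           n_rows x p covariate matrix
# case        integer row -> case index (1..N, contiguous)
# is_case_row logical, exactly one TRUE per case
# offset      per-row offset added to the linear predictor
# mult        per-case frequency weight
#
# Starts from theta = 0, tolerance on the parameter change, step-halving if
# a step decreases the likelihood, score bisection fallback for a singular
# one-parameter Hessian.  |theta| running away beyond `bound` is reported as
# separation (unbounded estimate).
nr_clogit <- function(U, case, is_case_row, offset = NULL, mult = NULL,
                      tol = 1e-10, max_iter = 100L, bound = 30) {
  U <- as.matrix(U)
  p <- ncol(U)
  N <- max(case)
  if (is.null(offset)) offset <- numeric(nrow(U))
  if (is.null(mult)) mult <- rep(1, N)
  case_rows <- which(is_case_row)
  stopifnot(length(case_rows) == N)
  U_case <- U[case_rows, , drop = FALSE]

  loglik_parts <- function(theta) {
    eta <- drop(U %*% theta) + offset
    emax <- vapply(split(eta, case), max, numeric(1L))
    w <- exp(eta - emax[case])
    denom <- rowsum(w, case)[, 1L]
    pr <- w / denom[case]
    ll <- sum(mult * (eta[case_rows] - (log(denom) + emax)))
    list(ll = ll, pr = pr)
  }
  score_info <- function(pr) {
    EU <- rowsum(pr * U, case)                    # N x p, E[U | case]
    sc <- colSums(mult * (U_case - EU))
    info <- matrix(0, p, p)
    for (a in seq_len(p)) for (b in a:p) {
      E2 <- rowsum(pr * U[, a] * U[, b], case)[, 1L]
      v <- sum(mult * (E2 - EU[, a] * EU[, b]))
      info[a, b] <- v
      info[b, a] <- v
    }
    list(score = sc, info = info)
  }

  theta <- numeric(p)
  parts <- loglik_parts(theta)
  converged <- FALSE
  separated <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    si <- score_info(parts$pr)
    sing <- !is.finite(rcond_sym(si$info)) || rcond_sym(si$info) < 1e-12
    if (sing && p == 1L) {
      # bisection on the score: the conditional log-likelihood is concave,
      # so the score is decreasing in beta
      root <- score_bisect(function(b) {
        pp <- loglik_parts(b)
        score_info(pp$pr)$score
      }, bound)
      theta <- root$theta
      converged <- root$converged
      separated <- root$separated
      parts <- loglik_parts(theta)
      break
    }
    if (sing)
      return(list(theta = theta, vcov = matrix(NA_real_, p, p),
                  loglik = parts$ll, converged = FALSE, separated = FALSE,
                  iter = iter,
                  note = "singular information matrix"))
    delta <- solve(si$info, si$score)
    step <- 1
    repeat {
      cand <- theta + step * delta
      cand_parts <- loglik_parts(cand)
      if (cand_parts$ll >= parts$ll - 1e-12 || step < 1e-4) break
      step <- step / 2
    }
    theta <- cand
    parts <- cand_parts
    if (max(abs(theta)) > bound) {
      separated <- TRUE
      break
    }
    if (max(abs(step * delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  si <- score_info(parts$pr)
  vc <- tryCatch(solve(si$info), error = function(e) matrix(NA_real_, p, p))
  list(theta = theta, vcov = vc, loglik = parts$ll,
       converged = converged && !separated, separated = separated,
       iter = iter, note = NULL)
}

rcond_sym <- function(m) {
  if (!all(is.finite(m))) return(NA_real_)
  ev <- tryCatch(eigen(m, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) NA_real_)
  if (any(is.na(ev)) || max(abs(ev)) == 0) return(0)
  min(abs(ev)) / max(abs(ev))
}

score_bisect <- function(score_fun, bound, tol = 1e-10) {
  lo <- -bound; hi <- bound
  s_lo <- score_fun(lo); s_hi <- score_fun(hi)
  if (s_lo < 0 || s_hi > 0)   # score does not change sign: unbounded MLE
    return(list(theta = if (s_hi > 0) bound else -bound,
                converged = FALSE, separated = TRUE))
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (score_fun(mid) > 0) lo <- mid else hi <- mid
  }
  list(theta = (lo + hi) / 2, converged = TRUE, separated = FALSE)
}
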