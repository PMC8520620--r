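# three-case toy dataset with M = 2: pi10 = 2/3, OR_G = OR_MH = 3
toy3 <- function() {
  cc_data(rbind(c(1, 0, 1),
                c(0, 1, 0),
                c(1, 0, 0)),
          case_id = c("A", "B", "C"))
}

# random binary-exposure dataset guaranteed to have discordance both ways
rand_cc_data <- function(n, M, seed, p = 0.5, confounder = FALSE,
                         multiplicity = FALSE) {
  set.seed(seed)
  repeat {
    x <- matrix(rbinom(n * (M + 1L), 1L, p), n, M + 1L)
    x0 <- x[, 1L]
    d_exp <- x0 == 1L & rowSums(x[, -1L, drop = FALSE]) < M
    d_un <- x0 == 0L & rowSums(x[, -1L, drop = FALSE]) > 0L
    if (any(d_exp) && any(d_un)) break
  }
  z <- if (confounder) matrix(rbinom(n * (M + 1L), 1L, 0.3), n, M + 1L)
  mult <- if (multiplicity) sample(1:3, n, replace = TRUE) else 1L
  cc_data(x, z, multiplicity = mult)
}

# all permutations of 1..n (n small), one per row
all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub), n - 1L))
  }))
}

# direct evaluation of the standard conditional logistic log-likelihood
scl_loglik <- function(data, beta) {
  eta <- beta * data$exposure
  sum(data$multiplicity *
        (eta[, 1L] - log(rowSums(exp(eta)))))
}

# independent oracle for the permutation-probability likelihood: for each
# case, explicitly enumerate every permutation of its observed periods,
# score the arranged sequence with the exposure-sequence probability from
# the table times, when a confounder is present, prod_m q(z_m | x_m) with
# q(1|1) = f1, q(1|0) = f0, and accumulate the probability mass landing on
# each case-period value class.  Returns a log-likelihood function of
# (beta, gamma) built only from these enumerated masses.
vf_loglik_bruteforce_fn <- function(data, patterns, f0 = 0.3, f1 = 0.6) {
  p <- data$M + 1L
  perms <- all_perms(p)
  lookup <- function(xseq) {
    i <- match(paste(xseq, collapse = ""), patterns$sequence)
    if (is.na(i)) 0 else patterns$probability[i]
  }
  has_z <- !is.null(data$confounder)
  cases <- list()
  for (i in seq_len(nrow(data$exposure))) {
    x <- data$exposure[i, ]
    z <- if (has_z) data$confounder[i, ]
    mass <- numeric(4L)  # classes (x0, z0) = (0,0), (0,1), (1,0), (1,1)
    for (r in seq_len(nrow(perms))) {
      xs <- x[perms[r, ]]
      P <- lookup(xs)
      if (P == 0) next
      if (has_z) {
        zs <- z[perms[r, ]]
        q <- ifelse(xs == 1L, ifelse(zs == 1L, f1, 1 - f1),
                    ifelse(zs == 1L, f0, 1 - f0))
        P <- P * prod(q)
        cls <- 1L + zs[1L] + 2L * xs[1L]
      } else {
        cls <- 1L + 2L * xs[1L]
      }
      mass[cls] <- mass[cls] + P
    }
    obs <- if (has_z) 1L + z[1L] + 2L * x[1L] else 1L + 2L * x[1L]
    if (mass[obs] == 0 || sum(mass[-obs]) == 0) next  # positivity fails
    cases[[length(cases) + 1L]] <-
      list(mass = mass, obs = obs, mult = data$multiplicity[i])
  }
  lin_class <- function(beta, gamma)
    c(0, gamma, beta, beta + gamma)  # by class order above
  function(beta, gamma = 0) {
    lin <- lin_class(beta, gamma)
    sum(vapply(cases, function(cs) {
      den <- sum(exp(lin) * cs$mass)
      cs$mult * (lin[cs$obs] + log(cs$mass[cs$obs]) - log(den))
    }, numeric(1L)))
  }
}

grid_argmax <- function(f, lo = -3, hi = 3, by = 0.001) {
  grid <- seq(lo, hi, by = by)
  grid[which.max(vapply(grid, f, numeric(1L)))]
}
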