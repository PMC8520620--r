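test_that("conditional logistic fit solves the worked cyclic example", {
  # patterns (1101), (1011), (0110) with case multiplicities 40, 40, 10;
  # the score equation reduces to 3*psi^2 - 7*psi - 8 = 0
  d <- cc_scenario("motivating")$data
  fit <- cc_fit(d, "scl")
  expect_equal(fit$or, (7 + sqrt(145)) / 6, tolerance = 1e-8)
  expect_true(fit$converged)
  expect_equal(fit$n_informative, 90L)
})

test_that("at M = 1 the estimate reduces to the discordant-pair ratio", {
  d <- rand_cc_data(40, 1, seed = 8, multiplicity = TRUE)
  s <- cc_discordance(d)
  expect_equal(cc_fit(d, "scl")$or, s$a1 / s$a0, tolerance = 1e-9)
})

test_that("maximised likelihood matches a brute-force grid search", {
  for (seed in 1:4) {
    d <- rand_cc_data(5, 3, seed = seed, multiplicity = TRUE)
    fit <- cc_fit(d, "scl")
    b_grid <- grid_argmax(function(b) scl_loglik(d, b))
    expect_equal(coef(fit)[["exposure"]], b_grid, tolerance = 2e-3)
    expect_gte(fit$loglik, scl_loglik(d, b_grid) - 1e-8)
  }
})

test_that("estimates agree with survival::clogit", {
  library(survival)
  d <- rand_cc_data(30, 4, seed = 3, confounder = TRUE, multiplicity = TRUE)
  long <- as.data.frame(d)
  # expand frequency weights into separate strata for the reference fit
  expand <- do.call(rbind, lapply(split(long, long$case_id), function(g) {
    do.call(rbind, lapply(seq_len(g$multiplicity[1L]), function(k) {
      g$stratum <- paste0(g$case_id, "_", k)
      g
    }))
  }))
  expand$y <- as.integer(expand$period == 0L)

  ref <- survival::clogit(y ~ exposure + survival::strata(stratum),
                          data = expand)
  fit <- cc_fit(d, "scl")
  expect_equal(coef(fit)[["exposure"]], unname(coef(ref)[1L]),
               tolerance = 1e-6)

  ref2 <- survival::clogit(y ~ exposure + confounder +
                             survival::strata(stratum), data = expand)
  fit2 <- cc_fit(d, "scl", adjust_confounder = TRUE)
  expect_equal(unname(coef(fit2)), unname(coef(ref2)), tolerance = 1e-6)
  expect_equal(unname(diag(vcov(fit2))), unname(diag(vcov(ref2))),
               tolerance = 1e-5)
})

test_that("separation is reported rather than silently returned", {
  # every exposed-at-case case has all-exposed controls removed: cases
  # exposed at m = 0 always carry more exposed periods
  d <- cc_data(rbind(c(1, 1, 0), c(1, 0, 1), c(0, 0, 0), c(1, 1, 0)))
  fit <- cc_fit(d, "scl")
  expect_false(fit$converged)
  expect_match(paste(fit$diagnostics, collapse = " "), "separation|unbounded")
})

test_that("fits without any discordant case are refused", {
  d <- cc_data(rbind(c(1, 1, 1), c(0, 0, 0)))
  expect_error(cc_fit(d, "scl"), "no informative")
})
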