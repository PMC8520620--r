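test_that("pattern tables validate their contents", {
  expect_error(cc_patterns(c("110", "110"), c(0.5, 0.5)), "duplicated")
  expect_error(cc_patterns(c("110", "1100"), c(0.5, 0.5)), "same length")
  expect_error(cc_patterns("10a", 1), "strings over")
  expect_error(cc_patterns(c("10", "01"), c(0.9, 0.2)), "more than 1")
  expect_error(cc_patterns("10", -0.1), "nonnegative")
  # sub-normalised tables are fine: only ratios matter
  expect_s3_class(cc_patterns(c("10", "01"), c(0.2, 0.2)), "cc_patterns")
})

test_that("pattern tables round-trip through CSV", {
  tab <- cc_pattern_table(cc_population(n_control_periods = 3))
  path <- withr::local_tempfile(fileext = ".csv")
  write_cc_patterns(tab, path)
  tab2 <- read_cc_patterns(path)
  expect_equal(tab2$sequence, tab$sequence)
  expect_equal(tab2$probability, tab$probability)
})

test_that("permutation-probability fit matches explicit enumeration", {
  # binary exposure: the distinct-arrangement shortcut must agree with a
  # grid argmax of the likelihood summed over every permutation
  pop <- cc_population(n_control_periods = 3)
  tab <- cc_pattern_table(pop)
  d <- cc_expected_cases(pop)
  fit <- cc_fit(d, "vf", patterns = tab)
  expect_equal(fit$or, 4, tolerance = 1e-6)
  ll <- vf_loglik_bruteforce_fn(d, tab)
  expect_equal(coef(fit)[["exposure"]], grid_argmax(ll), tolerance = 2e-3)

  for (seed in 1:3) {
    d2 <- rand_cc_data(5, 3, seed = seed)
    tab2 <- ccxover:::iid_patterns(4L, p = 0.4)
    fit2 <- cc_fit(d2, "vf", patterns = tab2)
    ll2 <- vf_loglik_bruteforce_fn(d2, tab2)
    expect_equal(coef(fit2)[["exposure"]], grid_argmax(ll2),
                 tolerance = 2e-3)
  }
})

test_that("confounder-adjusted fit matches enumeration over (x, z) pairs", {
  # the confounder-given-exposure factor is shared by all permutations of a
  # case's (x, z) pairs, so the fit must not depend on f0 and f1; the
  # oracle carries them explicitly
  pop <- cc_population(cycle_length = 3, exposed_days = c(1, 2),
                       n_control_periods = 2,
                       include_stopper = FALSE, include_starter = FALSE)
  tab <- cc_pattern_table(pop)
  set.seed(31)
  idx <- sample(1:3, 8, replace = TRUE)
  d <- cc_data(pop$exposure[idx, ],
               matrix(rbinom(8 * 3, 1, 0.4), 8, 3))
  fit <- cc_fit(d, "vf", patterns = tab, adjust_confounder = TRUE)
  for (f_pair in list(c(0.3, 0.6), c(0.1, 0.9))) {
    ll <- vf_loglik_bruteforce_fn(d, tab, f0 = f_pair[1L], f1 = f_pair[2L])
    # the enumerated likelihood must peak at the fitted point
    b_hat <- coef(fit)[["exposure"]]; g_hat <- coef(fit)[["confounder"]]
    for (db in c(-0.01, 0.01)) {
      expect_gt(ll(b_hat, g_hat), ll(b_hat + db, g_hat))
      expect_gt(ll(b_hat, g_hat), ll(b_hat, g_hat + db))
    }
  }
})

test_that("global exchangeability makes the fit equal conditional logistic", {
  for (seed in 1:3) {
    d <- rand_cc_data(40, 4, seed = seed, multiplicity = TRUE, p = 0.3)
    tab <- ccxover:::iid_patterns(5L, p = 0.3)
    expect_equal(coef(cc_fit(d, "vf", patterns = tab))[["exposure"]],
                 coef(cc_fit(d, "scl"))[["exposure"]],
                 tolerance = 1e-7)
  }
})

test_that("positivity failure across all cases raises the dedicated error", {
  for (M in c(7L, 10L, 14L, 17L, 21L)) {
    pop <- cc_population(n_control_periods = M)
    d <- cc_expected_cases(pop)
    expect_error(cc_fit(d, "vf", patterns = cc_pattern_table(pop)),
                 class = "cc_no_informative_cases")
  }
})

test_that("partial positivity failures are excluded and reported", {
  # support only covers k = 1 with both case-period classes; a case with
  # k = 2 exposed periods is non-informative
  tab <- cc_patterns(c("100", "010", "110"), c(0.3, 0.3, 0.4))
  d <- cc_data(rbind(c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)))
  fit <- cc_fit(d, "vf", patterns = tab)
  expect_equal(fit$n_informative, 2L)
  expect_match(paste(fit$diagnostics, collapse = " "), "positivity")
})

test_that("sequence length must match the dataset", {
  d <- rand_cc_data(5, 3, seed = 1)
  expect_error(cc_fit(d, "vf", patterns = ccxover:::iid_patterns(3L)),
               "length")
})
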