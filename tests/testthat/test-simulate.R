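test_that("default cyclic population has 8 stationary subgroups", {
  pop <- cc_population()
  expect_equal(nrow(pop$exposure), 8L)
  expect_equal(ncol(pop$exposure), 22L)
  # exposed fraction exactly 1/4 on every day
  expect_equal(unname(colMeans(pop$exposure)), rep(0.25, 22))
  # exactly 2 subgroups exposed at the case period
  expect_equal(sum(pop$exposure[, 1L]), 2L)
  # stopper unexposed at m = 0, cyclic controls; starter the reverse
  expect_equal(pop$exposure[1L, 1L], 0L)
  expect_equal(unname(pop$exposure[8L, ]), c(1L, rep(0L, 21)))
})

test_that("stationarity holds for the extended study periods too", {
  for (M in c(69L, 139L)) {
    pop <- cc_population(n_control_periods = M)
    expect_equal(unname(colMeans(pop$exposure)), rep(0.25, M + 1L))
  }
})

test_that("pairwise exchangeability holds exactly in every control period", {
  for (M in c(1L, 5L, 21L)) {
    pop <- cc_population(n_control_periods = M)
    x0 <- pop$exposure[, 1L]
    for (m in seq_len(M) + 1L) {
      xm <- pop$exposure[, m]
      expect_equal(sum(pop$size[x0 == 1L & xm == 0L]),
                   sum(pop$size[x0 == 0L & xm == 1L]))
    }
  }
})

test_that("the 3-day-cycle population gives the three known patterns", {
  pop <- cc_population(cycle_length = 3, exposed_days = c(1, 2),
                       n_control_periods = 3,
                       include_stopper = FALSE, include_starter = FALSE)
  seqs <- apply(pop$exposure, 1L, paste, collapse = "")
  expect_setequal(seqs, c("1101", "1011", "0110"))
})

test_that("one-sided churn breaks stationarity and is refused", {
  expect_error(cc_population(include_stopper = TRUE, include_starter = FALSE),
               "stationary")
  expect_error(cc_population(include_stopper = FALSE, include_starter = TRUE),
               "stationary")
  expect_error(cc_population(exposed_days = 1:7), "unexposed")
})

test_that("expected case counts follow the case-period exposure only", {
  pop <- cc_population()
  d <- cc_expected_cases(pop)
  expect_equal(sum(d$multiplicity), 140L)
  expect_equal(sort(unique(d$multiplicity)), c(10L, 40L))
  expect_equal(sum(d$multiplicity == 40L), 2L)
  # null effect: every subgroup contributes N * r0 cases
  d0 <- cc_expected_cases(pop, rr = 1)
  expect_equal(d0$multiplicity, rep(10L, 8L))
  # longer histories keep the same multiplicities
  d69 <- cc_expected_cases(cc_population(n_control_periods = 69))
  expect_equal(sort(d69$multiplicity), sort(d$multiplicity))
  expect_equal(d69$M, 69L)
  # non-integer expected counts are refused with advice
  expect_error(cc_expected_cases(pop, r0 = 0.00101), "not an integer")
})

test_that("confounder scenario has 184 cases in the documented strata", {
  pop <- cc_population()
  d <- cc_expected_cases_confounded(pop, seed = 3)
  expect_equal(sum(d$multiplicity), 184L)
  x0 <- d$exposure[, 1L]
  z0 <- d$confounder[, 1L]
  # per exposed-at-case subgroup: (z0 = 0, z0 = 1) = (24, 32); per
  # unexposed-at-case subgroup: (8, 4)
  expect_equal(sum(x0 == 1L & z0 == 0L), 2L * 24L)
  expect_equal(sum(x0 == 1L & z0 == 1L), 2L * 32L)
  expect_equal(sum(x0 == 0L & z0 == 0L), 6L * 8L)
  expect_equal(sum(x0 == 0L & z0 == 1L), 6L * 4L)
  # confounder null recovers the exposure-only totals
  d0 <- cc_expected_cases_confounded(pop, rr_z = 1, f0 = 0.2, f1 = 0.2,
                                     seed = 3)
  expect_equal(sum(d0$multiplicity), 140L)
})

test_that("confounder draws are seed-deterministic", {
  pop <- cc_population(n_control_periods = 5)
  a <- cc_expected_cases_confounded(pop, seed = 11)
  b <- cc_expected_cases_confounded(pop, seed = 11)
  c_ <- cc_expected_cases_confounded(pop, seed = 12)
  expect_identical(a, b)
  expect_identical(a$exposure, c_$exposure)
  expect_false(identical(a$confounder, c_$confounder))
})

test_that("control-period confounder frequencies converge to f1 and f0", {
  pop <- cc_population()
  d <- cc_expected_cases_confounded(pop, seed = 21)
  ctrl_x <- d$exposure[, -1L]
  ctrl_z <- d$confounder[, -1L]
  for (x_val in 0:1) {
    f <- if (x_val == 1L) 0.4 else 0.2
    n <- sum(ctrl_x == x_val)
    p_hat <- mean(ctrl_z[ctrl_x == x_val])
    expect_lt(abs(p_hat - f), 3 * sqrt(f * (1 - f) / n))
  }
})

test_that("pattern tables carry population shares", {
  tab <- cc_pattern_table(cc_population())
  expect_equal(nrow(tab), 8L)
  expect_equal(tab$probability, rep(1 / 8, 8))
  mot <- cc_pattern_table(cc_population(cycle_length = 3,
                                        exposed_days = c(1, 2),
                                        n_control_periods = 3,
                                        include_stopper = FALSE,
                                        include_starter = FALSE))
  expect_equal(mot$probability, rep(1 / 3, 3))
  # unequal subgroup sizes give proportional probabilities
  pop <- cc_population(cycle_length = 3, exposed_days = c(1, 2),
                       n_control_periods = 3,
                       include_stopper = FALSE, include_starter = FALSE)
  pop$size <- c(2000L, 1000L, 1000L)
  tab2 <- cc_pattern_table(pop)
  expect_setequal(tab2$probability, c(0.5, 0.25, 0.25))
})
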