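test_that("weighting method closed form matches the toy arithmetic", {
  fit <- cc_fit(toy3(), "greenland")
  expect_equal(fit$or, 3)           # (a1/a0) / pi10 = (2/1) * (3/2)
  expect_equal(fit$pi10, 2 / 3)
  expect_equal(unname(vcov(fit)[1L, 1L]), 1 / 1 + 1 / 2)
  mh <- cc_fit(toy3(), "mh")
  expect_equal(mh$or, 3)            # sum PT10 / sum PT01 = 3 / 1
})

test_that("weighting-method and Mantel-Haenszel point estimates coincide", {
  for (seed in 1:8) {
    d <- rand_cc_data(20, 2L + (seed %% 5L), seed = seed, multiplicity = TRUE)
    g <- cc_fit(d, "greenland")
    mh <- cc_fit(d, "mh")
    expect_equal(g$or, mh$or, tolerance = 1e-10)
    # the weighted-likelihood route agrees with the closed form
    expect_equal(g$beta_weighted_fit, coef(g)[["exposure"]],
                 tolerance = 1e-6)
  }
})

test_that("all three estimators collapse to a1/a0 at M = 1", {
  d <- rand_cc_data(60, 1, seed = 13, multiplicity = TRUE)
  s <- cc_discordance(d)
  target <- s$a1 / s$a0
  expect_equal(cc_fit(d, "scl")$or, target, tolerance = 1e-9)
  expect_equal(cc_fit(d, "mh")$or, target)
  expect_equal(cc_fit(d, "greenland")$or, target)
  # and the matched-pair variance 1/a1 + 1/a0 is reproduced by both routes
  expect_equal(unname(vcov(cc_fit(d, "mh"))[1L, 1L]), 1 / s$a1 + 1 / s$a0)
  expect_equal(unname(vcov(cc_fit(d, "greenland"))[1L, 1L]),
               1 / s$a1 + 1 / s$a0)
})

test_that("unit weights in the weighted likelihood reproduce the standard fit", {
  d <- rand_cc_data(25, 4, seed = 6)
  p <- d$M + 1L
  U <- matrix(as.numeric(t(d$exposure)), ncol = 1L)
  case <- rep(seq_len(nrow(d$exposure)), each = p)
  is_case_row <- rep(c(TRUE, rep(FALSE, p - 1L)), nrow(d$exposure))
  nr <- ccxover:::nr_clogit(U, case, is_case_row,
                            offset = numeric(nrow(U)),
                            mult = d$multiplicity)
  expect_equal(nr$theta[1L], coef(cc_fit(d, "scl"))[["exposure"]],
               tolerance = 1e-8)
})

test_that("degenerate discordance propagates to weights and fits", {
  d <- cc_data(rbind(c(1, 0, 1), c(1, 1, 0), c(1, 1, 1)))  # a0 = 0
  expect_error(cc_fit(d, "greenland"), "degenerate")
  expect_error(cc_weights(d), "degenerate")
})

test_that("one-sided person-time yields an unbounded Mantel-Haenszel estimate", {
  d <- cc_data(rbind(c(1, 0, 1), c(1, 1, 0), c(0, 0, 0)))
  fit <- cc_fit(d, "mh")
  expect_equal(fit$or, Inf)
  expect_match(paste(fit$diagnostics, collapse = " "), "unbounded")
})

test_that("null data give an odds ratio of one", {
  # a1 = a0 and pi10 = 1 by symmetry
  d <- cc_data(rbind(c(1, 0, 1, 0), c(0, 1, 0, 1)))
  expect_equal(cc_fit(d, "greenland")$or, 1)
  expect_equal(cc_fit(d, "mh")$or, 1)
})

test_that("Maclure stratification deletes confounder-discordant control periods", {
  x <- rbind(c(1, 0, 1, 0), c(0, 1, 1, 0), c(1, 0, 0, 1))
  z <- rbind(c(1, 1, 0, 1), c(0, 0, 1, 0), c(0, 0, 0, 0))
  d <- cc_data(x, z)
  fit <- cc_fit(d, "mh", stratify_by_confounder = TRUE)
  # case 1 (z0 = 1) keeps controls m = 1, 3 -> exposed 0, unexposed 2
  # case 2 (z0 = 0) keeps controls m = 1, 3 -> exposed 1 (m=3? no: x=(1,1,0) at m=1..3, z=(0,1,0): keeps m=1,3 -> exposed x_m1=1, x_m3=0)
  # case 3 (z0 = 0) keeps all controls   -> exposed 1, unexposed 2
  # MH = sum a_i d_i / n_i over x0 = 1 vs sum b_i c_i / n_i over x0 = 0
  R <- 1 * 2 / 3 + 2 / 4          # cases 1 and 3
  S <- 1 * 1 / 3                  # case 2
  expect_equal(fit$or, R / S)
  expect_true(fit$stratified)
})
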