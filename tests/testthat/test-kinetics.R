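test_that("no sperm means no fertilization in every evaluator", {
  p <- default_params()
  expect_equal(normal_fraction(p, 0), 0)
  expect_equal(monospermy_limit(p, 0), 0)
  ode <- outcome_fractions_ode(p, 0)
  expect_equal(ode$frac_unfert, 1)
  expect_equal(ode$frac_normal, 0)
})

test_that("quadrature matches the ODE oracle", {
  S0 <- c(10, 1e3, 1e4, 1e5)
  for (beta in c(1e-4, 3e-4)) {
    for (delta in c(0.05, 0.5)) {
      p <- kinetics_params(beta, 0.05, delta)
      q <- normal_fraction(p, S0)
      o <- outcome_fractions_ode(p, S0)$frac_normal
      expect_lt(max(abs(q - o) / pmax(o, 1e-12)), 1e-6)
    }
  }
})

test_that("instant polyspermy block recovers the monospermy closed form", {
  p <- kinetics_params(1e-4, 0.05, 1e6)
  S0 <- 10^seq(0, 6)
  # a tiny genuine gap of order beta*gamma*S0/delta remains (second hits
  # during the vanishing pre-block window), so the comparison is not exact
  expect_equal(normal_fraction(p, S0), monospermy_limit(p, S0),
               tolerance = 1e-4)
  # monospermy limit bounds normal fertilization for any finite block rate
  for (delta in c(0.05, 0.2, 1)) {
    pf <- kinetics_params(1e-4, 0.05, delta)
    expect_true(all(normal_fraction(pf, S0) <=
                      monospermy_limit(pf, S0) + 1e-10))
  }
})

test_that("outcome fractions conserve mass and behave at the delta extremes", {
  S0 <- 10^seq(0, 6, length.out = 10)
  grid <- expand.grid(beta = c(1e-4, 5e-4), delta = c(0.05, 0.5),
                      gamma = c(0.01, 0.1))
  for (i in seq_len(nrow(grid))) {
    p <- kinetics_params(grid$beta[i], grid$gamma[i], grid$delta[i])
    oc <- outcome_fractions_ode(p, S0)
    expect_lt(max(abs(rowSums(oc[, -1]) - 1)), 1e-8)
    # polyspermy accumulates with sperm availability
    expect_true(all(diff(oc$frac_polyspermic) > -1e-10))
    # closed-form fast path agrees with the ODE
    cf <- outcome_fractions(p, S0)
    expect_equal(cf$frac_unfert, oc$frac_unfert, tolerance = 1e-8)
    expect_equal(cf$frac_pending, oc$frac_pending, tolerance = 1e-6)
  }
  # a block rate of zero leaves nothing scored normal
  p0 <- list(beta = 3e-4, gamma = 0.05, delta = 0, r = 3e-4,
             E_T = 1000 / 23000, t = 30)
  class(p0) <- "kinetics_params"
  expect_true(all(outcome_fractions_ode(p0, c(10, 1e4))$frac_normal == 0))
})

test_that("normal fertilization is unimodal in sperm concentration", {
  p <- default_params()
  S0 <- 10^seq(-1, 7, length.out = 60)
  y <- normal_fraction(p, S0)
  i_peak <- which.max(y)
  expect_gt(i_peak, 1)
  expect_lt(i_peak, length(S0))
  expect_true(all(diff(y[1:i_peak]) > -1e-12))
  expect_true(all(diff(y[i_peak:length(S0)]) < 1e-12))
})

test_that("sperm decay is negligible over the 30 s contact window", {
  S0 <- 10^seq(0, 6)
  p_r <- default_params()
  p_0 <- kinetics_params(3e-4, 0.05, 0.2, r = 0)
  y_r <- normal_fraction(p_r, S0)
  y_0 <- normal_fraction(p_0, S0)
  # the decay factor shifts the integrated sperm exposure by ~0.4%, which
  # is < 1e-3 on the scale of the fertilized fraction itself
  expect_lt(max(abs(y_r - y_0)), 1e-3)
  expect_lt(max(abs(y_r - y_0) / pmax(y_r, 1e-12)), 5e-3)
  # algebraic long-time limit of the monospermy exponent with r = 0
  p_long <- kinetics_params(3e-4, 0.05, 0.2, r = 0, t = 1e7)
  expect_equal(monospermy_limit(p_long, 100),
               1 - exp(-3e-4 * 0.05 * 100 / (3e-4 * (1000 / 23000))),
               tolerance = 1e-4)
})

test_that("parameter validation rejects out-of-range inputs", {
  expect_error(kinetics_params(-1e-4, 0.05, 0.2), "positive")
  expect_error(kinetics_params(1e-4, 0.5, 0.2), "gamma")
  expect_error(kinetics_params(1e-4, 0.05, 0.2, r = -1), "r must")
  expect_error(normal_fraction(default_params(), -5), "S0")
})
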