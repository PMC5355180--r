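test_that("design expansion matches the study layout", {
  d <- generate_design(sim_config())
  expect_equal(nrow(d), (12 + 10 + 12) * 3 * 8)
  expect_equal(length(unique(d$pair_id[d$site == "BMR"])), 10)
  d1 <- generate_design(sim_config(sites = c(FC = 1),
                                   treatments_by_site = list(FC = "8.03")))
  expect_equal(nrow(d1), 8)
  d4 <- generate_design(sim_config(sites = c(FC = 1),
                                   treatments_by_site = list(FC = "8.03"),
                                   n_steps = 4))
  expect_equal(log10(max(d4$sperm_conc) / min(d4$sperm_conc)), 3)
})

test_that("simulation is deterministic given the seed", {
  a <- simulate_trials(sim_config(sites = c(FC = 2),
                                  treatments_by_site = list(FC = c("8.03", "7.61"))),
                       seed = 99)
  b <- simulate_trials(sim_config(sites = c(FC = 2),
                                  treatments_by_site = list(FC = c("8.03", "7.61"))),
                       seed = 99)
  expect_identical(a$trials, b$trials)
  expect_identical(a$truth, b$truth)
  expect_error(simulate_trials(sim_config()), "seed")
})

test_that("beta-binomial sampler has the stated moments and boundaries", {
  expect_true(all(rbetabinom(200, 0, 50, size = 100) == 0))
  expect_true(all(rbetabinom(200, 1, 50, size = 100) == 200))
  expect_error(rbetabinom(200, 1.2, 50), "p must")
  expect_error(rbetabinom(200, 0.5, -1), "lambda")

  set.seed(7)
  x <- rbetabinom(200, 0.4, 50, size = 1e5)
  expect_equal(mean(x), 200 * 0.4, tolerance = 0.01)
  v_expected <- 200 * 0.4 * 0.6 * (1 + 199 / 51)
  expect_equal(var(x), v_expected, tolerance = 0.05)
})

test_that("huge precision approaches binomial scoring variance", {
  set.seed(8)
  x <- rbetabinom(200, 0.4, 1e6, size = 1e4)
  expect_equal(var(x) / (200 * 0.4 * 0.6), 1, tolerance = 0.05)
  # and the beta-binomial log-likelihood converges to the binomial one
  # over the plausible data range (mean +/- 3 sd)
  sdv <- sqrt(200 * 0.4 * 0.6)
  k <- seq(ceiling(80 - 3 * sdv), floor(80 + 3 * sdv))
  d1 <- dbetabinom_log(k, 200, 0.4, 1e6)
  d2 <- dbinom(k, 200, 0.4, log = TRUE)
  expect_lt(max(abs(d1 - d2)), 1e-3)
})

test_that("simulated counts partition the scored eggs and track the kinetics curve", {
  sim <- small_sim(seed = 5)
  tr <- sim$trials
  expect_true(all(tr$n_unfert + tr$n_tight + tr$n_abn_dev <= tr$n_scored))
  expect_true(all(tr$n_scored == 200))

  # mean TF rises with sperm concentration below the polyspermy peak
  tf <- (tr$n_scored - tr$n_unfert) / tr$n_scored
  mean_tf <- tapply(tf, tr$vial_index, mean)
  expect_true(all(diff(rev(mean_tf)) > -0.02))

  # probabilities attached to the truth table are valid
  probs <- attr(sim$truth, "vial_probs")
  expect_true(all(probs >= 0 & probs <= 1))
  expect_equal(rowSums(probs), rep(1, nrow(probs)), tolerance = 1e-9)
})

test_that("the tight-membrane split is a nuisance for scored proportions", {
  cfg1 <- sim_config(sites = c(SB = 4),
                     treatments_by_site = list(SB = c("8.03", "7.76")),
                     tight_fraction = 0.2)
  cfg2 <- sim_config(sites = c(SB = 4),
                     treatments_by_site = list(SB = c("8.03", "7.76")),
                     tight_fraction = 0.8)
  s1 <- score_trials(simulate_trials(cfg1, seed = 31)$trials)
  s2 <- score_trials(simulate_trials(cfg2, seed = 31)$trials)
  # same seed, same underlying fertilization and abnormality draws:
  # TF and AbnF are unchanged by how abnormal eggs split between categories
  expect_equal(s1$tf, s2$tf)
  expect_equal(s1$abnf, s2$abnf)
  expect_equal(s1$nf, s2$nf)
  expect_false(identical(s1$n_tight, s2$n_tight))
})
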