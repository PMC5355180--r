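fake_fit <- function(draws_by_chain) {
  structure(list(chains = draws_by_chain), class = "hier_fit")
}

test_that("decline summary is the stated deterministic transform", {
  n <- 200
  ref <- rnorm(n, log(3e-4), 0.1)
  draws <- cbind(`mu_beta[SB:8.03]` = ref,
                 `mu_beta[SB:7.76]` = ref + log(0.54))
  fit <- fake_fit(list(draws))
  d <- decline_summary(fit, "SB", "7.76", "8.03")
  expect_equal(d$decline_pct, 46)
  expect_equal(d$lo95, 46)
  expect_equal(d$hi95, 46)
  expect_equal(d$pr_decline, 1)

  # identical draws in both cells: no decline, ties counted half
  same <- cbind(`mu_beta[SB:8.03]` = ref, `mu_beta[SB:7.76]` = ref)
  d0 <- decline_summary(fake_fit(list(same)), "SB", "7.76", "8.03")
  expect_equal(d0$decline_pct, 0)
  expect_equal(d0$pr_decline, 0.5)

  expect_error(decline_summary(fit, "SB", "7.61", "8.03"), "not in posterior")
})

test_that("convergence diagnostics separate mixed from stuck chains", {
  set.seed(2)
  good <- lapply(1:2, function(i)
    cbind(a = rnorm(500), b = rnorm(500, 2, 0.5)))
  cg <- convergence_check(good)
  expect_lt(cg$max_rhat, 1.02)
  expect_true(cg$pass)

  bad <- list(cbind(a = rnorm(500, 0)), cbind(a = rnorm(500, 5)))
  cb <- convergence_check(bad)
  expect_gt(cb$max_rhat, 1.5)
  expect_false(cb$pass)

  expect_error(convergence_check(list(cbind(a = rnorm(100)))), "2 chains")
})

test_that("hierarchical fit runs, is seed-reproducible and order invariant", {
  cfg <- sim_config(sites = c(SB = 3),
                    treatments_by_site = list(SB = c("8.03", "7.76")))
  trials <- simulate_trials(cfg, seed = 4)$trials
  hc <- hier_config(chains = 2, warmup = 120, iter = 100)
  fit1 <- fit_hierarchical(trials, hc, seed = 11)
  expect_s3_class(fit1, "hier_fit")
  expect_true(all(c("mean", "median", "lo95", "hi95") %in%
                    names(fit1$summary)))
  expect_true(all(fit1$summary$lo95 <= fit1$summary$median + 1e-12))
  expect_true(all(fit1$summary$median <= fit1$summary$hi95 + 1e-12))
  expect_true(is.logical(fit1$flagged))
  # every population parameter carries a diagnostic row
  expect_setequal(
    fit1$diagnostics$table$parameter,
    c(paste0("mu_beta[SB:", c("7.76", "8.03"), "]"),
      paste0("mu_delta[SB:", c("7.76", "8.03"), "]"),
      paste0("mu_gamma[SB:", c("7.76", "8.03"), "]"),
      "sigma_beta", "sigma_delta",
      paste0("sigma_gamma[SB:", c("7.76", "8.03"), "]"), "lambda"))

  fit2 <- fit_hierarchical(trials, hc, seed = 11)
  expect_identical(fit1$chains, fit2$chains)

  # permuting vial rows leaves the posterior draws unchanged
  perm <- sample(nrow(trials))
  fit3 <- fit_hierarchical(trials[perm, ], hc, seed = 11)
  expect_identical(fit1$chains, fit3$chains)
})

test_that("fit preconditions are enforced", {
  cfg <- sim_config(sites = c(SB = 1),
                    treatments_by_site = list(SB = "8.03"))
  trials <- simulate_trials(cfg, seed = 4)$trials
  expect_error(fit_hierarchical(trials, hier_config(), seed = 1),
               ">= 2 pairs")
  expect_error(hier_config(chains = 1), "2 chains")
})
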