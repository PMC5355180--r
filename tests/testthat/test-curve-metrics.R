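test_that("metric solver matches closed forms on constructed curves", {
  # ascending linear logit TF, no abnormality: S_NF50 = 10^(-a/b)
  a <- -4; b <- 1.5
  tf <- fake_curve("pooled", list(c(a, b, 0, 0)))
  abn <- fake_curve("pooled", list(c(-30, 0, 0, 0)))
  m <- solve_metrics(tf, abn, xrange_nf = c(0, 6))
  s50 <- m[m$metric == "S_NF50", ]
  expect_equal(s50$log10_conc, -a / b, tolerance = 1e-6)
  expect_equal(s50$sperm_conc, 10^(-a / b), tolerance = 1e-5)

  # flat 10% abnormality never reaches 25%
  abn10 <- fake_curve("pooled", list(c(qlogis(0.1), 0, 0, 0)))
  m2 <- solve_metrics(tf, abn10)
  expect_false(m2$attainable[m2$metric == "S_AbnF25"])
  expect_true(is.na(m2$log10_conc[m2$metric == "S_AbnF25"]))

  # unimodal NF from rising TF and rising AbnF: optimum matches a dense grid
  tf2 <- fake_curve("pooled", list(c(-6, 2.4, 0, 0)))
  abn2 <- fake_curve("pooled", list(c(-12, 2.4, 0, 0)))
  m3 <- solve_metrics(tf2, abn2, xrange_nf = c(0, 8))
  xg <- seq(0, 8, length.out = 2e5)
  nf <- plogis(-6 + 2.4 * xg) * (1 - plogis(-12 + 2.4 * xg))
  expect_equal(m3$log10_conc[m3$metric == "S_OptNF"], xg[which.max(nf)],
               tolerance = 1e-3)
  expect_equal(m3$level[m3$metric == "S_OptNF"], max(nf), tolerance = 1e-6)
})

test_that("metrics are equivariant to a change of concentration units", {
  tf <- fake_curve("pooled", list(c(-4, 1.5, -0.02, 0.001)))
  abn <- fake_curve("pooled", list(c(-8, 1.2, 0, 0)))
  m1 <- solve_metrics(tf, abn, xrange_nf = c(0, 6), xrange_abnf = c(0, 8))
  # per-ml instead of per-ul concentrations shift log10 by exactly 3:
  # encode by shifting the polynomial's center
  tf2 <- tf; tf2$center <- tf$center + 3
  abn2 <- abn; abn2$center <- abn$center + 3
  m2 <- solve_metrics(tf2, abn2, xrange_nf = c(3, 9), xrange_abnf = c(3, 11))
  expect_equal(m2$log10_conc, m1$log10_conc + 3, tolerance = 1e-6)
})

test_that("NF never exceeds TF across random cubic curves", {
  set.seed(21)
  xg <- seq(0, 6, length.out = 200)
  for (i in 1:20) {
    ctf <- rnorm(4, c(-3, 1.5, 0, 0), c(1, 0.5, 0.2, 0.05))
    cab <- rnorm(4, c(-6, 1, 0, 0), c(1, 0.5, 0.2, 0.05))
    tf_v <- plogis(ctf[1] + ctf[2] * xg + ctf[3] * xg^2 + ctf[4] * xg^3)
    ab_v <- plogis(cab[1] + cab[2] * xg + cab[3] * xg^2 + cab[4] * xg^3)
    expect_true(all(tf_v * (1 - ab_v) <= tf_v))
  }
})

test_that("glm fit recovers a known cubic logit curve", {
  set.seed(3)
  cfg <- sim_config(sites = c(SB = 6),
                    treatments_by_site = list(SB = c("8.03", "7.87", "7.76")))
  trials <- simulate_trials(cfg, seed = 3)$trials
  dat <- glmm_prepare(trials, glmm_spec("tf"))
  truth <- c(0.5, 2.2, -0.4, -0.35)
  eta <- truth[1] + truth[2] * dat$xs1 + truth[3] * dat$xs2 +
    truth[4] * dat$xs3
  dat$n_unfert <- rbinom(nrow(dat), dat$n_scored,
                         1 - plogis(eta))
  dat$n_tight <- 0L
  dat$n_abn_dev <- 0L
  fit <- fit_glmm(dat[names(trials)],
                  glmm_spec("tf", random = FALSE, pooled = TRUE))
  est <- fit$coef
  # joint 3-standard-error check against the generating coefficients
  z <- (est - truth) / sqrt(diag(fit$vcov))
  expect_true(all(abs(z) < 3))
})

test_that("mixed model recovers pair-level variation", {
  set.seed(14)
  cfg <- sim_config(sites = c(SB = 10),
                    treatments_by_site = list(SB = c("8.03", "7.87", "7.76")),
                    sigma_beta = 0.6, lambda = 1e5)
  trials <- simulate_trials(cfg, seed = 14)$trials
  fit <- fit_glmm(trials, glmm_spec("tf"))
  expect_true(fit$converged)
  # pair heterogeneity in beta must surface as pair-level logit variance
  expect_gt(fit$varcomp[["pair"]] + fit$varcomp[["pair_trt"]], 0.05)
  expect_true(all(eigen(fit$vcov, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-8))
})

test_that("constant responses are rejected as degenerate", {
  cfg <- sim_config(sites = c(SB = 2),
                    treatments_by_site = list(SB = c("8.03", "7.76")))
  trials <- simulate_trials(cfg, seed = 8)$trials
  trials$n_unfert <- 0L
  trials$n_tight <- 0L
  trials$n_abn_dev <- 0L
  expect_error(fit_glmm(trials, glmm_spec("tf")), "degenerate")
})

test_that("likelihood-ratio table mirrors the factorial testing scheme", {
  # the study layout: an incomplete factorial where each site sees only
  # three of the four treatment levels
  sim <- simulate_trials(sim_config(
    sites = c(FC = 2, BMR = 2, SB = 2),
    treatments_by_site = list(FC = c("8.03", "7.76", "7.61"),
                              BMR = c("8.03", "7.76", "7.61"),
                              SB = c("8.03", "7.87", "7.76"))), seed = 17)
  tab <- lrt_table(sim$trials, glmm_spec("tf", random = FALSE))
  expect_setequal(tab$source,
                  c("Sperm Conc.", "Site", "pH treatment", "Site x Sperm",
                    "pH x Sperm", "Site x pH", "Site x pH x Sperm"))
  expect_true(all(tab$chisq >= 0))
  expect_true(all(tab$df >= 1))
  expect_true(all(tab$p >= 0 & tab$p <= 1))
  # sperm concentration dominates fertilization in this design
  expect_lt(tab$p[tab$source == "Sperm Conc."], 1e-6)
  expect_equal(tab$df[tab$source == "Sperm Conc."], 3)
})

test_that("zero-covariance bootstrap collapses to the point estimates", {
  tf <- fake_curve(c("SB:8.03", "SB:7.76"),
                   list(c(-4, 1.5, 0, 0), c(-4.5, 1.5, 0, 0)))
  abn <- fake_curve(c("SB:8.03", "SB:7.76"),
                    list(c(-30, 0, 0, 0), c(-30, 0, 0, 0)))
  out <- bootstrap_contrasts(tf, abn, n_boot = 50, seed = 2)
  est <- out$estimates
  s50 <- est[est$metric == "S_NF50", ]
  expect_equal(s50$lo95, s50$sperm_conc, tolerance = 1e-8)
  expect_equal(s50$hi95, s50$sperm_conc, tolerance = 1e-8)
  expect_true(all(out$contrasts$p[out$contrasts$metric == "S_NF50"] == 1))
})

test_that("contrast p-values are symmetric under treatment relabeling", {
  set.seed(5)
  S <- diag(c(0.04, 0.01, 1e-4, 1e-6))
  tf_a <- fake_curve(c("SB:8.03", "SB:7.76"),
                     list(c(-4, 1.5, 0, 0), c(-4.6, 1.5, 0, 0)),
                     vcov = as.matrix(Matrix::bdiag(S, S)))
  abn <- fake_curve(c("SB:8.03", "SB:7.76"),
                    list(c(-30, 0, 0, 0), c(-30, 0, 0, 0)))
  out1 <- bootstrap_contrasts(tf_a, abn, n_boot = 400, seed = 9)
  # swap which cell carries which coefficients
  tf_b <- fake_curve(c("SB:8.03", "SB:7.76"),
                     list(c(-4.6, 1.5, 0, 0), c(-4, 1.5, 0, 0)),
                     vcov = as.matrix(Matrix::bdiag(S, S)))
  out2 <- bootstrap_contrasts(tf_b, abn, n_boot = 400, seed = 9)
  p1 <- out1$contrasts$p[out1$contrasts$metric == "S_NF50"]
  p2 <- out2$contrasts$p[out2$contrasts$metric == "S_NF50"]
  expect_lt(abs(p1 - p2), 0.1)
})

test_that("variance partition follows the logit-scale formula", {
  # fixed-effect variance 1, nothing else: marginal R2 = 1/(1 + pi^2/3)
  n <- 400
  dat_x <- seq(-sqrt(3), sqrt(3), length.out = n)   # variance ~ 1
  curve <- fake_curve("pooled", list(c(0, 1, 0, 0)))
  curve$data <- data.frame(xs1 = dat_x, xs2 = dat_x^2, xs3 = dat_x^3)
  curve$model <- stats::lm(rnorm(n) ~ 1 + xs1 + xs2 + xs3, data = curve$data)
  X <- stats::model.matrix(curve$model)
  vf <- as.numeric(var(X %*% curve$coef)) * (n - 1) / n
  vp <- variance_partition(curve)
  expect_equal(vp$r2_marginal, vf / (vf + pi^2 / 3), tolerance = 1e-10)
  expect_equal(vp$r2_conditional, vp$r2_marginal)

  # all-zero fixed effects explain nothing
  curve0 <- curve
  curve0$coef[] <- 0
  expect_equal(variance_partition(curve0)$r2_marginal, 0)

  # a random component equal to the fixed variance halves nothing but
  # enlarges the denominator by the same amount
  curve_r <- curve
  curve_r$varcomp <- c(pair = vf, pair_trt = 0, olre = 0)
  vp_r <- variance_partition(curve_r)
  expect_equal(vp_r$r2_marginal, vf / (2 * vf + pi^2 / 3), tolerance = 1e-10)
  expect_gt(vp_r$r2_conditional, vp_r$r2_marginal)

  expect_error(variance_partition(curve, fixed_subsets = list(bad = "nope")),
               "unknown coefficient")
})
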