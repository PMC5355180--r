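test_that("vial scoring follows the TF/AbnF/NF definitions", {
  s <- score_vial(vial_counts(200, 50, 10, 5))
  expect_equal(s$tf, 0.75)
  expect_equal(s$abnf, 0.10)
  expect_equal(s$nf, 0.675)
  expect_true(s$abnf_defined)

  # nothing fertilized: AbnF undefined, NF zero
  s0 <- score_vial(vial_counts(200, 200, 0, 0))
  expect_equal(s0$tf, 0)
  expect_true(is.na(s0$abnf))
  expect_false(s0$abnf_defined)
  expect_equal(s0$nf, 0)

  # everything normal
  s1 <- score_vial(vial_counts(100, 0, 0, 0))
  expect_equal(s1$tf, 1)
  expect_equal(s1$abnf, 0)
  expect_equal(s1$nf, 1)
})

test_that("scored proportions partition the vial and are scale invariant", {
  set.seed(11)
  for (i in 1:25) {
    n <- sample(50:400, 1)
    u <- sample(0:(n - 1), 1)
    rest <- n - u
    t <- sample(0:rest, 1)
    a <- sample(0:(rest - t), 1)
    s <- score_vial(vial_counts(n, u, t, a))
    # NF + TF*AbnF + (1 - TF) partitions all scored eggs
    expect_equal(s$nf + s$tf * s$abnf + (1 - s$tf), 1)
    s2 <- score_vial(vial_counts(3 * n, 3 * u, 3 * t, 3 * a))
    expect_equal(s$tf, s2$tf)
    expect_equal(s$abnf, s2$abnf)
    expect_equal(s$nf, s2$nf)
  }
})

test_that("inconsistent counts are rejected with the violated invariant named", {
  expect_error(vial_counts(200, 150, 40, 30), "partition")
  expect_error(vial_counts(200, -1, 0, 0), "non-negative")
  expect_error(vial_counts(200.5, 1, 0, 0), "integer")
})

test_that("serial dilution concentrations form the expected geometric series", {
  conc <- dilution_concentrations(2e6, n_steps = 8)
  expect_length(conc, 8)
  expect_equal(conc, 2e6 / 10^(1:8))
  expect_true(all(diff(conc) < 0))
  expect_equal(dilution_concentrations(2e6, n_steps = 1), 2e5)
  # the bench 2.3 ml into 23 ml transfer is exactly one 1:10 step
  expect_equal(dilution_concentrations(2e6, step_volume_ratio = 2.3 / 23),
               dilution_concentrations(2e6, step_volume_ratio = 1 / 10))
  expect_error(dilution_concentrations(-5), "positive")
  expect_error(dilution_concentrations(2e6, n_steps = 0), "n_steps")
})

test_that("analysis windows are open intervals and response specific", {
  rec <- data.frame(sperm_conc = c(0.5, 10, 1e5, 3e5))
  kept_tf <- filter_analysis_window(rec, "tf")
  expect_equal(kept_tf$sperm_conc, c(10, 1e5))
  kept_ab <- filter_analysis_window(rec, "abnf")
  expect_equal(kept_ab$sperm_conc, c(1e5, 3e5))
  # boundary values are excluded (strict inequalities)
  expect_equal(nrow(filter_analysis_window(
    data.frame(sperm_conc = c(1, 2e5)), "tf")), 0)
  expect_equal(nrow(filter_analysis_window(rec[0, , drop = FALSE], "tf")), 0)
  expect_error(filter_analysis_window(rec, "nf"))
  # output is a subset and filtering is idempotent
  expect_true(all(kept_tf$sperm_conc %in% rec$sperm_conc))
  expect_identical(filter_analysis_window(kept_tf, "tf"), kept_tf)
})

test_that("trial CSV round trips and validation names offending input", {
  sim <- simulate_trials(sim_config(), seed = 3)
  expect_equal(nrow(sim$trials), 816)
  path <- withr::local_tempfile(fileext = ".csv")
  write_trials(sim$trials, path)
  back <- load_trials(path)
  expect_equal(back, sim$trials, ignore_attr = TRUE)

  bad <- sim$trials
  bad$n_unfert <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(load_trials(path2), "n_unfert")

  bad2 <- sim$trials
  bad2$n_tight[5] <- bad2$n_scored[5] + 1
  expect_error(write_trials(bad2, path), "row")

  bad3 <- sim$trials
  bad3$site[1] <- "XX"
  expect_error(validate_trials(bad3), "site")
})
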