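# Simulated fertilization trials with the statistical structure the analyses
# assume: mechanistic outcome probabilities per vial, lognormal pair-level
# heterogeneity in beta and delta, truncated-normal gamma, and beta-binomial
# scoring overdispersion.

#' Default simulation configuration
#'
#' The default configuration mirrors the study design: three sites (FC 12
#' pairs, BMR 10, SB 12), three pH treatments per site, eight 1:10 serial
#' dilutions from a 2e6 sperm/ul hemocytometer stock, 1,000 eggs per vial in
#' 23 ml (E_T = 0.0435 eggs/ul), a 30 s contact window and 200 embryos
#' scored.  Truth values default to beta = 3e-4 ul/sperm/s, gamma = 0.05,
#' delta = 0.2 /s with lognormal/truncated-normal pair spreads of 0.3 (0.01
#' for gamma) and beta-binomial precision lambda = 100; these are generator
#' defaults calibrated so TF traverses 0 to 1 across the dilution series,
#' not published estimates.
#'
#' @param sites named integer vector of pairs per site.
#' @param treatments_by_site named list of treatment labels per site.
#' @param hemocytometer_count stock sperm concentration, per ul.
#' @param n_steps serial dilution steps.
#' @param eggs_per_vial eggs added per vial.
#' @param vial_volume_ul vial volume in ul used for egg concentration.
#' @param contact_time sperm-egg contact time, s.
#' @param n_scored embryos scored per vial.
#' @param beta,gamma,delta,r population-mean kinetics truth.
#' @param sigma_beta,sigma_delta,sigma_gamma pair-level spreads (log scale
#'   for beta and delta; natural scale for gamma).
#' @param lambda beta-binomial precision.
#' @param beta_scale named list site -> named numeric vector treatment ->
#'   multiplier on the population beta (e.g. a 0.54 multiplier encodes a 46%
#'   decline at that treatment); unlisted cells default to 1.
#' @param delta_scale as `beta_scale`, for delta.
#' @param tight_fraction fraction of polyspermic eggs scored as tight
#'   membrane rather than abnormal cleavage (nuisance split, default 0.5).
#' @param pending_as_normal score singly-fertilized unblocked eggs as normal
#'   (default TRUE, mirroring lab scoring of any raised envelope).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(sites = c(FC = 12, BMR = 10, SB = 12),
                       treatments_by_site = list(
                         FC = c("8.03", "7.76", "7.61"),
                         BMR = c("8.03", "7.76", "7.61"),
                         SB = c("8.03", "7.87", "7.76")),
                       hemocytometer_count = 2e6,
                       n_steps = 8,
                       eggs_per_vial = 1000,
                       vial_volume_ul = 23000,
                       contact_time = 30,
                       n_scored = 200,
                       beta = 3e-4, gamma = 0.05, delta = 0.2, r = 3e-4,
                       sigma_beta = 0.3, sigma_delta = 0.3,
                       sigma_gamma = 0.01,
                       lambda = 100,
                       beta_scale = list(), delta_scale = list(),
                       tight_fraction = 0.5,
                       pending_as_normal = TRUE) {
  stopifnot(all(sites >= 1), length(sites) >= 1,
            setequal(names(treatments_by_site), names(sites)),
            sigma_beta > 0, sigma_delta > 0, sigma_gamma > 0, lambda > 0,
            gamma > GAMMA_BOUNDS[1], gamma < GAMMA_BOUNDS[2],
            tight_fraction >= 0, tight_fraction <= 1)
  structure(list(sites = sites, treatments_by_site = treatments_by_site,
                 hemocytometer_count = hemocytometer_count, n_steps = n_steps,
                 eggs_per_vial = eggs_per_vial,
                 vial_volume_ul = vial_volume_ul,
                 contact_time = contact_time, n_scored = n_scored,
                 beta = beta, gamma = gamma, delta = delta, r = r,
                 sigma_beta = sigma_beta, sigma_delta = sigma_delta,
                 sigma_gamma = sigma_gamma, lambda = lambda,
                 beta_scale = beta_scale, delta_scale = delta_scale,
                 tight_fraction = tight_fraction,
                 pending_as_normal = pending_as_normal),
            class = "sim_config")
}

scale_for <- function(scales, site, treatment) {
  s <- scales[[site]]
  if (is.null(s) || is.na(s[treatment])) 1 else unname(s[treatment])
}

#' Expand a simulation configuration into the vial layout
#'
#' @param config a [sim_config()].
#' @return data frame with one row per vial: `site`, `pair_id`,
#'   `ph_treatment`, `ph_measured`, `vial_index`, `sperm_conc`.
#' @export
generate_design <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  conc <- dilution_concentrations(config$hemocytometer_count,
                                  n_steps = config$n_steps)
  rows <- list()
  for (site in names(config$sites)) {
    for (pair in seq_len(config$sites[[site]])) {
      for (trt in config$treatments_by_site[[site]]) {
        rows[[length(rows) + 1L]] <- data.frame(
          site = site, pair_id = sprintf("%s_p%02d", site, pair),
          ph_treatment = trt, ph_measured = as.numeric(trt),
          vial_index = seq_along(conc), sperm_conc = conc,
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, rows)
}

#' Draw a beta-binomial sample
#'
#' Count out of `n` with success probability `p` and precision `lambda`:
#' the per-draw probability is Beta(lambda p, lambda (1-p)), giving mean
#' `n p` and variance `n p (1-p) (1 + (n-1)/(lambda+1))`.
#'
#' @param n trials per draw (scalar or vector).
#' @param p success probability (recycled against `n`).
#' @param lambda precision; larger approaches binomial sampling.
#' @param size number of draws (default `max(length(n), length(p))`).
#' @return integer vector of counts.
#' @export
rbetabinom <- function(n, p, lambda, size = max(length(n), length(p))) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (lambda <= 0) stop("lambda must be positive")
  n <- rep_len(n, size); p <- rep_len(p, size)
  q <- numeric(size)
  inner <- p > 0 & p < 1
  q[inner] <- stats::rbeta(sum(inner), lambda * p[inner],
                           lambda * (1 - p[inner]))
  q[!inner] <- p[!inner]
  stats::rbinom(size, n, q)
}

#' Beta-binomial log-likelihood
#'
#' @param x observed counts.
#' @param n trials.
#' @param p mean probabilities (clamped to \[1e-9, 1-1e-9\]).
#' @param lambda precision.
#' @return vector of log-densities.
#' @export
dbetabinom_log <- function(x, n, p, lambda) {
  p <- pmin(pmax(p, 1e-9), 1 - 1e-9)
  a <- lambda * p; b <- lambda * (1 - p)
  lchoose(n, x) + lbeta(x + a, n - x + b) - lbeta(a, b)
}

#' Simulate a complete fertilization-trial dataset
#'
#' Draws pair-level kinetics parameters around the (optionally
#' treatment-scaled) population truth, computes each vial's outcome
#' fractions from the mechanistic model, maps them to the four scoring
#' categories, and samples overdispersed counts.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (mandatory; the generator is deterministic
#'   given config and seed).
#' @return list with `trials` (trial CSV schema plus nothing else) and
#'   `truth` (pair-level and population parameter table plus per-vial true
#'   category probabilities as attribute `vial_probs`).
#' @export
simulate_trials <- function(config = sim_config(), seed) {
  stopifnot(inherits(config, "sim_config"))
  if (missing(seed)) stop("seed is mandatory")
  set.seed(as.integer(seed))
  design <- generate_design(config)
  E_T <- config$eggs_per_vial / config$vial_volume_ul

  pairs <- unique(design[c("site", "pair_id", "ph_treatment")])
  truth_rows <- list()
  for (i in seq_len(nrow(pairs))) {
    site <- pairs$site[i]; trt <- pairs$ph_treatment[i]
    mu_b <- config$beta * scale_for(config$beta_scale, site, trt)
    mu_d <- config$delta * scale_for(config$delta_scale, site, trt)
    beta_i <- stats::rlnorm(1, log(mu_b), config$sigma_beta)
    delta_i <- stats::rlnorm(1, log(mu_d), config$sigma_delta)
    gamma_i <- rtruncnorm1(config$gamma, config$sigma_gamma,
                           GAMMA_BOUNDS[1], GAMMA_BOUNDS[2])
    truth_rows[[i]] <- data.frame(
      site = site, pair_id = pairs$pair_id[i], ph_treatment = trt,
      beta = beta_i, gamma = gamma_i, delta = delta_i,
      beta_pop = mu_b, gamma_pop = config$gamma, delta_pop = mu_d,
      stringsAsFactors = FALSE)
  }
  truth <- do.call(rbind, truth_rows)

  key <- paste(design$site, design$pair_id, design$ph_treatment)
  tkey <- paste(truth$site, truth$pair_id, truth$ph_treatment)
  idx <- match(key, tkey)
  if (anyNA(idx)) stop("truth table does not cover every design cell")

  probs <- matrix(NA_real_, nrow(design), 3,
                  dimnames = list(NULL, c("p_unfert", "p_normal", "p_abn")))
  for (j in unique(idx)) {
    rows <- which(idx == j)
    par <- kinetics_params(truth$beta[j], truth$gamma[j], truth$delta[j],
                           r = config$r, E_T = E_T, t = config$contact_time)
    oc <- outcome_fractions(par, design$sperm_conc[rows])
    normal <- oc$frac_normal +
      if (config$pending_as_normal) oc$frac_pending else 0
    probs[rows, ] <- cbind(oc$frac_unfert, normal,
                           pmax(1 - oc$frac_unfert - normal, 0))
  }

  n <- config$n_scored
  n_unfert <- rbetabinom(n, probs[, "p_unfert"], config$lambda)
  n_fert <- n - n_unfert
  p_abn_f <- ifelse(probs[, "p_unfert"] < 1 - 1e-12,
                    probs[, "p_abn"] / (1 - probs[, "p_unfert"]), 0)
  n_abn <- rbetabinom(n_fert, pmin(p_abn_f, 1), config$lambda)
  n_tight <- stats::rbinom(nrow(design), n_abn, config$tight_fraction)

  trials <- design
  trials$n_scored <- n
  trials$n_unfert <- n_unfert
  trials$n_tight <- n_tight
  trials$n_abn_dev <- n_abn - n_tight
  validate_trials(trials)
  attr(truth, "vial_probs") <- probs
  list(trials = trials, truth = truth)
}

# one truncated-normal draw by inversion
rtruncnorm1 <- function(mean, sd, lo, hi) {
  u <- stats::runif(1, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  stats::qnorm(u, mean, sd)
}
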