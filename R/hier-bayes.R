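# Hierarchical Bayesian estimation of site x pH-treatment fertilization
# kinetics from vial-level normal-fertilization counts.
#
# Hierarchy: for each site x treatment cell, population log-means mu_beta and
# mu_delta and a population gamma-mean mu_gamma; pair-level values
#   log beta_i ~ Normal(mu_beta, sigma_beta)       (lognormal beta)
#   log delta_i ~ Normal(mu_delta, sigma_delta)    (lognormal delta)
#   gamma_i ~ TruncNormal(mu_gamma, sigma_gamma) on (1e-4, 0.15)
# Observation model: normal count ~ BetaBinomial(n, lambda p, lambda (1-p))
# with p the mechanistic normal-fertilization probability of the vial.
#
# Sampler: Metropolis-within-Gibbs.  Population log-means are conjugate
# normal draws given the pair-level values.  Pair x treatment blocks are
# updated by joint random walks in (log(beta*gamma), log gamma, log delta)
# coordinates — the likelihood identifies the beta*gamma product, so the
# walk is aligned with the posterior ridge — batched into one vectorized
# forward-model evaluation per sweep.  The remaining flat direction (the
# whole gamma group sliding along the ridge with beta compensating) is
# sampled exactly by univariate slice sampling per gamma group.  Spread and
# precision parameters use cheap scalar Metropolis steps.  Proposal scales
# adapt during warmup only.

#' Configuration for the hierarchical kinetics fit
#'
#' @param chains number of MCMC chains (>= 2).
#' @param warmup adaptation iterations per chain (discarded).
#' @param iter retained iterations per chain.
#' @param prior_mu_beta,prior_mu_delta normal priors (mean, sd) on the
#'   population log-means.
#' @param prior_sigma_beta,prior_sigma_delta,prior_sigma_gamma half-normal
#'   prior scales on the pair-level spreads.
#' @param prior_lambda half-normal prior scale on the beta-binomial
#'   precision.
#' @param gamma_bounds truncation bounds for gamma.
#' @param share_gamma if `TRUE`, one gamma population mean per site (shared
#'   across treatments) instead of one per site x treatment cell.
#' @param sigma_gamma_shared if `TRUE`, a single gamma spread shared across
#'   all gamma groups; the default estimates one spread per group, which
#'   keeps the pair-level spread proportional to the group mean as the
#'   weakly identified gamma level is integrated over.
#' @param pending_as_normal include the singly-fertilized, not-yet-blocked
#'   class in the modelled normal probability (matches the default scoring
#'   convention of the simulator).
#' @param r,E_T,t fixed forward-model settings (sperm decay rate, egg
#'   concentration, contact time).
#' @param nodes Gauss-Legendre order for the forward model inside the
#'   likelihood.
#' @return list of class `hier_config`.
#' @export
hier_config <- function(chains = 2, warmup = 600, iter = 600,
                        prior_mu_beta = c(log(1e-4), 3),
                        prior_mu_delta = c(log(0.1), 3),
                        prior_sigma_beta = 1, prior_sigma_delta = 1,
                        prior_sigma_gamma = 0.05, prior_lambda = 500,
                        gamma_bounds = GAMMA_BOUNDS,
                        share_gamma = FALSE,
                        sigma_gamma_shared = FALSE,
                        pending_as_normal = TRUE,
                        r = 3e-4, E_T = 1000 / 23000, t = 30, nodes = 12) {
  if (chains < 2) stop("at least 2 chains are required")
  if (iter < 100) stop("iter must be >= 100")
  stopifnot(gamma_bounds[1] < gamma_bounds[2])
  structure(as.list(environment()), class = "hier_config")
}

# normal-fertilization probability for vials with per-vial parameter vectors
vial_normal_prob <- function(lb, lg, ld, S0, cfg) {
  beta <- exp(lb); gamma <- exp(lg); delta <- exp(ld)
  k <- beta * cfg$E_T + cfg$r
  p <- normal_fraction_gl(S0, beta, gamma, delta, k, cfg$t, cfg$nodes)
  if (cfg$pending_as_normal) {
    n <- length(S0)
    kv <- rep_len(k, n); dv <- rep_len(delta, n)
    bgS0 <- rep_len(beta * gamma, n) * S0
    sat <- (1 - exp(-kv * cfg$t)) / kv
    p <- p + bgS0 * block_kernel(cfg$t, kv, dv) * exp(-bgS0 * sat)
  }
  pmin(pmax(p, 0), 1)
}

log_dtnorm <- function(x, mean, sd, lo, hi) {
  ifelse(x <= lo | x >= hi, -Inf,
         stats::dnorm(x, mean, sd, log = TRUE) -
           log(stats::pnorm(hi, mean, sd) - stats::pnorm(lo, mean, sd)))
}

# univariate slice sampler (Neal 2003, stepping out + shrinkage);
# g is the log-density, x0 the current point with g0 = g(x0)
slice1 <- function(g, x0, g0, w = 1, max_step = 25) {
  y <- g0 - stats::rexp(1)
  lo <- x0 - w * stats::runif(1)
  hi <- lo + w
  steps <- 0
  while (g(lo) > y && steps < max_step) { lo <- lo - w; steps <- steps + 1 }
  steps <- 0
  while (g(hi) > y && steps < max_step) { hi <- hi + w; steps <- steps + 1 }
  repeat {
    x1 <- stats::runif(1, lo, hi)
    if (g(x1) > y) return(x1)
    if (x1 < x0) lo <- x1 else hi <- x1
  }
}

#' Fit the hierarchical kinetics model
#'
#' @param records trial data frame (trial CSV schema); normal counts are
#'   derived as `n_scored - n_unfert - n_tight - n_abn_dev`.
#' @param config a [hier_config()].
#' @param seed integer seed; the fit is deterministic given seed and
#'   settings.
#' @return object of class `hier_fit`: per-chain draw matrices, a
#'   `summary` data frame (posterior mean/median/95% CI for the population
#'   beta, delta, gamma of every site x treatment cell, spreads and lambda),
#'   pair-level posterior medians, convergence diagnostics and a `flagged`
#'   logical (TRUE when any split-Rhat of a population parameter
#'   exceeds 1.05).
#' @export
fit_hierarchical <- function(records, config = hier_config(), seed) {
  stopifnot(inherits(config, "hier_config"))
  if (missing(seed)) stop("seed is mandatory")
  validate_trials(records)
  records$n_normal <- records$n_scored - records$n_unfert -
    records$n_tight - records$n_abn_dev

  records$cell <- paste(records$site, records$ph_treatment, sep = ":")
  records$unit <- paste(records$cell, records$pair_id, sep = "/")
  cells <- sort(unique(records$cell))
  units <- sort(unique(records$unit))
  unit_cell <- vapply(units, function(u)
    records$cell[match(u, records$unit)], character(1))
  gcell_of <- function(cell)
    if (config$share_gamma) sub(":.*$", "", cell) else cell
  gcells <- sort(unique(gcell_of(cells)))
  unit_gcell <- gcell_of(unit_cell)
  sg_of <- if (config$sigma_gamma_shared) rep(1L, length(gcells))
  else seq_along(gcells)
  names(sg_of) <- gcells
  n_sg <- max(sg_of)
  sg_names <- if (n_sg == 1) "sigma_gamma"
  else paste0("sigma_gamma[", gcells, "]")
  if (any(table(unit_cell) < 2))
    stop("need >= 2 pairs per site x treatment cell")

  uidx <- match(records$unit, units)          # vial -> unit
  ord <- order(uidx, -records$sperm_conc)     # grouped by unit, stable order
  records <- records[ord, ]; uidx <- uidx[ord]
  S0 <- records$sperm_conc
  xn <- records$n_normal; nn <- records$n_scored
  n_units <- length(units)
  cellidx <- match(unit_cell, cells)
  lo <- config$gamma_bounds[1]; hi <- config$gamma_bounds[2]

  # crude data-driven initial beta*gamma per unit from the half-fertilization
  # vial (monospermy approximation)
  init_lprod <- vapply(seq_len(n_units), function(ui) {
    rows <- which(uidx == ui)
    tf <- 1 - records$n_unfert[rows] / records$n_scored[rows]
    i <- which.min(abs(tf - 0.5))
    tf_i <- min(max(tf[i], 0.02), 0.98)
    log(-log(1 - tf_i) / (S0[rows][i] * config$t))
  }, numeric(1))

  sum_by_unit <- function(v) as.vector(rowsum(v, uidx))

  run_chain <- function(chain_seed) {
    set.seed(chain_seed)
    lg <- rep(log(sqrt(lo * hi)), n_units) + stats::rnorm(n_units, 0, 0.1)
    lb <- init_lprod - lg + stats::rnorm(n_units, 0, 0.2)
    ld <- rep(log(0.2), n_units) + stats::rnorm(n_units, 0, 0.3)
    mu_b <- as.vector(tapply(lb, cellidx, mean))
    mu_d <- as.vector(tapply(ld, cellidx, mean))
    mu_g <- stats::setNames(rep(exp(mean(lg)), length(gcells)), gcells)
    sig_b <- 0.3; sig_d <- 0.3
    sig_g <- rep(0.02, n_sg)   # one spread per gamma group unless shared
    lambda <- 100

    p_vial <- vial_normal_prob(lb[uidx], lg[uidx], ld[uidx], S0, config)
    ll_vial <- dbetabinom_log(xn, nn, p_vial, lambda)

    unit_lprior <- function(lbv, lgv, ldv) {
      stats::dnorm(lbv, mu_b[cellidx], sig_b, log = TRUE) +
        stats::dnorm(ldv, mu_d[cellidx], sig_d, log = TRUE) +
        log_dtnorm(exp(lgv), mu_g[unit_gcell], sig_g[sg_of[unit_gcell]],
                   lo, hi) + lgv
    }

    s_prod <- rep(0.15, n_units); s_g <- rep(0.3, n_units)
    s_d <- rep(0.4, n_units)
    s_mug <- rep(0.01, length(gcells)); s_sig <- 0.25; s_lam <- 0.3
    s_alloc <- rep(0.3, length(gcells))
    total_iter <- config$warmup + config$iter
    keep <- matrix(NA_real_, config$iter,
                   2 * length(cells) + length(gcells) + 3 + n_sg +
                     3 * n_units)

    for (it in seq_len(total_iter)) {
      adapting <- it <= config$warmup
      gam <- if (adapting) min(0.25, 2 / sqrt(it)) else 0

      # --- batched joint update of every pair x treatment block ---
      dp <- stats::rnorm(n_units, 0, s_prod)
      dg <- stats::rnorm(n_units, 0, s_g)
      dd <- stats::rnorm(n_units, 0, s_d)
      lg_new <- lg + dg
      lb_new <- lb + dp - dg           # beta*gamma moves by dp only
      ld_new <- ld + dd
      lp_old <- unit_lprior(lb, lg, ld)
      lp_new <- unit_lprior(lb_new, lg_new, ld_new)
      p_new <- vial_normal_prob(lb_new[uidx], lg_new[uidx], ld_new[uidx],
                                S0, config)
      ll_new <- dbetabinom_log(xn, nn, p_new, lambda)
      logr <- sum_by_unit(ll_new) - sum_by_unit(ll_vial) + lp_new - lp_old
      acc <- is.finite(logr) & log(stats::runif(n_units)) < logr
      if (any(acc)) {
        lb[acc] <- lb_new[acc]; lg[acc] <- lg_new[acc]; ld[acc] <- ld_new[acc]
        vacc <- acc[uidx]
        p_vial[vacc] <- p_new[vacc]; ll_vial[vacc] <- ll_new[vacc]
      }
      if (adapting) {
        mult <- exp(gam * ((acc * 1) - 0.3))
        s_prod <- s_prod * mult; s_g <- s_g * mult; s_d <- s_d * mult
      }

      # --- conjugate normal updates for the population log-means ---
      for (ci in seq_along(cells)) {
        sel <- cellidx == ci
        for (w in c("b", "d")) {
          vals <- if (w == "b") lb[sel] else ld[sel]
          sig <- if (w == "b") sig_b else sig_d
          pri <- if (w == "b") config$prior_mu_beta else config$prior_mu_delta
          prec <- length(vals) / sig^2 + 1 / pri[2]^2
          mn <- (sum(vals) / sig^2 + pri[1] / pri[2]^2) / prec
          draw <- stats::rnorm(1, mn, sqrt(1 / prec))
          if (w == "b") mu_b[ci] <- draw else mu_d[ci] <- draw
        }
      }

      # --- gamma population means: random-walk MH, uniform prior ---
      for (gi in seq_along(gcells)) {
        sel <- unit_gcell == gcells[gi]
        prop <- mu_g[gi] + stats::rnorm(1, 0, s_mug[gi])
        macc <- FALSE
        if (prop > lo && prop < hi) {
          sgi <- sig_g[sg_of[gi]]
          logr <- sum(log_dtnorm(exp(lg[sel]), prop, sgi, lo, hi)) -
            sum(log_dtnorm(exp(lg[sel]), mu_g[gi], sgi, lo, hi))
          macc <- log(stats::runif(1)) < logr
          if (macc) mu_g[gi] <- prop
        }
        if (adapting) s_mug[gi] <- s_mug[gi] * exp(gam * ((macc * 1) - 0.4))
      }

      # the ridge and allocation moves below are the expensive part of the
      # sweep (each costs batched forward-model evaluations); running them
      # on alternate sweeps halves cost with little mixing loss
      do_ridge <- it %% 2L == 0L
      # --- exact slice sampling along the flat ridge of each gamma group:
      #     shift gamma_i, mu_gamma and (when no other group shares it)
      #     sigma_gamma by e^dl, compensate beta_i and the cell log-means by
      #     e^-dl; beta*gamma is invariant, the likelihood re-enters only
      #     through beta*E_T in the sperm-loss rate ---
      for (gi in if (do_ridge) seq_along(gcells) else integer(0)) {
        sel <- which(unit_gcell == gcells[gi])
        vsel <- which(uidx %in% sel)
        usub <- match(uidx[vsel], sel)
        ci_sel <- unique(cellidx[sel])
        owns_sig <- sum(sg_of == sg_of[gi]) == 1
        g_dl <- function(dl) {
          g_new <- exp(lg[sel] + dl)
          mu_g_new <- mu_g[gi] * exp(dl)
          sg_new <- if (owns_sig) sig_g[sg_of[gi]] * exp(dl)
          else sig_g[sg_of[gi]]
          if (any(g_new <= lo | g_new >= hi) || mu_g_new <= lo ||
              mu_g_new >= hi) return(-Inf)
          lbn <- lb[sel] - dl
          mbn <- mu_b[ci_sel] - dl
          pn <- vial_normal_prob(lbn[usub], lg[sel][usub] + dl,
                                 ld[sel][usub], S0[vsel], config)
          val <- sum(dbetabinom_log(xn[vsel], nn[vsel], pn, lambda)) +
            sum(log_dtnorm(g_new, mu_g_new, sg_new, lo, hi)) +
            (length(sel) + 1 + owns_sig) * dl +
            sum(stats::dnorm(mbn, config$prior_mu_beta[1],
                             config$prior_mu_beta[2], log = TRUE)) +
            sum(stats::dnorm(lbn, mbn[match(cellidx[sel], ci_sel)], sig_b,
                             log = TRUE))
          if (owns_sig)
            val <- val + stats::dnorm(sg_new, 0, config$prior_sigma_gamma,
                                      log = TRUE)
          val
        }
        dl <- slice1(g_dl, 0, g_dl(0), w = 2)
        if (dl != 0) {
          lg[sel] <- lg[sel] + dl; lb[sel] <- lb[sel] - dl
          mu_g[gi] <- mu_g[gi] * exp(dl); mu_b[ci_sel] <- mu_b[ci_sel] - dl
          if (owns_sig) sig_g[sg_of[gi]] <- sig_g[sg_of[gi]] * exp(dl)
          p_vial[vsel] <- vial_normal_prob(lb[uidx[vsel]], lg[uidx[vsel]],
                                           ld[uidx[vsel]], S0[vsel], config)
          ll_vial[vsel] <- dbetabinom_log(xn[vsel], nn[vsel], p_vial[vsel],
                                          lambda)
        }
      }

      # --- allocation move: the pair-to-pair spread can sit in beta or in
      #     gamma (products fixed); rescale the gamma residuals about the
      #     group mean by e^ds, co-scaling the group spread, and compensate
      #     each beta so every product is unchanged ---
      for (gi in if (do_ridge) seq_along(gcells) else integer(0)) {
        sel <- which(unit_gcell == gcells[gi])
        vsel <- which(uidx %in% sel)
        owns_sig <- sum(sg_of == sg_of[gi]) == 1
        ds <- stats::rnorm(1, 0, s_alloc[gi])
        ghat <- mu_g[gi]
        g_old <- exp(lg[sel])
        g_new <- ghat + (g_old - ghat) * exp(ds)
        sg_new <- if (owns_sig) sig_g[sg_of[gi]] * exp(ds) else
          sig_g[sg_of[gi]]
        aacc <- FALSE
        if (all(g_new > lo & g_new < hi)) {
          lg_new_sel <- log(g_new)
          lb_new_sel <- lb[sel] + lg[sel] - lg_new_sel
          pn <- vial_normal_prob(lb_new_sel[match(uidx[vsel], sel)],
                                 lg_new_sel[match(uidx[vsel], sel)],
                                 ld[uidx[vsel]], S0[vsel], config)
          lln <- dbetabinom_log(xn[vsel], nn[vsel], pn, lambda)
          logr <- sum(lln) - sum(ll_vial[vsel]) +
            sum(log_dtnorm(g_new, ghat, sg_new, lo, hi)) -
            sum(log_dtnorm(g_old, ghat, sig_g[sg_of[gi]], lo, hi)) +
            sum(stats::dnorm(lb_new_sel, mu_b[cellidx[sel]], sig_b,
                             log = TRUE)) -
            sum(stats::dnorm(lb[sel], mu_b[cellidx[sel]], sig_b,
                             log = TRUE)) +
            sum(log(g_old) + ds - log(g_new)) +
            sum(lg_new_sel - lg[sel])
          if (owns_sig)
            logr <- logr + ds +
              stats::dnorm(sg_new, 0, config$prior_sigma_gamma, log = TRUE) -
              stats::dnorm(sig_g[sg_of[gi]], 0, config$prior_sigma_gamma,
                           log = TRUE)
          aacc <- is.finite(logr) && log(stats::runif(1)) < logr
          if (aacc) {
            lg[sel] <- lg_new_sel; lb[sel] <- lb_new_sel
            if (owns_sig) sig_g[sg_of[gi]] <- sg_new
            p_vial[vsel] <- pn; ll_vial[vsel] <- lln
          }
        }
        if (adapting)
          s_alloc[gi] <- s_alloc[gi] * exp(gam * ((aacc * 1) - 0.3))
      }

      # --- spreads: MH on the log scale with half-normal priors ---
      upd_sigma <- function(sig, vals, means, prior_scale) {
        prop <- sig * exp(stats::rnorm(1, 0, s_sig))
        logr <- sum(stats::dnorm(vals, means, prop, log = TRUE)) -
          sum(stats::dnorm(vals, means, sig, log = TRUE)) +
          stats::dnorm(prop, 0, prior_scale, log = TRUE) -
          stats::dnorm(sig, 0, prior_scale, log = TRUE) +
          log(prop) - log(sig)
        if (log(stats::runif(1)) < logr) prop else sig
      }
      sig_b <- upd_sigma(sig_b, lb, mu_b[cellidx], config$prior_sigma_beta)
      sig_d <- upd_sigma(sig_d, ld, mu_d[cellidx], config$prior_sigma_delta)
      for (si in seq_len(n_sg)) {
        usel <- sg_of[match(unit_gcell, gcells)] == si
        prop <- sig_g[si] * exp(stats::rnorm(1, 0, s_sig))
        g_all <- exp(lg[usel]); mg <- mu_g[unit_gcell[usel]]
        logr <- sum(log_dtnorm(g_all, mg, prop, lo, hi)) -
          sum(log_dtnorm(g_all, mg, sig_g[si], lo, hi)) +
          stats::dnorm(prop, 0, config$prior_sigma_gamma, log = TRUE) -
          stats::dnorm(sig_g[si], 0, config$prior_sigma_gamma, log = TRUE) +
          log(prop) - log(sig_g[si])
        if (is.finite(logr) && log(stats::runif(1)) < logr) sig_g[si] <- prop
      }

      # --- beta-binomial precision: MH on log lambda with stored p ---
      {
        prop <- lambda * exp(stats::rnorm(1, 0, s_lam))
        ll_new <- dbetabinom_log(xn, nn, p_vial, prop)
        logr <- sum(ll_new) - sum(ll_vial) +
          stats::dnorm(prop, 0, config$prior_lambda, log = TRUE) -
          stats::dnorm(lambda, 0, config$prior_lambda, log = TRUE) +
          log(prop) - log(lambda)
        if (log(stats::runif(1)) < logr) { lambda <- prop; ll_vial <- ll_new }
      }

      if (it > config$warmup)
        keep[it - config$warmup, ] <- c(mu_b, mu_d, mu_g,
                                        sig_b, sig_d, sig_g, lambda,
                                        lb, ld, exp(lg))
    }
    colnames(keep) <- c(paste0("mu_beta[", cells, "]"),
                        paste0("mu_delta[", cells, "]"),
                        paste0("mu_gamma[", gcells, "]"),
                        "sigma_beta", "sigma_delta", sg_names, "lambda",
                        paste0("beta_i[", units, "]"),
                        paste0("delta_i[", units, "]"),
                        paste0("gamma_i[", units, "]"))
    keep
  }

  set.seed(as.integer(seed))
  chain_seeds <- sample.int(2^30, config$chains)
  chains <- lapply(chain_seeds, run_chain)

  pop_pars <- c(paste0("mu_beta[", cells, "]"),
                paste0("mu_delta[", cells, "]"),
                paste0("mu_gamma[", gcells, "]"),
                "sigma_beta", "sigma_delta", sg_names, "lambda")
  diag <- convergence_check(lapply(chains, function(d) d[, pop_pars]))

  all_draws <- do.call(rbind, chains)
  summarize <- function(x) c(mean = mean(x), median = stats::median(x),
                             lo95 = unname(stats::quantile(x, 0.025)),
                             hi95 = unname(stats::quantile(x, 0.975)))
  rows <- list()
  for (cc in cells) {
    site <- sub(":.*$", "", cc); trt <- sub("^.*:", "", cc)
    for (par in c("beta", "delta", "gamma")) {
      col <- if (par == "gamma") paste0("mu_gamma[", gcell_of(cc), "]")
      else paste0("mu_", par, "[", cc, "]")
      x <- all_draws[, col]
      if (par != "gamma") x <- exp(x)
      rows[[length(rows) + 1L]] <-
        data.frame(site = site, treatment = trt, parameter = par,
                   t(summarize(x)), stringsAsFactors = FALSE)
    }
  }
  for (par in c("sigma_beta", "sigma_delta", sg_names, "lambda")) {
    rows[[length(rows) + 1L]] <-
      data.frame(site = NA, treatment = NA, parameter = par,
                 t(summarize(all_draws[, par])), stringsAsFactors = FALSE)
  }
  pair_cols <- grep("^(beta|delta|gamma)_i\\[", colnames(all_draws),
                    value = TRUE)
  pair_medians <- apply(all_draws[, pair_cols, drop = FALSE], 2,
                        stats::median)

  structure(list(chains = chains, cells = cells, units = units,
                 summary = do.call(rbind, rows),
                 pair_medians = pair_medians,
                 diagnostics = diag,
                 flagged = !diag$pass,
                 config = config, seed = seed),
            class = "hier_fit")
}

#' Posterior decline of a kinetics rate relative to a reference treatment
#'
#' Evaluates, per posterior draw, the ratio of the population rate at
#' `treatment` to the rate at `reference` within `site`, and reports the
#' percent decline `100 (1 - ratio)` with an equal-tailed 95% credible set
#' and the posterior probability of a decline (ties counted half).
#'
#' @param fit a `hier_fit`.
#' @param site site label.
#' @param treatment,reference treatment labels present in the fit.
#' @param parameter `"beta"` or `"delta"`.
#' @return one-row data frame: `site`, `parameter`, `treatment`,
#'   `reference`, `decline_pct`, `lo95`, `hi95`, `pr_decline`.
#' @export
decline_summary <- function(fit, site, treatment, reference,
                            parameter = c("beta", "delta")) {
  stopifnot(inherits(fit, "hier_fit"))
  parameter <- match.arg(parameter)
  col_t <- paste0("mu_", parameter, "[", site, ":", treatment, "]")
  col_r <- paste0("mu_", parameter, "[", site, ":", reference, "]")
  all_draws <- do.call(rbind, fit$chains)
  for (col in c(col_t, col_r))
    if (!col %in% colnames(all_draws))
      stop("treatment cell not in posterior: ", col)
  ratio <- exp(all_draws[, col_t] - all_draws[, col_r])
  decline <- 100 * (1 - ratio)
  pr <- mean(ratio < 1) + 0.5 * mean(ratio == 1)
  data.frame(site = site, parameter = parameter, treatment = treatment,
             reference = reference,
             decline_pct = stats::median(decline),
             lo95 = unname(stats::quantile(decline, 0.025)),
             hi95 = unname(stats::quantile(decline, 0.975)),
             pr_decline = pr, stringsAsFactors = FALSE)
}

#' Split-Rhat and effective sample size diagnostics
#'
#' Computes split-chain potential scale reduction factors and an
#' autocorrelation-based effective sample size per parameter, with a pass
#' flag at Rhat < 1.05 and ESS > 100.
#'
#' @param chains list (length >= 2) of iteration x parameter draw matrices
#'   with identical column names.
#' @return list with `table` (parameter, rhat, ess), `pass`, `max_rhat`,
#'   `min_ess`.
#' @export
convergence_check <- function(chains) {
  if (!is.list(chains) || length(chains) < 2)
    stop("at least 2 chains are required")
  pars <- colnames(chains[[1]])
  halves <- unlist(lapply(chains, function(d) {
    n <- nrow(d) %/% 2
    list(d[seq_len(n), , drop = FALSE],
         d[(n + 1):(2 * n), , drop = FALSE])
  }), recursive = FALSE)
  n <- nrow(halves[[1]])
  rhat <- vapply(pars, function(p) {
    x <- vapply(halves, function(d) d[, p], numeric(n))
    means <- colMeans(x); vars <- apply(x, 2, stats::var)
    B <- n * stats::var(means); W <- mean(vars)
    if (W < 1e-300) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, numeric(1))
  ess <- vapply(pars, function(p) {
    sum(vapply(chains, function(d) ess_one(d[, p]), numeric(1)))
  }, numeric(1))
  tab <- data.frame(parameter = pars, rhat = rhat, ess = ess,
                    row.names = NULL, stringsAsFactors = FALSE)
  list(table = tab, pass = all(rhat < 1.05) && all(ess > 100),
       max_rhat = max(rhat), min_ess = min(ess))
}

# effective sample size of one chain via the initial positive sequence of
# paired autocorrelations
ess_one <- function(x) {
  n <- length(x)
  if (stats::var(x) < 1e-300) return(n)
  ac <- stats::acf(x, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (k in seq(1, length(ac) - 1, by = 2)) {
    pair <- ac[k] + ac[k + 1]
    if (is.na(pair) || pair < 0) break
    s <- s + pair
  }
  n / (1 + 2 * s)
}
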