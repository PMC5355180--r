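# Shared fixtures, generated in code.

# small single-site simulation used across tests
small_sim <- function(seed = 42, pairs = 6, beta_scale = list()) {
  cfg <- sim_config(sites = c(SB = pairs),
                    treatments_by_site = list(SB = c("8.03", "7.87", "7.76")),
                    beta_scale = beta_scale)
  simulate_trials(cfg, seed = seed)
}

# hand-built fitted_curve with explicit polynomial coefficients per cell;
# coefficients are on the raw log10-sperm scale (center 0, scale 1)
fake_curve <- function(cells, coef_list, vcov = NULL, degree = 3,
                       varcomp = c(pair = 0, pair_trt = 0, olre = 0)) {
  nm <- unlist(lapply(cells, function(cl) {
    if (length(cells) > 1)
      c(paste0("cell", cl), paste0("cell", cl, ":xs", seq_len(degree)))
    else c("(Intercept)", paste0("xs", seq_len(degree)))
  }))
  cf <- unlist(coef_list)
  names(cf) <- nm
  if (is.null(vcov)) vcov <- diag(0, length(cf))
  dimnames(vcov) <- list(nm, nm)
  structure(list(coef = cf, vcov = vcov, varcomp = varcomp,
                 xrange = c(0, 6),
                 center = 0, scale = 1, cells = cells, degree = degree,
                 loglik = NA_real_, n = 0, converged = TRUE),
            class = "fitted_curve")
}

default_params <- function(...) kinetics_params(beta = 3e-4, gamma = 0.05,
                                                delta = 0.2, ...)
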