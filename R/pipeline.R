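# Orchestration: pH-regime summaries, a single reproducible end-to-end run
# over simulated or supplied trials, and report tables.

#' Summary statistics of a pH time series
#'
#' The regime descriptors used to characterise a site's pH exposure: mean,
#' coefficient of variation, and the fraction of observations at or below a
#' threshold (inclusive, default pH 7.80).
#'
#' @param ph numeric vector of pH (total scale) observations.
#' @param threshold low-pH threshold (default 7.80).
#' @return list with `mean`, `cv`, `frac_below` (fraction <= threshold) and
#'   `n`.
#' @export
regime_stats <- function(ph, threshold = 7.80) {
  ph <- ph[!is.na(ph)]
  if (!length(ph)) stop("pH series is empty")
  if (any(ph < 6 | ph > 9)) stop("pH values outside [6, 9]")
  m <- mean(ph)
  list(mean = m,
       cv = if (length(ph) > 1) stats::sd(ph) / m else 0,
       frac_below = mean(ph <= threshold),
       n = length(ph))
}

#' Read a pH sensor series CSV
#'
#' @param path CSV with columns `timestamp` (ISO-8601) and `ph_T`.
#' @return data frame with parsed `timestamp` and numeric `ph_T`.
#' @export
load_ph_series <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("timestamp", "ph_T"), names(d))
  if (length(missing))
    stop("pH series is missing column(s): ", paste(missing, collapse = ", "))
  d$timestamp <- as.POSIXct(d$timestamp, tz = "UTC",
                            tryFormats = c("%Y-%m-%dT%H:%M:%S",
                                           "%Y-%m-%d %H:%M:%S",
                                           "%Y-%m-%d"))
  d
}

#' Run the full analysis pipeline
#'
#' Executes, in order: trial simulation (or loading), vial scoring,
#' treatment-water CO2-system computation, the TF/AbnF mixed-model analysis
#' with metrics and bootstrap contrasts, and (optionally) the hierarchical
#' kinetics fit.  Every output is written under `out_dir` and listed with an
#' md5 checksum in the returned manifest; identical configuration and seeds
#' give identical checksums for the non-MCMC stages.
#'
#' @param out_dir output directory (created if needed).
#' @param trials optional trial data frame; when `NULL`, trials are
#'   simulated from `config`.
#' @param config a [sim_config()] used when simulating.
#' @param chemistry optional data frame with `ph_T`, `alk`, `sal`, `temp`;
#'   default: the printed treatment-water conditions.
#' @param seed integer seed for all stochastic stages.
#' @param n_boot bootstrap draws for the metric contrasts.
#' @param run_bayes run the hierarchical kinetics fit (slow; default FALSE).
#' @param bayes_config a [hier_config()] used when `run_bayes` is TRUE.
#' @return the run manifest: list with `config`, `seed`, `outputs` (file,
#'   md5), `warnings`, `started`, `finished`.
#' @export
run_pipeline <- function(out_dir, trials = NULL, config = sim_config(),
                         chemistry = NULL, seed = 1, n_boot = 200,
                         run_bayes = FALSE, bayes_config = hier_config()) {
  if (is.null(trials) && is.null(config))
    stop("configuration error: neither trials nor a simulation config given")
  started <- Sys.time()
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  warns <- character(0)
  emit <- function(obj, name) {
    path <- file.path(out_dir, name)
    utils::write.csv(obj, path, row.names = FALSE)
    outputs <<- c(outputs, path)
    path
  }

  if (is.null(trials)) {
    sim <- simulate_trials(config, seed = seed)
    trials <- sim$trials
    emit(sim$truth, "truth.csv")
  }
  emit(trials, "trials.csv")
  scored <- score_trials(trials)
  emit(scored, "scored.csv")

  if (is.null(chemistry)) {
    tc <- treatment_conditions()
    chemistry <- data.frame(site = tc$site, treatment = tc$treatment,
                            ph_T = tc$ph_t, alk = tc$alk_umol_kg,
                            sal = tc$salinity, temp = tc$temp_c)
  }
  emit(solve_carbonate_table(chemistry), "carbonate.csv")

  curve_tf <- fit_glmm(trials, glmm_spec("tf"), seed = seed)
  curve_abn <- fit_glmm(trials, glmm_spec("abnf"), seed = seed)
  if (!curve_tf$converged || !curve_abn$converged)
    warns <- c(warns, "GLMM convergence flagged")
  boot <- bootstrap_contrasts(curve_tf, curve_abn, n_boot = n_boot,
                              seed = seed)
  emit(boot$estimates, "metrics.csv")
  emit(boot$contrasts, "contrasts.csv")
  vp_tf <- variance_partition(curve_tf)
  vp_abn <- variance_partition(curve_abn)
  emit(data.frame(response = c("tf", "abnf"),
                  r2_marginal = c(vp_tf$r2_marginal, vp_abn$r2_marginal),
                  r2_conditional = c(vp_tf$r2_conditional,
                                     vp_abn$r2_conditional)),
       "variance_partition.csv")

  if (run_bayes) {
    fit <- fit_hierarchical(trials, bayes_config, seed = seed)
    if (fit$flagged) warns <- c(warns, "hierarchical fit convergence flagged")
    emit(fit$summary, "posterior_summary.csv")
  }

  manifest <- list(seed = seed,
                   outputs = data.frame(
                     file = basename(outputs),
                     md5 = unname(tools::md5sum(outputs)),
                     stringsAsFactors = FALSE),
                   warnings = warns,
                   started = format(started, usetz = TRUE),
                   finished = format(Sys.time(), usetz = TRUE),
                   version = as.character(utils::packageVersion("fertdyn")))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Report tables from pipeline outputs
#'
#' Collects the metric estimates with group letters and the posterior
#' intervals into display-ready tables (one row per panel entry of the
#' corresponding figures).
#'
#' @param out_dir directory written by [run_pipeline()].
#' @return list with `metric_panels` and, if present, `posterior_panels`;
#'   an attribute `notes` records missing or empty inputs.
#' @export
report_tables <- function(out_dir) {
  notes <- character(0)
  metrics_path <- file.path(out_dir, "metrics.csv")
  metric_panels <- NULL
  if (file.exists(metrics_path)) {
    m <- utils::read.csv(metrics_path, stringsAsFactors = FALSE,
                         colClasses = c(treatment = "character"))
    if (nrow(m) == 0) notes <- c(notes, "no estimable metrics")
    else metric_panels <- m[order(m$site, m$metric, m$treatment),
                            c("site", "treatment", "metric", "sperm_conc",
                              "lo95", "hi95", "group", "level")]
  } else notes <- c(notes, "metrics.csv missing")
  post_path <- file.path(out_dir, "posterior_summary.csv")
  posterior_panels <- NULL
  if (file.exists(post_path)) {
    p <- utils::read.csv(post_path, stringsAsFactors = FALSE)
    posterior_panels <- p[!is.na(p$site) & p$parameter %in%
                            c("beta", "delta"), ]
  }
  structure(list(metric_panels = metric_panels,
                 posterior_panels = posterior_panels),
            notes = notes)
}
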