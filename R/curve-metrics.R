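# Flexible statistical analysis of the fertilization functions: binomial
# mixed models on a cubic polynomial of log10 sperm concentration with
# observation-level overdispersion, likelihood-ratio tests, numerically
# solved sperm-requirement metrics and parametric-bootstrap contrasts.

#' Specification of the fertilization-function GLMM
#'
#' @param response `"tf"` (total fertilization, denominator = eggs scored)
#'   or `"abnf"` (abnormal fertilization, denominator = fertilized eggs;
#'   vials with no fertilized eggs are excluded).
#' @param degree polynomial degree in log10 sperm concentration (default 3).
#' @param window analysis window override (open interval, sperm/ul).
#' @param random include pair and treatment-within-pair random intercepts.
#' @param olre include an observation-level random intercept (the Gaussian
#'   logit-scale overdispersion term).
#' @param pooled fit a single global curve (no site/treatment fixed
#'   structure); used as a visual reference only.
#' @return list of class `glmm_spec`.
#' @export
glmm_spec <- function(response = c("tf", "abnf"), degree = 3, window = NULL,
                      random = TRUE, olre = TRUE, pooled = FALSE) {
  response <- match.arg(response)
  stopifnot(degree >= 1)
  structure(list(response = response, degree = degree, window = window,
                 random = random, olre = olre, pooled = pooled),
            class = "glmm_spec")
}

glmm_prepare <- function(records, spec) {
  validate_trials(records)
  records <- filter_analysis_window(records, spec$response,
                                    window = spec$window)
  n_fert <- records$n_scored - records$n_unfert
  if (spec$response == "tf") {
    records$succ <- n_fert
    records$fail <- records$n_unfert
  } else {
    records <- records[n_fert > 0, , drop = FALSE]
    n_fert <- records$n_scored - records$n_unfert
    records$succ <- records$n_tight + records$n_abn_dev
    records$fail <- n_fert - records$succ
  }
  if (nrow(records) == 0) stop("no records inside the analysis window")
  if (all(records$fail == 0) || all(records$succ == 0))
    stop("degenerate fit: response is constant (complete separation) ",
         "across the analysis window")
  x <- log10(records$sperm_conc)
  records$x_center <- mean(x)
  records$x_scale <- stats::sd(x)
  if (records$x_scale[1] == 0) stop("sperm concentration has no spread")
  xs <- (x - records$x_center[1]) / records$x_scale[1]
  for (d in seq_len(spec$degree)) records[[paste0("xs", d)]] <- xs^d
  records$cell <- if (spec$pooled) factor("pooled")
  else factor(paste(records$site, records$ph_treatment, sep = ":"))
  records$pair_trt <- paste(records$pair_id, records$ph_treatment, sep = ":")
  records$obs_id <- seq_len(nrow(records))
  records
}

poly_terms <- function(degree) paste0("xs", seq_len(degree))

#' Fit the cubic logit fertilization-function model
#'
#' Fits a binomial mixed model of the response on a polynomial of log10
#' sperm concentration with site-by-treatment cell-means coding (each cell
#' gets its own polynomial), random intercepts by pair and by treatment
#' within pair, and an observation-level random intercept for logit-scale
#' overdispersion.  Uses `lme4::glmer` (or `glm` when `random = FALSE`).
#'
#' @param records trial data frame (trial CSV schema).
#' @param spec a [glmm_spec()].
#' @param seed integer seed (optimizer reproducibility).
#' @return list of class `fitted_curve`: `coef`, `vcov`, `varcomp`
#'   (pair, pair-treatment, observation-level variances), `center`/`scale`
#'   of the polynomial variable, `cells`, `loglik`, `n`, `converged`.
#' @export
fit_glmm <- function(records, spec = glmm_spec(), seed = 1) {
  stopifnot(inherits(spec, "glmm_spec"))
  set.seed(seed)
  dat <- glmm_prepare(records, spec)
  fx <- if (nlevels(dat$cell) > 1)
    paste("0 + cell +", paste0("cell:", poly_terms(spec$degree),
                               collapse = " + "))
  else paste("1 +", paste(poly_terms(spec$degree), collapse = " + "))
  if (spec$random) {
    re <- "(1 | pair_id) + (1 | pair_trt)"
    if (spec$olre) re <- paste(re, "+ (1 | obs_id)")
    form <- stats::as.formula(paste("cbind(succ, fail) ~", fx, "+", re))
    fit <- suppressMessages(lme4::glmer(
      form, data = dat, family = stats::binomial(),
      control = lme4::glmerControl(optimizer = "bobyqa",
                                   calc.derivs = FALSE,
                                   optCtrl = list(maxfun = 1e5),
                                   check.conv.singular = "ignore")))
    vc <- lme4::VarCorr(fit)
    varcomp <- c(pair = unname(vc$pair_id[1]),
                 pair_trt = unname(vc$pair_trt[1]),
                 olre = if (spec$olre) unname(vc$obs_id[1]) else 0)
    coefs <- lme4::fixef(fit)
    vcv <- as.matrix(stats::vcov(fit))
    conv <- length(fit@optinfo$conv$lme4) == 0
  } else {
    form <- stats::as.formula(paste("cbind(succ, fail) ~", fx))
    fit <- stats::glm(form, data = dat, family = stats::binomial())
    varcomp <- c(pair = 0, pair_trt = 0, olre = 0)
    coefs <- stats::coef(fit)
    vcv <- stats::vcov(fit)
    conv <- fit$converged
  }
  keep <- !is.na(coefs)
  structure(list(coef = coefs[keep], vcov = vcv[keep, keep, drop = FALSE],
                 varcomp = varcomp,
                 xrange = range(log10(dat$sperm_conc)),
                 center = dat$x_center[1], scale = dat$x_scale[1],
                 cells = levels(dat$cell), degree = spec$degree,
                 spec = spec, loglik = as.numeric(stats::logLik(fit)),
                 n = nrow(dat), converged = conv, model = fit,
                 data = dat),
            class = "fitted_curve")
}

# logit-scale linear predictor of one cell's polynomial at log10-sperm x,
# for an arbitrary coefficient vector named like curve$coef
curve_eta <- function(curve, coefs, cell, x) {
  xs <- (x - curve$center) / curve$scale
  if (length(curve$cells) > 1) {
    nm_int <- paste0("cell", cell)
    nm_poly <- paste0("cell", cell, ":xs", seq_len(curve$degree))
  } else {
    nm_int <- "(Intercept)"
    nm_poly <- paste0("xs", seq_len(curve$degree))
  }
  miss <- setdiff(c(nm_int, nm_poly), names(coefs))
  if (length(miss))
    stop("cell not present in fitted curve: ", cell)
  eta <- rep(coefs[[nm_int]], length(xs))
  for (d in seq_len(curve$degree)) eta <- eta + coefs[[nm_poly[d]]] * xs^d
  eta
}

#' Likelihood-ratio test table for the fertilization-function model
#'
#' Tests each term of the site x treatment x sperm-polynomial factorial with
#' the nesting scheme: main effects are tested in the absence of every
#' interaction containing the focal effect, two-way interactions in the
#' absence of the three-way interaction, and the three-way against the full
#' model.  All fits are maximum likelihood with the same random-effects
#' structure.
#'
#' @param records trial data frame.
#' @param spec a [glmm_spec()].
#' @param seed optimizer seed.
#' @return data frame with `source`, `chisq`, `df`, `p`, `full`, `reduced`.
#' @export
lrt_table <- function(records, spec = glmm_spec(), seed = 1) {
  stopifnot(inherits(spec, "glmm_spec"))
  set.seed(seed)
  dat <- glmm_prepare(records, spec)
  sp <- paste0("(", paste(poly_terms(spec$degree), collapse = "+"), ")")
  terms_of <- function(...) paste(c(...), collapse = " + ")
  main <- c("site", "ph_treatment", sp)
  two <- c(paste0("site:", sp), paste0("ph_treatment:", sp),
           "site:ph_treatment")
  three <- paste0("site:ph_treatment:", sp)
  schemes <- list(
    `Sperm Conc.` = list(full = terms_of(main, "site:ph_treatment"),
                         drop = sp),
    Site = list(full = terms_of(main, paste0("ph_treatment:", sp)),
                drop = "site"),
    `pH treatment` = list(full = terms_of(main, paste0("site:", sp)),
                          drop = "ph_treatment"),
    `Site x Sperm` = list(full = terms_of(main, two), drop = two[1]),
    `pH x Sperm` = list(full = terms_of(main, two), drop = two[2]),
    `Site x pH` = list(full = terms_of(main, two), drop = two[3]),
    `Site x pH x Sperm` = list(full = terms_of(main, two, three),
                               drop = three))
  fit_ml <- function(fixed) {
    re <- if (spec$random) {
      r <- "(1 | pair_id) + (1 | pair_trt)"
      if (spec$olre) paste(r, "+ (1 | obs_id)") else r
    } else NULL
    form <- stats::as.formula(paste(
      "cbind(succ, fail) ~", fixed, if (!is.null(re)) paste("+", re)))
    if (spec$random)
      suppressMessages(lme4::glmer(
        form, data = dat, family = stats::binomial(),
        control = lme4::glmerControl(optimizer = "bobyqa",
                                     calc.derivs = FALSE,
                                     optCtrl = list(maxfun = 1e5),
                                     check.conv.singular = "ignore")))
    else stats::glm(form, data = dat, family = stats::binomial())
  }
  n_fixed <- function(fit)
    if (inherits(fit, "merMod")) sum(!is.na(lme4::fixef(fit)))
  else sum(!is.na(stats::coef(fit)))
  cache <- new.env(parent = emptyenv())
  get_fit <- function(fixed) {
    key <- digest_terms(fixed)
    if (is.null(cache[[key]])) cache[[key]] <- fit_ml(fixed)
    cache[[key]]
  }
  rows <- lapply(names(schemes), function(term) {
    sc <- schemes[[term]]
    full <- get_fit(sc$full)
    red_terms <- setdiff(strsplit(sc$full, " \\+ ")[[1]], sc$drop)
    reduced <- get_fit(paste(red_terms, collapse = " + "))
    df <- n_fixed(full) - n_fixed(reduced)
    if (df < 1) stop("reduced model is not nested with fewer parameters for ",
                     term)
    chisq <- max(0, 2 * (as.numeric(stats::logLik(full)) -
                           as.numeric(stats::logLik(reduced))))
    data.frame(source = term, chisq = chisq, df = df,
               p = stats::pchisq(chisq, df, lower.tail = FALSE),
               full = sc$full, reduced = paste(red_terms, collapse = " + "),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

digest_terms <- function(s) paste(sort(strsplit(s, " \\+ ")[[1]]),
                                  collapse = "|")

#' Solve sperm-requirement metrics from fitted fertilization functions
#'
#' Computes, per site x treatment cell, the sperm concentrations achieving
#' 50% normal fertilization (`S_NF50`, ascending limb), the optimum of the
#' normal-fertilization curve (`S_OptNF`, with the peak NF level), and 25%
#' abnormal fertilization (`S_AbnF25`, ascending), where
#' NF(x) = TF(x) (1 - AbnF(x)) on x = log10 sperm.  Root finding and the
#' argmax are refined to |dx| < 1e-6; a metric that is not attainable inside
#' its search range is flagged rather than extrapolated.
#'
#' @param curve_tf,curve_abnf `fitted_curve` objects for TF and AbnF.
#' @param cells character vector of `site:treatment` cells (default: all in
#'   the TF curve).
#' @param coefs_tf,coefs_abnf optional coefficient-vector overrides (used by
#'   the bootstrap).
#' @param xrange_nf,xrange_abnf log10 search ranges; the defaults are the
#'   observed concentration ranges of the fitted data (falling back to the
#'   analysis windows), which protects against spurious roots of the cubic
#'   outside the region the data constrain.
#' @param grid_n dense grid size for bracketing.
#' @return data frame with `cell`, `site`, `treatment`, `metric`,
#'   `log10_conc`, `sperm_conc`, `level`, `attainable`.
#' @export
solve_metrics <- function(curve_tf, curve_abnf, cells = NULL,
                          coefs_tf = curve_tf$coef,
                          coefs_abnf = curve_abnf$coef,
                          xrange_nf = curve_xrange(curve_tf, "tf"),
                          xrange_abnf = curve_xrange(curve_abnf, "abnf"),
                          grid_n = 2001) {
  if (is.null(cells)) cells <- curve_tf$cells
  rows <- list()
  for (cell in cells) {
    nf_fun <- function(x)
      stats::plogis(curve_eta(curve_tf, coefs_tf, cell, x)) *
      (1 - stats::plogis(curve_eta(curve_abnf, coefs_abnf, cell, x)))
    abn_fun <- function(x)
      stats::plogis(curve_eta(curve_abnf, coefs_abnf, cell, x))
    site <- if (grepl(":", cell)) sub(":.*$", "", cell) else NA
    trt <- if (grepl(":", cell)) sub("^.*:", "", cell) else NA
    r50 <- ascending_root(nf_fun, 0.5, xrange_nf, grid_n)
    opt <- grid_argmax(nf_fun, xrange_nf, grid_n)
    r25 <- ascending_root(abn_fun, 0.25, xrange_abnf, grid_n)
    add <- function(metric, x, level) {
      rows[[length(rows) + 1L]] <<- data.frame(
        cell = cell, site = site, treatment = trt, metric = metric,
        log10_conc = x, sperm_conc = 10^x, level = level,
        attainable = is.finite(x), stringsAsFactors = FALSE)
    }
    add("S_NF50", r50, 0.5)
    add("S_OptNF", opt$x, opt$value)
    add("S_AbnF25", r25, 0.25)
  }
  do.call(rbind, rows)
}

curve_xrange <- function(curve, response) {
  if (!is.null(curve$xrange)) curve$xrange
  else log10(ANALYSIS_WINDOWS[[response]] + c(1e-9, 0))
}

# smallest x in range where f crosses `level` from below; NA if none
ascending_root <- function(f, level, xrange, grid_n) {
  xs <- seq(xrange[1], xrange[2], length.out = grid_n)
  ys <- f(xs) - level
  up <- which(ys[-grid_n] < 0 & ys[-1] >= 0)
  if (!length(up)) return(NA_real_)
  i <- up[1]
  stats::uniroot(function(x) f(x) - level, c(xs[i], xs[i + 1]),
                 tol = 1e-8)$root
}

grid_argmax <- function(f, xrange, grid_n) {
  xs <- seq(xrange[1], xrange[2], length.out = grid_n)
  ys <- f(xs)
  i <- which.max(ys)
  lo <- xs[max(1, i - 1)]; hi <- xs[min(grid_n, i + 1)]
  op <- stats::optimize(f, c(lo, hi), maximum = TRUE, tol = 1e-8)
  list(x = op$maximum, value = op$objective)
}

#' Parametric bootstrap CIs and within-site contrasts for the metrics
#'
#' Draws `n_boot` fixed-effect vectors from the multivariate normal defined
#' by each fitted curve's coefficient estimates and covariance matrix
#' (independently for TF and AbnF), recomputes every metric per draw, and
#' reports 95% percentile confidence intervals plus pairwise within-site
#' treatment contrasts with two-tailed percentile p-values using the
#' add-one correction (r+1)/(n+1).  Homogeneous groups are lettered at the
#' Bonferroni-adjusted level (default alpha 0.05/3).
#'
#' @param curve_tf,curve_abnf `fitted_curve` objects.
#' @param n_boot bootstrap draws (default 1000).
#' @param seed integer seed.
#' @param alpha familywise level before Bonferroni (default 0.05).
#' @param n_comparisons comparisons per site x metric family (default 3).
#' @return list with `estimates` (metric table plus `lo95`, `hi95`,
#'   `n_missing`, `unstable`, `group`) and `contrasts` (`site`, `metric`,
#'   `treatment_1`, `treatment_2`, `p`, `significant`).
#' @export
bootstrap_contrasts <- function(curve_tf, curve_abnf, n_boot = 1000, seed = 1,
                                alpha = 0.05, n_comparisons = 3) {
  set.seed(seed)
  point <- solve_metrics(curve_tf, curve_abnf)
  draws_tf <- draw_coefs(curve_tf, n_boot)
  draws_abn <- draw_coefs(curve_abnf, n_boot)
  boot <- array(NA_real_, dim = c(n_boot, nrow(point)))
  for (b in seq_len(n_boot)) {
    mb <- solve_metrics(curve_tf, curve_abnf,
                        coefs_tf = draws_tf[b, ],
                        coefs_abnf = draws_abn[b, ])
    boot[b, ] <- mb$log10_conc
  }
  point$lo95 <- 10^apply(boot, 2, stats::quantile, 0.025, na.rm = TRUE)
  point$hi95 <- 10^apply(boot, 2, stats::quantile, 0.975, na.rm = TRUE)
  point$n_missing <- colSums(is.na(boot))
  # unstable: many unattainable draws, or the bootstrap mass sits on a
  # different root branch than the point estimate (interval excludes it)
  point$unstable <- point$n_missing > 0.2 * n_boot |
    (!is.na(point$log10_conc) &
       (10^point$log10_conc < point$lo95 - 1e-9 |
          10^point$log10_conc > point$hi95 + 1e-9))
  point$lo95[point$n_missing == n_boot] <- NA
  point$hi95[point$n_missing == n_boot] <- NA

  adj_alpha <- alpha / n_comparisons
  contrasts <- list()
  for (site in unique(stats::na.omit(point$site))) {
    for (metric in unique(point$metric)) {
      sel <- which(point$site == site & point$metric == metric)
      trts <- point$treatment[sel]
      if (length(sel) < 2) next
      prs <- utils::combn(seq_along(sel), 2)
      for (j in seq_len(ncol(prs))) {
        i1 <- sel[prs[1, j]]; i2 <- sel[prs[2, j]]
        d <- boot[, i1] - boot[, i2]
        d <- d[!is.na(d)]
        if (!length(d)) {
          p <- NA_real_
        } else if (all(d == d[1])) {
          # degenerate draws carry no distributional evidence
          p <- 1
        } else {
          r <- min(sum(d <= 0), sum(d >= 0))
          p <- min(1, 2 * (r + 1) / (length(d) + 1))
        }
        contrasts[[length(contrasts) + 1L]] <- data.frame(
          site = site, metric = metric,
          treatment_1 = trts[prs[1, j]], treatment_2 = trts[prs[2, j]],
          p = p, significant = !is.na(p) & p < adj_alpha,
          stringsAsFactors = FALSE)
      }
    }
  }
  contrasts <- if (length(contrasts)) do.call(rbind, contrasts) else
    data.frame()
  point$group <- NA_character_
  if (nrow(contrasts)) {
    for (site in unique(contrasts$site)) {
      for (metric in unique(contrasts$metric)) {
        sel <- which(point$site == site & point$metric == metric)
        cc <- contrasts[contrasts$site == site & contrasts$metric == metric, ]
        point$group[sel] <- letter_groups(point$treatment[sel], cc)
      }
    }
  }
  list(estimates = point, contrasts = contrasts)
}

draw_coefs <- function(curve, n_boot) {
  draws <- MASS::mvrnorm(n_boot, mu = curve$coef, Sigma = curve$vcov)
  if (is.null(dim(draws))) draws <- matrix(draws, nrow = n_boot)
  colnames(draws) <- names(curve$coef)
  draws
}

# compact letter display from pairwise significance (small k brute force)
letter_groups <- function(trts, contrasts) {
  k <- length(trts)
  ns <- matrix(TRUE, k, k, dimnames = list(trts, trts))
  for (i in seq_len(nrow(contrasts))) {
    if (isTRUE(contrasts$significant[i])) {
      a <- contrasts$treatment_1[i]; b <- contrasts$treatment_2[i]
      ns[a, b] <- ns[b, a] <- FALSE
    }
  }
  subsets <- list()
  for (size in k:1) {
    for (combo in utils::combn(k, size, simplify = FALSE)) {
      if (all(ns[combo, combo])) {
        covered <- any(vapply(subsets, function(s) all(combo %in% s),
                              logical(1)))
        if (!covered) subsets[[length(subsets) + 1L]] <- combo
      }
    }
  }
  labels <- rep("", k)
  for (j in seq_along(subsets))
    labels[subsets[[j]]] <- paste0(labels[subsets[[j]]], letters[j])
  labels
}

#' Logit-scale variance partitioning of a fitted curve
#'
#' Variance explained on the logit scale with the distribution-specific
#' variance pi^2/3 and the observation-level (overdispersion) variance in
#' the denominator: marginal R2 uses the fixed-effect linear predictor
#' variance, conditional R2 adds the random-effect variances.  Optional
#' coefficient subsets report the share of each fixed-effect group.
#'
#' @param curve a `fitted_curve`.
#' @param fixed_subsets optional named list of coefficient-name vectors.
#' @return list with `var_fixed`, `var_pair`, `var_pair_trt`, `var_olre`,
#'   `var_dist`, `r2_marginal`, `r2_conditional`, and `subset_shares`.
#' @export
variance_partition <- function(curve, fixed_subsets = NULL) {
  stopifnot(inherits(curve, "fitted_curve"))
  X <- fixed_model_matrix(curve)
  eta <- as.vector(X %*% curve$coef)
  var_f <- stats::var(eta) * (length(eta) - 1) / length(eta)
  vc <- curve$varcomp
  var_dist <- pi^2 / 3
  total <- var_f + vc[["pair"]] + vc[["pair_trt"]] + vc[["olre"]] + var_dist
  shares <- NULL
  if (!is.null(fixed_subsets)) {
    shares <- vapply(fixed_subsets, function(nms) {
      missing <- setdiff(nms, names(curve$coef))
      if (length(missing))
        stop("unknown coefficient name(s): ", paste(missing, collapse = ", "))
      sub_eta <- as.vector(X[, nms, drop = FALSE] %*% curve$coef[nms])
      stats::var(sub_eta) * (length(sub_eta) - 1) / length(sub_eta) / total
    }, numeric(1))
  }
  list(var_fixed = var_f, var_pair = vc[["pair"]],
       var_pair_trt = vc[["pair_trt"]], var_olre = vc[["olre"]],
       var_dist = var_dist,
       r2_marginal = var_f / total,
       r2_conditional = (var_f + vc[["pair"]] + vc[["pair_trt"]]) / total,
       subset_shares = shares)
}

fixed_model_matrix <- function(curve) {
  dat <- curve$data
  if (inherits(curve$model, "merMod")) {
    X <- lme4::getME(curve$model, "X")
  } else {
    X <- stats::model.matrix(curve$model)
  }
  X[, names(curve$coef), drop = FALSE]
}
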