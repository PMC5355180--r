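# Mechanistic fertilization dynamics with polyspermy blocking.
#
# State variables (concentrations, per ul): S sperm, E_U unfertilized eggs,
# E_1 singly-fertilized eggs that have not yet raised a polyspermy block,
# E_N normally fertilized (blocked after one fertilization), E_P polyspermic
# (hit a second time before blocking).  With k = beta*E_T + r:
#   S'   = -k S                          (consumption by eggs + viability decay)
#   E_U' = -beta*gamma*S E_U
#   E_1' =  beta*gamma*S E_U - delta E_1 - beta*gamma*S E_1
#   E_N' =  delta E_1
#   E_P' =  beta*gamma*S E_1
# S(tau) = S0 e^{-k tau} is available in closed form, so E_U and E_1 are too,
# and the normal fraction reduces to a single integral evaluated by
# Gauss-Legendre quadrature:
#   E_N(t)/E_T = delta*beta*gamma*S0 *
#     int_0^t (e^{-delta tau} - e^{-k tau})/(k - delta) *
#             exp(-beta*gamma*S0 (1 - e^{-k tau})/k) dtau .

GAMMA_BOUNDS <- c(1e-4, 0.15)

#' Kinetics parameter set
#'
#' @param beta sperm-egg interaction rate, ul per sperm per second.
#' @param gamma dimensionless product of sperm acceptability and fertilizable
#'   egg-surface fraction; must lie in (0.0001, 0.15).
#' @param delta polyspermy-block rate, per second.
#' @param r sperm viability decay rate, per second (0.0003 for
#'   *S. purpuratus*; negligible over a 30 s contact).
#' @param E_T egg concentration, eggs per ul (default 1000 eggs in 23 ml).
#' @param t sperm-egg contact time, seconds.
#' @return validated list of class `kinetics_params`.
#' @export
kinetics_params <- function(beta, gamma, delta, r = 3e-4,
                            E_T = 1000 / 23000, t = 30) {
  vals <- c(beta = beta, gamma = gamma, delta = delta, r = r, E_T = E_T, t = t)
  if (any(!is.finite(vals))) stop("kinetics parameters must be finite")
  if (beta <= 0 || delta <= 0 || E_T <= 0 || t <= 0)
    stop("beta, delta, E_T and t must be positive")
  if (r < 0) stop("r must be non-negative")
  if (gamma <= GAMMA_BOUNDS[1] || gamma >= GAMMA_BOUNDS[2])
    stop("gamma outside its truncation bounds (", GAMMA_BOUNDS[1], ", ",
         GAMMA_BOUNDS[2], ")")
  structure(as.list(vals), class = "kinetics_params")
}

# (e^{-delta u} - e^{-k u}) / (k - delta), stable as k -> delta.
block_kernel <- function(u, k, delta) {
  d <- k - delta
  ifelse(abs(d * u) < 1e-8,
         u * exp(-delta * u) * (1 - d * u / 2),
         (exp(-delta * u) - exp(-k * u)) / d)
}

#' Expected normal-fertilization fraction (quadrature)
#'
#' Evaluates the mechanistic model's normal-fertilization fraction
#' E_N(t)/E_T at the end of the sperm-egg contact window by Gauss-Legendre
#' quadrature of the closed-form integrand, doubling the node count until
#' two successive estimates agree within `tol`.
#'
#' @param params a [kinetics_params()] object.
#' @param S0 initial sperm concentration(s), sperm per ul; vectorized.
#' @param nodes initial Gauss-Legendre order (default 40).
#' @param tol successive-refinement tolerance (default 1e-8).
#' @return normal-fertilization fraction(s) in \[0, 1\].
#' @export
normal_fraction <- function(params, S0, nodes = 40, tol = 1e-8) {
  stopifnot(inherits(params, "kinetics_params"))
  if (any(S0 < 0)) stop("S0 must be non-negative")
  with(params, {
    k <- beta * E_T + r
    est <- normal_fraction_gl(S0, beta, gamma, delta, k, t, nodes)
    repeat {
      nodes <- 2L * nodes
      est2 <- normal_fraction_gl(S0, beta, gamma, delta, k, t, nodes)
      if (max(abs(est2 - est)) < tol || nodes > 5120) break
      est <- est2
    }
    pmin(pmax(est2, 0), 1)
  })
}

# Gauss-Legendre evaluation, elementwise over vials: S0 and (recycled)
# beta, gamma, delta, k may all be vectors of the vial count.  The integrand
# has a boundary layer at tau = 0 whose width is set by the fastest of the
# block rate, the fertilization rate beta*gamma*S0 and the sperm-loss rate;
# the integral is therefore evaluated on geometrically graded panels (one
# per decade of stiffness) with `nodes` Gauss-Legendre points per panel.
normal_fraction_gl <- function(S0, beta, gamma, delta, k, t, nodes) {
  n <- length(S0)
  kv <- rep_len(k, n); dv <- rep_len(delta, n)
  bgS0 <- rep_len(beta * gamma, n) * S0
  rate <- max(dv, bgS0, kv) * t
  edges <- if (rate <= 10) c(0, t)
  else {
    J <- ceiling(log10(rate))
    c(0, t * 10^(-(J - 1):0))
  }
  out <- numeric(n)
  for (j in seq_len(length(edges) - 1)) {
    gl <- gl_rule(nodes, edges[j], edges[j + 1])
    Ek <- exp(-outer(gl$x, kv))                    # nodes x n
    Ed <- exp(-outer(gl$x, dv))
    diffm <- matrix(kv - dv, length(gl$x), n, byrow = TRUE)
    um <- matrix(gl$x, length(gl$x), n)
    kern <- ifelse(abs(diffm * um) < 1e-8,
                   um * Ed * (1 - diffm * um / 2),
                   (Ed - Ek) / diffm)
    sat <- (1 - Ek) / matrix(kv, length(gl$x), n, byrow = TRUE)
    f <- kern * exp(-sweep(sat, 2, bgS0, `*`))
    out <- out + as.vector(crossprod(f, gl$w))
  }
  dv * bgS0 * out
}

# Gauss-Legendre nodes/weights on [a, b], cached by order.
gl_cache <- new.env(parent = emptyenv())
gl_rule <- function(n, a, b) {
  key <- as.character(n)
  raw <- gl_cache[[key]]
  if (is.null(raw)) {
    raw <- pracma::gaussLegendre(n, -1, 1)
    gl_cache[[key]] <- raw
  }
  list(x = (b - a) / 2 * raw$x + (a + b) / 2, w = (b - a) / 2 * raw$w)
}

#' Full outcome decomposition by ODE integration
#'
#' Integrates the kinetic system with `deSolve::lsoda` at tight tolerances
#' and returns the outcome fractions at contact time `t`.  Serves as the
#' independent arbiter for the quadrature evaluator.
#'
#' @inheritParams normal_fraction
#' @return data frame with one row per `S0`: `S0`, `frac_unfert`,
#'   `frac_normal`, `frac_polyspermic`, `frac_pending` (singly fertilized,
#'   not yet blocked at `t`).
#' @export
outcome_fractions_ode <- function(params, S0) {
  stopifnot(inherits(params, "kinetics_params"))
  if (any(S0 < 0)) stop("S0 must be non-negative")
  with(params, {
    k <- beta * E_T + r
    rows <- lapply(S0, function(s0) {
      if (s0 == 0)
        return(c(frac_unfert = 1, frac_normal = 0, frac_polyspermic = 0,
                 frac_pending = 0))
      deriv <- function(tau, y, parms) {
        s <- s0 * exp(-k * tau)
        rate <- beta * gamma * s
        list(c(eu = -rate * y[["eu"]],
               e1 = rate * y[["eu"]] - delta * y[["e1"]] - rate * y[["e1"]],
               en = delta * y[["e1"]],
               ep = rate * y[["e1"]]))
      }
      out <- deSolve::lsoda(c(eu = 1, e1 = 0, en = 0, ep = 0), c(0, t), deriv,
                            rtol = 1e-10, atol = 1e-12)
      if (attr(out, "istate")[1] < 0) stop("ODE integration failed at S0 = ", s0)
      y <- out[nrow(out), -1]
      c(frac_unfert = unname(y[["eu"]]), frac_normal = unname(y[["en"]]),
        frac_polyspermic = unname(y[["ep"]]), frac_pending = unname(y[["e1"]]))
    })
    res <- as.data.frame(do.call(rbind, rows))
    cbind(S0 = S0, res)
  })
}

#' Closed-form outcome decomposition
#'
#' The closed-form solutions of the kinetic system (unfertilized and pending
#' classes exactly; normal fraction via [normal_fraction()]; polyspermic by
#' complement).  Fast path used inside likelihoods and the simulator.
#'
#' @inheritParams normal_fraction
#' @return data frame as in [outcome_fractions_ode()].
#' @export
outcome_fractions <- function(params, S0, nodes = 40, tol = 1e-8) {
  stopifnot(inherits(params, "kinetics_params"))
  with(params, {
    k <- beta * E_T + r
    bg <- beta * gamma
    sat <- (1 - exp(-k * t)) / k
    unfert <- exp(-bg * S0 * sat)
    # exact pending class: E_1(t)/E_T =
    #   bg*S0 (e^{-delta t} - e^{-k t})/(k - delta) * exp(-bg*S0*sat)
    pending <- bg * S0 * block_kernel(t, k, delta) * exp(-bg * S0 * sat)
    normal <- normal_fraction(params, S0, nodes = nodes, tol = tol)
    poly <- pmax(1 - unfert - pending - normal, 0)
    data.frame(S0 = S0, frac_unfert = unfert, frac_normal = normal,
               frac_polyspermic = poly, frac_pending = pending)
  })
}

#' Monospermy (instant-block) limit
#'
#' The classic fertilization-kinetics limit in which eggs block instantly
#' after the first fertilization (delta -> infinity): the fertilized fraction
#' 1 - exp(-beta*gamma*S0 (1 - e^{-(beta*E_T + r) t}) / (beta*E_T + r)).
#'
#' @inheritParams normal_fraction
#' @return proportion(s) in \[0, 1\].
#' @export
monospermy_limit <- function(params, S0) {
  stopifnot(inherits(params, "kinetics_params"))
  if (any(S0 < 0)) stop("S0 must be non-negative")
  with(params, {
    k <- beta * E_T + r
    1 - exp(-beta * gamma * S0 * (1 - exp(-k * t)) / k)
  })
}
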