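---
title: "Models and methods behind fertdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind fertdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`fertdyn` analyses laboratory fertilization trials of broadcast-spawning sea
urchins (*Strongylocentrotus purpuratus*) run across seawater pH treatments
and serial sperm dilutions. This vignette is the package's own account of
the models it implements, the parameters that matter, the numerical choices
made, and what the test suite does and does not demonstrate.

## Trial scoring

Each vial exposes ~1,000 eggs to a known sperm concentration for a 30 s
contact window; 200 embryos are later scored into four categories: normal
(raised envelope, equal cleavage), unfertilized (no envelope), tight
fertilization membrane, and abnormal cleavage. From the counts the package
computes

* total fertilization `TF = (scored - unfertilized) / scored`,
* abnormal fertilization `AbnF = (tight + abnormal) / (scored - unfertilized)`,
* normal fertilization `NF = TF (1 - AbnF)`.

`AbnF` is undefined when nothing is fertilized; such vials carry an explicit
flag and are excluded from AbnF model fitting rather than imputed as zero.
Tight membranes and abnormal cleavage are pooled because both reflect
failed or excess fertilization and the distinction does not enter any
downstream statistic (a test asserts this).

Sperm concentrations follow a 1:10 serial dilution (2.3 ml transferred into
20.7 ml of treatment water, eight steps) from a hemocytometer-counted
stock. Concentration is defined at the moment of egg addition
(post-dilution, pre-egg-volume correction); the convention is constant
across vials, so it cancels in every comparison the package makes.

## Seawater carbonate chemistry

Treatment water is characterised by pH on the total scale and total
alkalinity at known salinity and temperature. `solve_carbonate()` computes
DIC directly from the alkalinity balance (carbonate, borate, water,
bisulfate and fluoride terms; nutrients omitted as they were not measured,
a ≤1% effect), then pCO2 (with the Weiss fugacity correction) and the
aragonite saturation state. Carbonic-acid constants use the Mehrbach
refit by Dickson & Millero; ancillary constants follow the de-facto
CO2-system-calculator defaults (Weiss K0, Dickson KB/KS, Millero KW,
Perez & Fraga KF, Mucci Ksp, Uppström borate, Riley & Tongudai calcium).
Pressure is fixed at 0 dbar (bench vials). The inverse direction (pH from
DIC and alkalinity, used by the 25 °C-to-in-situ conversion) is a bracketed
monotone root solve on pH in [2, 12] at 10⁻¹⁰ tolerance. The solver
reproduces all published per-site treatment means of pCO2 and Ω_a within
1.5%, well inside the 5% band the acceptance suite checks.

## Fertilization kinetics

The mechanistic model tracks sperm `S` and egg classes: unfertilized `E_U`,
singly fertilized but not yet blocked `E_1`, normally fertilized (blocked
after one fertilization) `E_N`, and polyspermic `E_P`. With
`k = βE_T + r`:

```
S'   = -k S
E_U' = -βγ S E_U
E_1' =  βγ S E_U - δ E_1 - βγ S E_1
E_N' =  δ E_1
E_P' =  βγ S E_1
```

β is the sperm–egg interaction rate (µl sperm⁻¹ s⁻¹), γ the dimensionless
product of sperm acceptability and fertilizable egg-surface fraction
(truncated to (0.0001, 0.15)), δ the polyspermy-block rate (s⁻¹), r the
sperm viability decay rate (0.0003 s⁻¹, fixed, negligible over 30 s),
`E_T` the egg concentration (default 1000/23000 eggs µl⁻¹). Because
`S(τ) = S0 e^{-kτ}` is closed-form, `E_U` and `E_1` are too, and the
normal fraction reduces to a single integral

```
E_N(t)/E_T = δ βγ S0 ∫₀ᵗ (e^{-δτ} - e^{-kτ})/(k - δ) ·
             exp(-βγ S0 (1 - e^{-kτ})/k) dτ
```

whose exponent groupings (`βE_T + r`, `βE_T - δ + r`) define the model.
The same βγ product drives first and second fertilizations: the model has
a single acceptability parameter, so only the product βγ (together with δ)
is identified by fertilization curves at bench egg concentrations — a fact
that shapes the Bayesian machinery below.

Numerics: the integrand has a boundary layer at τ = 0 whose width is set
by the fastest of δ, βγS0 and k. A single Gauss–Legendre rule cannot
resolve it at high block rates, so the integral is evaluated on
geometrically graded panels (one per decade of stiffness) with a fixed
Gauss–Legendre order per panel: order 40 with adaptive doubling (to 10⁻⁸)
for user-facing calls, order 12 fixed inside MCMC likelihoods (worst-case
relative error 2×10⁻⁶ against the ODE oracle across a wide parameter
sweep). `outcome_fractions_ode()` integrates the system with `lsoda` at
10⁻¹⁰/10⁻¹² tolerances and is the arbiter in all equivalence tests. Eggs
still in `E_1` at the end of the contact window (`frac_pending`) are
reported separately; by default both the simulator and the fitted
likelihood count them as normal, mirroring how a scorer reads any raised
envelope without visible abnormality (a toggle reverts to the strict
blocked-only definition).

## Hierarchical Bayesian inference

For each site × treatment cell the model has population location
parameters: log-mean `μ_β`, `μ_δ` and a γ population mean; pair-level
values are `log β_i ~ N(μ_β, σ_β)`, `log δ_i ~ N(μ_δ, σ_δ)` (lognormal),
`γ_i ~ TruncNormal(γ̄, σ_γ)` on (0.0001, 0.15). The observation model is
beta-binomial: the normal count out of 200 scored has mean probability
given by the forward model and precision λ (shapes `λp`, `λ(1-p)`).
Default priors are vague on the design's scales: `μ_β ~ N(log 10⁻⁴, 3²)`,
`μ_δ ~ N(log 0.1, 3²)`, `γ̄ ~ U(0.0001, 0.15)`, half-normal(1) spreads for
σ_β and σ_δ, half-normal(0.05) for σ_γ, half-normal(500) for λ; all
overridable in `hier_config()`.

Because only βγ and δ are likelihood-identified, β estimates are
*marginalized over the uncertainty in γ*: γ̄ credible intervals are wide by
construction, and the width propagates into β's intervals. Two structural
choices follow from this geometry:

* γ̄ is estimated per site × treatment by default (an option shares it
  within a site). Treatment contrasts of β therefore carry the full γ
  uncertainty, which is what makes their credible sets honestly wide.
* Each γ group estimates its own σ_γ by default (an option shares one
  σ_γ globally). Tying the spread to its group keeps pair-level γ
  variation proportional to the weakly identified γ level as the sampler
  integrates over it; with a single global σ_γ the γ level of one group
  would be pinned by the packs of the others, an artefact of the
  truncated-normal's absolute scale rather than information in the data.

The sampler is an adaptive Metropolis-within-Gibbs scheme built around the
identified directions: conjugate normal draws for `μ_β`, `μ_δ`; batched
joint random-walk updates per pair in `(log βγ, log γ, log δ)` coordinates
(one vectorized forward-model evaluation per sweep); exact univariate
slice sampling along each γ group's flat ridge (γ values, γ̄ and the
group's σ_γ all scale by `e^{dl}` while every β compensates by `e^{-dl}`,
leaving all products unchanged — the likelihood re-enters only through the
small βE_T term in the sperm-loss rate); a residual-reallocation move that
exchanges pair-to-pair spread between β and γ at fixed products; and
scalar Metropolis steps for spreads and λ. Proposal scales adapt only
during warmup. Gradient-based samplers were considered; the quadrature
forward model is not automatically differentiable here, and the posterior
contract is correctness of draws, which the scheme above meets with
split-Rhat near 1 and adequate effective sizes at the default 2 × (500
warmup + 600 kept) iterations. Convergence is always reported
(`convergence_check()`: split-Rhat, autocorrelation ESS) and a fit with
any population-parameter Rhat above 1.05 is flagged, never silently
accepted.

Decline summaries compute, per draw, the ratio of a treatment's population
rate to the reference (pH 8.03) rate and report the median percent
decline, the equal-tailed 95% credible set, and the posterior probability
of a decline.

## Flexible fertilization-function analysis

Independently of the mechanism, TF and AbnF are modelled as binomial
GLMMs on the logit scale with a cubic polynomial of log₁₀ sperm
concentration per site × treatment cell (cell-means coding — each site
sees only three of the four treatment levels, so a full factorial would be
rank deficient), random intercepts by pair and by treatment-within-pair,
and an observation-level random intercept implementing the Gaussian
logit-scale overdispersion term. Fits use `lme4::glmer` (Laplace, bobyqa).
The polynomial is built on a centred, scaled log₁₀ concentration for
conditioning; all public quantities are mapped back to the natural scale.
AbnF fits weight by fertilized count and use only vials with defined AbnF.
Analysis windows restrict fitting to concentrations where the response is
informative: (1, 2×10⁵) sperm µl⁻¹ for TF, (10², 2×10⁷) for AbnF, open
intervals.

Likelihood-ratio tests follow the nesting scheme in which a main effect is
tested without any interaction containing it, two-way interactions without
the three-way, and the three-way against the full model; degrees of
freedom are counted as estimated-coefficient differences, which handles
the incomplete factorial's dropped columns.

Sperm-requirement metrics are solved from the fitted curves:
`NF(x) = TF(x)(1 - AbnF(x))` on `x = log₁₀` sperm; `S_NF50` is the
smallest ascending crossing of 0.5, `S_OptNF` the argmax (with the peak NF
level), `S_AbnF25` the smallest ascending crossing of 0.25. A 2001-point
bracketing grid over the window is refined by `uniroot`/`optimize` to
10⁻⁸; the ascending-smallest-root rule protects against spurious distal
roots of the cubic, and a metric that never reaches its level inside the
window is flagged unattainable rather than extrapolated. Confidence
intervals and within-site treatment contrasts come from a fully parametric
bootstrap: 1,000 fixed-effect vectors drawn from the multivariate normal
defined by each fit's coefficient estimates and covariance matrix
(independently for TF and AbnF), metrics recomputed per draw, percentile
95% intervals, two-tailed percentile p-values with the add-one correction
`(r+1)/(n+1)`, Bonferroni-adjusted significance at α = 0.05/3 ≈ 0.017 and
compact-letter homogeneous groups. Draws in which a metric is unattainable
are recorded as missing; an interval with more than 20% missing draws is
flagged unstable. Degenerate zero-covariance fits yield zero-width
intervals and, by convention, p = 1 (constant differences carry no
distributional evidence).

Variance partitioning follows the logit-scale marginal/conditional R²
construction with distribution-specific variance π²/3 and the
observation-level variance in the denominator; named coefficient subsets
report the share of any fixed-effect group.

## The synthetic-data generator

Raw trial records are not distributed with the study, so the generator is
the package's data source and defines the study conditions: FC 12, BMR 10
and SB 12 male–female pairs; three treatments per site (FC/BMR: 8.03,
7.76, 7.61; SB: 8.03, 7.87, 7.76); eight 1:10 dilutions from a 2×10⁶
sperm µl⁻¹ stock; 1,000 eggs per 23 ml vial; 30 s contact; 200 embryos
scored — 816 vials. Truth values default to β = 3×10⁻⁴ µl sperm⁻¹ s⁻¹,
γ = 0.05, δ = 0.2 s⁻¹, lognormal pair spreads 0.3 (σ_γ = 0.01 on the
natural scale), λ = 100. These are generator defaults calibrated once so
TF traverses 0→1 across the dilution range and polyspermy appears at the
top dilutions, as in bench trials; they are not published estimates.
Site- or treatment-specific multipliers on β or δ encode scenarios (a
0.54 multiplier on β encodes a 46% interaction-rate decline). Counts are
drawn hierarchically: unfertilized via beta-binomial with precision λ,
abnormal among fertilized likewise, and the tight-membrane/abnormal-
cleavage split as a 50/50 nuisance binomial.

What the generator does *not* emulate: day/run order effects, technical
replicate structure (the design sacrifices them for pair-level replication),
non-polyspermic abnormality mechanisms, egg-size variation among females,
and measured-pH jitter around nominal treatments beyond a recorded
metadata column. Passing recovery tests therefore demonstrate correctness
of the estimation machinery under the model's own assumptions, not
robustness to misspecification on real data.

## Problem sizes and tolerances in the test suite

The suite runs everything at sizes a laptop handles in minutes, stated
here as the package's chosen configurations: carbonate checks are exact
desk calculations; kinetics equivalence uses a 135-point parameter grid
against the ODE oracle at 10⁻⁵ relative tolerance; hierarchical recovery
uses the full single-site design (12 pairs × 3 treatments × 8 dilutions ×
200 eggs) with 2 chains × (500 + 600) iterations, 10 replicate fits for
credible-interval coverage of a true 46% decline (≥ 8/10 required) plus 10
null fits whose mean decline probability must sit in 0.5 ± 0.1; the metric
solver is checked against 10⁵-point brute-force grids for 50 random
coefficient vectors; bootstrap null calibration uses 200 replicates of 150
draws with a Kolmogorov–Smirnov uniformity check at α = 0.01. The
sperm-decay sensitivity bound (10⁻³) is applied on the absolute scale of
the normal-fertilization fraction: the decay factor changes integrated
sperm exposure by ≈0.45% uniformly, so a strict relative bound is not
meaningful where the fraction itself is vanishing.

## Known limitations

* The published per-study posterior numbers (the 46% decline with 14–69%
  credible set at SB, variance-explained percentages, the χ² table) are
  not reproducible without the raw trial records; the machinery that would
  compute each of them is implemented and exercised on synthetic data.
* β and γ are separated only by prior information plus the weak βE_T
  depletion term; reported β levels are prior-sensitive even though
  treatment *contrasts* of β are data-driven through the βγ products.
* The GLMM uses random intercepts (not random polynomial coefficients) by
  pair and treatment-within-pair; full random curves are identifiable only
  with many more pairs than the design provides.
* The carbonate module omits nutrient alkalinity and the spectrophotometric
  dye-offset correction; both are sub-percent effects here.
* The MCMC sampler is exactly reproducible only for a fixed iteration
  budget and R RNG version (R's default generator, seeded per chain).
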