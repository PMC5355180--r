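# fertdyn

Analysis pipeline for sea-urchin fertilization trials run across seawater pH
treatments and serial sperm dilutions, built for the study design of
*Strongylocentrotus purpuratus* experiments in the California Current: unique
male–female pairs from three sites (FC, BMR, SB) with different natural pH
variability regimes, three pH treatments per site, eight 1:10 sperm
dilutions, 30 s sperm–egg contact, and 200 embryos scored per vial.

The package answers two questions about such data:

1. **Phenomenologically** — how do the total (TF), abnormal (AbnF) and
   normal (NF = TF·(1−AbnF)) fertilization functions of sperm concentration
   shift with site and pH? Cubic logit binomial mixed models (pair and
   treatment-within-pair random intercepts, observation-level logit-normal
   overdispersion) feed likelihood-ratio tests, logit-scale variance
   partitioning, and numerically solved sperm-requirement metrics —
   `S_NF50`, `S_OptNF`, `S_AbnF25` — with fully parametric bootstrap
   confidence intervals and Bonferroni-grouped within-site contrasts.

2. **Mechanistically** — are shifts driven by the sperm–egg interaction
   rate β or the polyspermy block rate δ? The fertilization-kinetics model

   ```
   S'   = -(βE_T + r) S          E_U' = -βγS·E_U
   E_1' =  βγS·E_U - δE_1 - βγS·E_1
   E_N' =  δE_1                  E_P' =  βγS·E_1
   ```

   gives the expected normal-fertilization fraction after the 30 s contact
   window as a one-dimensional integral evaluated by panelled
   Gauss–Legendre quadrature (an adaptive ODE solution is the built-in
   cross-check). A hierarchical Bayesian model with lognormal pair-level β
   and δ, truncated-normal γ, and a beta-binomial observation model is
   sampled by an adaptive Metropolis-within-Gibbs scheme aligned with the
   βγ-product ridge; posterior decline summaries compare each treatment
   with the pH 8.03 reference.

Because the study's raw trial records are not publicly deposited, the
package ships a first-class synthetic-data generator that reproduces the
design (FC 12, BMR 10, SB 12 pairs; 816 vials) with mechanistic outcome
probabilities, pair heterogeneity and beta-binomial scoring noise; every
stage of the pipeline is exercised and calibrated against it. A seawater
CO₂-system solver (Mehrbach constants refit by Dickson & Millero; CO2SYS
default ancillary constants) reproduces the reported treatment-water
chemistry from pH_T, total alkalinity, salinity and temperature.

## Worked example

```r
library(fertdyn)

# score a vial: 200 embryos, 50 unfertilized, 10 tight membranes, 5 abnormal
score_vial(vial_counts(200, 50, 10, 5))
#> $tf 0.75   $abnf 0.1   $nf 0.675   $abnf_defined TRUE

# treatment-water chemistry from measured means (FC, pH 7.61 treatment)
st <- solve_carbonate(ph_T = 7.61, A_T = 2245, S = 33.0, T = 14.8)
round(c(pco2 = st$pco2, omega_a = st$omega_a, dic = st$dic), 2)
#>    pco2 omega_a     dic
#> 1206.68    0.93 2202.04

# expected normal fertilization across sperm concentrations: rises with
# sperm supply, then falls as polyspermy takes over
p <- kinetics_params(beta = 3e-4, gamma = 0.05, delta = 0.2)
round(normal_fraction(p, c(1e2, 1e3, 1e4, 1e5)), 3)
#> 0.036 0.292 0.561 0.118

# simulate the full study with a 46% decline in beta at SB's pH 7.76
cfg <- sim_config(beta_scale = list(SB = c("7.76" = 0.54)))
sim <- simulate_trials(cfg, seed = 20170212)

# fertilization functions and sperm-requirement metrics
tf  <- fit_glmm(sim$trials, glmm_spec("tf"))
abn <- fit_glmm(sim$trials, glmm_spec("abnf"))
boot <- bootstrap_contrasts(tf, abn, n_boot = 1000, seed = 7)
subset(boot$estimates, site == "SB" & metric == "S_NF50",
       c(treatment, sperm_conc, lo95, hi95, group))
#>   treatment sperm_conc lo95 hi95 group
#>        7.76       2993 2342 3906     b     <- right-shifted curve
#>        7.87       1642 1332 2056     a
#>        8.03       1651 1348 1989     a
```

The right shift at SB 7.76 — about 1.8× more sperm needed for 50% normal
fertilization, with non-overlapping group letters — is the phenomenological
signature of the encoded interaction-rate decline. The mechanistic fit
recovers the rate itself: `analysis/04_kinetics_posterior.R` runs the
hierarchical model on the full simulated study and, for this scenario,
reports a posterior median β decline of 48% at SB 7.76 (truth: 46%) with
near-zero median β declines everywhere else (`results/declines.csv` holds
the full table of declines, 95% credible sets and decline probabilities;
β credible sets are wide by construction because β is reported
marginalized over the weakly identified acceptability parameter γ).

## Analysis workflow

The `analysis/` scripts run the pipeline end to end on the built-in
scenario and write tables under `results/`:

```sh
Rscript analysis/01_simulate_trials.R     # 816-vial study -> trials.csv, truth.csv
Rscript analysis/02_water_chemistry.R     # CO2 system vs reported chemistry
Rscript analysis/03_fertilization_curves.R  # GLMMs, LRTs, metrics, bootstrap
Rscript analysis/04_kinetics_posterior.R  # hierarchical Bayesian kinetics
Rscript analysis/05_report.R              # report tables (+ figures)
```

`run_pipeline()` performs the same sequence programmatically and writes a
checksummed run manifest. The methods vignette
(`vignettes/fertdyn-methods.Rmd`) documents the models, priors, numerical
choices and the calibration evidence behind each stage.

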