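# Seawater CO2-system solver on the total hydrogen-ion scale.
#
# K1/K2 follow the Mehrbach measurements as refit by Dickson & Millero (1987);
# ancillary constants follow the de-facto CO2-system-calculator defaults:
# Weiss (1974) K0 and fugacity, Dickson (1990) KB and KS, Millero (1995) KW,
# Perez & Fraga (1987) KF, Mucci (1983) aragonite Ksp, Uppstrom (1974) borate,
# Riley & Tongudai (1967) calcium.  Pressure fixed at 0 dbar (bench vials).

#' Equilibrium constants of the seawater CO2 system
#'
#' Evaluates the equilibrium constants and salinity-proportional totals used
#' by [solve_carbonate()], all converted to the total hydrogen-ion scale
#' (mol/kg-SW) at 0 dbar.
#'
#' @param S practical salinity, 0 < S < 45.
#' @param T temperature in degrees Celsius, -2 < T < 40.
#' @return list with `K0`, `K1`, `K2`, `KB`, `KW`, `KS` (free scale), `KF`,
#'   `Ksp_aragonite`, totals `BT`, `ST`, `FT`, `Ca` (mol/kg), the
#'   seawater-to-total scale factor `sws_to_tot`, and the CO2 fugacity
#'   coefficient `fugfac`.
#' @export
carbonate_constants <- function(S, T) {
  if (!is.finite(S) || S <= 0 || S >= 45) stop("salinity out of range (0, 45)")
  if (!is.finite(T) || T <= -2 || T >= 40) stop("temperature out of range (-2, 40) C")
  TK <- T + 273.15
  lnTK <- log(TK)
  sqS <- sqrt(S)

  # conservative totals, mol/kg-SW
  BT <- 0.0004157 * S / 35                    # Uppstrom 1974
  ST <- (0.14 / 96.062) * (S / 1.80655)       # Morris & Riley 1966
  FT <- (0.000067 / 18.998) * (S / 1.80655)   # Riley 1965
  Ca <- (0.02128 / 40.087) * (S / 1.80655)    # Riley & Tongudai 1967

  # bisulfate, free scale (Dickson 1990), ionic strength I
  I <- 19.924 * S / (1000 - 1.005 * S)
  lnKS <- -4276.1 / TK + 141.328 - 23.093 * lnTK +
    (-13856 / TK + 324.57 - 47.986 * lnTK) * sqrt(I) +
    (35474 / TK - 771.54 + 114.723 * lnTK) * I -
    2698 / TK * I^1.5 + 1776 / TK * I^2 + log(1 - 0.001005 * S)
  KS <- exp(lnKS)

  # hydrogen fluoride (Perez & Fraga 1987), total scale
  KF <- exp(874 / TK - 9.68 + 0.111 * sqS)

  sws_to_tot <- (1 + ST / KS) / (1 + ST / KS + FT / KF)

  # CO2 solubility (Weiss 1974), mol/kg/atm
  lnK0 <- -60.2409 + 93.4517 * (100 / TK) + 23.3585 * log(TK / 100) +
    S * (0.023517 - 0.023656 * (TK / 100) + 0.0047036 * (TK / 100)^2)
  K0 <- exp(lnK0)

  # carbonic acid (Mehrbach refit by Dickson & Millero 1987, seawater scale)
  pK1_sws <- 3670.7 / TK - 62.008 + 9.7944 * lnTK - 0.0118 * S + 0.000116 * S^2
  pK2_sws <- 1394.7 / TK + 4.777 - 0.0184 * S + 0.000118 * S^2
  K1 <- 10^(-pK1_sws) * sws_to_tot
  K2 <- 10^(-pK2_sws) * sws_to_tot

  # boric acid (Dickson 1990), total scale
  lnKB <- (-8966.90 - 2890.53 * sqS - 77.942 * S + 1.728 * S^1.5 -
             0.0996 * S^2) / TK +
    148.0248 + 137.1942 * sqS + 1.62142 * S +
    (-24.4344 - 25.085 * sqS - 0.2474 * S) * lnTK + 0.053105 * sqS * TK
  KB <- exp(lnKB)

  # water (Millero 1995), seawater scale -> total
  lnKW <- 148.9802 - 13847.26 / TK - 23.6521 * lnTK +
    (118.67 / TK - 5.977 + 1.0495 * lnTK) * sqS - 0.01615 * S
  KW <- exp(lnKW) * sws_to_tot

  # aragonite solubility (Mucci 1983), mol^2/kg^2
  log10Ksp <- -171.945 - 0.077993 * TK + 2903.293 / TK + 71.595 * log10(TK) +
    (-0.068393 + 0.0017276 * TK + 88.135 / TK) * sqS -
    0.10018 * S + 0.0059415 * S^1.5
  Ksp_aragonite <- 10^log10Ksp

  # fugacity coefficient of CO2 at 1 atm total pressure (Weiss 1974)
  B <- -1636.75 + 12.0408 * TK - 3.27957e-2 * TK^2 + 3.16528e-5 * TK^3  # cm3/mol
  delta <- 57.7 - 0.118 * TK
  RT <- 82.05736 * TK  # cm3 atm / mol
  fugfac <- exp((B + 2 * delta) / RT)

  out <- list(K0 = K0, K1 = K1, K2 = K2, KB = KB, KW = KW, KS = KS, KF = KF,
              Ksp_aragonite = Ksp_aragonite, BT = BT, ST = ST, FT = FT,
              Ca = Ca, sws_to_tot = sws_to_tot, fugfac = fugfac,
              S = S, T = T)
  if (any(!vapply(out, is.finite, logical(1))))
    stop("non-finite equilibrium constant")
  if (out$K1 <= out$K2) stop("constants violated K1 > K2")
  out
}

# Total alkalinity (mol/kg) at hydrogen-ion activity h (total scale) given DIC.
total_alkalinity <- function(h, dic, k) {
  denom <- h^2 + k$K1 * h + k$K1 * k$K2
  hco3 <- dic * k$K1 * h / denom
  co3 <- dic * k$K1 * k$K2 / denom
  boh4 <- k$BT * k$KB / (k$KB + h)
  oh <- k$KW / h
  h_free <- h / (1 + k$ST / k$KS)
  hso4 <- k$ST / (1 + k$KS / h_free)
  hf <- k$FT / (1 + k$KF / h)
  hco3 + 2 * co3 + boh4 + oh - h_free - hso4 - hf
}

#' Solve the seawater CO2 system from pH and total alkalinity
#'
#' Given pH on the total scale and total alkalinity at a stated salinity and
#' temperature, computes the full carbonate-system state: DIC, pCO2,
#' bicarbonate and carbonate ion concentrations, and the aragonite saturation
#' state.  This is the input pair reported for the fertilization-trial
#' treatment water.
#'
#' @param ph_T pH on the total hydrogen-ion scale.
#' @param A_T total alkalinity, micromol/kg-SW.
#' @param S practical salinity.
#' @param T temperature, degrees Celsius.
#' @return list of class `carbonate_state`: `ph_T`, `A_T`, `dic`, `pco2`
#'   (microatm), `fco2`, `hco3`, `co3` (micromol/kg), `omega_a`, `S`, `T`,
#'   `P` (0 dbar).
#' @export
solve_carbonate <- function(ph_T, A_T, S, T) {
  if (!is.finite(ph_T) || ph_T < 2 || ph_T > 12) stop("ph_T out of range")
  if (!is.finite(A_T) || A_T <= 0) stop("A_T must be positive (micromol/kg)")
  k <- carbonate_constants(S, T)
  h <- 10^(-ph_T)
  ta <- A_T * 1e-6
  # alkalinity balance is linear in DIC at fixed pH
  denom <- h^2 + k$K1 * h + k$K1 * k$K2
  carb_alk <- ta - total_alkalinity(h, 0, k)
  dic <- carb_alk * denom / (k$K1 * h + 2 * k$K1 * k$K2)
  if (dic <= 0) stop("no physical DIC for these inputs (carbonate alkalinity <= 0)")
  co2star <- dic * h^2 / denom
  hco3 <- dic * k$K1 * h / denom
  co3 <- dic * k$K1 * k$K2 / denom
  fco2 <- co2star / k$K0            # atm
  pco2 <- fco2 / k$fugfac
  omega_a <- k$Ca * co3 / k$Ksp_aragonite
  structure(list(ph_T = ph_T, A_T = A_T, dic = dic * 1e6,
                 pco2 = pco2 * 1e6, fco2 = fco2 * 1e6,
                 hco3 = hco3 * 1e6, co3 = co3 * 1e6,
                 omega_a = omega_a, S = S, T = T, P = 0),
            class = "carbonate_state")
}

#' pH of seawater from DIC and total alkalinity
#'
#' Inverts the alkalinity balance by a bracketed monotone root search on
#' pH in \[2, 12\] (relative tolerance 1e-10).
#'
#' @param dic dissolved inorganic carbon, micromol/kg-SW.
#' @param A_T total alkalinity, micromol/kg-SW.
#' @inheritParams solve_carbonate
#' @return pH on the total scale.
#' @export
ph_from_dic_alk <- function(dic, A_T, S, T) {
  k <- carbonate_constants(S, T)
  f <- function(ph) total_alkalinity(10^(-ph), dic * 1e-6, k) - A_T * 1e-6
  lo <- f(2); hi <- f(12)
  if (lo * hi > 0)
    stop("no pH root in [2, 12] for DIC = ", dic, ", A_T = ", A_T)
  stats::uniroot(f, c(2, 12), tol = 1e-10)$root
}

#' Convert a 25-degree spectrophotometric pH to in situ temperature
#'
#' Bench pH is measured spectrophotometrically at 25 C; the CO2 system of the
#' same water parcel is then evaluated at the in situ trial temperature.  DIC
#' and total alkalinity are conserved in the conversion: (pH@25, A_T) fixes
#' DIC, and (DIC, A_T) is re-solved for pH at the target temperature.
#'
#' @param ph_T_25C pH on the total scale measured at 25 C.
#' @param A_T total alkalinity, micromol/kg-SW.
#' @param S practical salinity.
#' @param T_insitu target temperature, degrees Celsius.
#' @return pH on the total scale at `T_insitu`.
#' @export
adjust_ph_to_insitu <- function(ph_T_25C, A_T, S, T_insitu) {
  if (identical(T_insitu, 25)) return(ph_T_25C)
  st25 <- solve_carbonate(ph_T_25C, A_T, S, 25)
  ph_from_dic_alk(st25$dic, A_T, S, T_insitu)
}

#' Batch CO2-system computation over a table
#'
#' @param chem data frame with columns `ph_T`, `alk`, `sal`, `temp`.
#' @return `chem` with `dic`, `pco2`, `omega_a`, `co3` appended.
#' @export
solve_carbonate_table <- function(chem) {
  need <- c("ph_T", "alk", "sal", "temp")
  missing <- setdiff(need, names(chem))
  if (length(missing))
    stop("chemistry table is missing column(s): ", paste(missing, collapse = ", "))
  states <- lapply(seq_len(nrow(chem)), function(i)
    solve_carbonate(chem$ph_T[i], chem$alk[i], chem$sal[i], chem$temp[i]))
  chem$dic <- vapply(states, `[[`, numeric(1), "dic")
  chem$pco2 <- vapply(states, `[[`, numeric(1), "pco2")
  chem$omega_a <- vapply(states, `[[`, numeric(1), "omega_a")
  chem$co3 <- vapply(states, `[[`, numeric(1), "co3")
  chem
}

#' Printed treatment-water chemistry of the fertilization trials
#'
#' Per-site, per-treatment means of the measured trial conditions (pH on the
#' total scale, total alkalinity, salinity, temperature) together with the
#' reported pCO2 and aragonite saturation state, as published for the three
#' study sites (FC, BMR, SB).
#'
#' @return data frame with columns `site`, `treatment`, `temp_c`, `ph_t`,
#'   `pco2_uatm`, `omega_a`, `alk_umol_kg`, `salinity`.
#' @export
treatment_conditions <- function() {
  path <- system.file("extdata", "treatment_conditions.csv",
                      package = "fertdyn", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(treatment = "character"))
}
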