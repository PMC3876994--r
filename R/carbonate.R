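# Aragonite saturation state from atmospheric CO2 and temperature.
#
# The growth module needs the aragonite saturation state (Omega_a) of
# surface seawater in equilibrium with a given atmospheric pCO2. Rather than
# requiring an external carbonate-chemistry package, a reduced equilibrium
# calculation is built in: total alkalinity and pCO2 fix the carbonate
# system, and the carbonate-alkalinity balance is solved in closed form
# (a quadratic in 1/[H+]) with the borate and water contributions folded in
# by a short fixed-point iteration. Equilibrium constants: Weiss (1974) K0,
# Lueker et al. (2000) K1/K2 (total pH scale), Dickson (1990) KB, Millero
# (1995) KW, Mucci (1983) aragonite Ksp; boron and calcium scale with
# salinity. Phosphate/silicate alkalinity and the fugacity correction are
# neglected -- a sub-percent effect at open-ocean surface conditions. Users
# with an externally computed Omega_a series can bypass this entirely (see
# run_pipeline()'s omega argument).

#' Seawater carbonate-system settings
#'
#' Inputs held fixed when converting atmospheric CO2 to an aragonite
#' saturation state. The defaults describe generic warm surface seawater.
#'
#' @param total_alkalinity micro-mol/kg (default 2300).
#' @param salinity practical salinity, in \[20, 40\] (default 35).
#' @return An object of class `"carbonate_settings"`.
#' @export
carbonate_settings <- function(total_alkalinity = 2300, salinity = 35) {
  if (total_alkalinity <= 0) stopf("total alkalinity must be positive")
  if (salinity < 20 || salinity > 40) stopf("salinity must be in [20, 40]")
  structure(list(total_alkalinity = total_alkalinity, salinity = salinity,
                 method = "reduced equilibrium (TA + pCO2)"),
            class = "carbonate_settings")
}

# Equilibrium constants at temperature t_c (C) and salinity sal.
# All on mol/kg-SW; K1/K2 on the total pH scale.
carbonate_constants <- function(t_c, sal) {
  TK <- t_c + 273.15
  lnK0 <- -60.2409 + 93.4517 * (100 / TK) + 23.3585 * log(TK / 100) +
    sal * (0.023517 - 0.023656 * (TK / 100) + 0.0047036 * (TK / 100)^2)
  pK1 <- 3633.86 / TK - 61.2172 + 9.6777 * log(TK) -
    0.011555 * sal + 0.0001152 * sal^2
  pK2 <- 471.78 / TK + 25.929 - 3.16967 * log(TK) -
    0.01781 * sal + 0.0001122 * sal^2
  lnKB <- (-8966.90 - 2890.53 * sqrt(sal) - 77.942 * sal +
             1.728 * sal^1.5 - 0.0996 * sal^2) / TK +
    148.0248 + 137.1942 * sqrt(sal) + 1.62142 * sal +
    (-24.4344 - 25.085 * sqrt(sal) - 0.2474 * sal) * log(TK) +
    0.053105 * sqrt(sal) * TK
  lnKW <- 148.9802 - 13847.26 / TK - 23.6521 * log(TK) +
    (118.67 / TK - 5.977 + 1.0495 * log(TK)) * sqrt(sal) - 0.01615 * sal
  log10Ksp <- -171.945 - 0.077993 * TK + 2903.293 / TK +
    71.595 * log10(TK) +
    (-0.068393 + 0.0017276 * TK + 88.135 / TK) * sqrt(sal) -
    0.10018 * sal + 0.0059415 * sal^1.5
  list(K0 = exp(lnK0), K1 = 10^(-pK1), K2 = 10^(-pK2),
       KB = exp(lnKB), KW = exp(lnKW), Ksp = 10^log10Ksp,
       BT = 4.157e-4 * sal / 35, Ca = 0.01028 * sal / 35)
}

#' Aragonite saturation state from CO2 and temperature
#'
#' Computes Omega_a for surface seawater in equilibrium with atmospheric
#' CO2 at the stated total alkalinity and salinity. Omega_a declines as CO2
#' rises (ocean acidification) and feeds the coral growth modifier
#' ([growth_modifier()]). Vectorised over `co2_ppm` and `sst`.
#'
#' @param co2_ppm atmospheric CO2, ppm (> 0).
#' @param sst sea-surface temperature, degrees C.
#' @param settings a [carbonate_settings()].
#' @return Omega_a, dimensionless and positive; strictly decreasing in
#'   `co2_ppm` at fixed temperature.
#' @examples
#' aragonite_saturation(369, 27)  # about 3.76, year-2000 tropical surface
#' aragonite_saturation(785, 27)  # about 2.27 at the 2100 BAU concentration
#' @export
aragonite_saturation <- function(co2_ppm, sst,
                                 settings = carbonate_settings()) {
  if (any(!is.finite(co2_ppm)) || any(co2_ppm <= 0)) {
    stopf("CO2 concentration must be positive (ppm)")
  }
  n <- max(length(co2_ppm), length(sst))
  co2_ppm <- rep_len(co2_ppm, n)
  sst <- rep_len(sst, n)
  ta <- settings$total_alkalinity * 1e-6
  vapply(seq_len(n), function(i) {
    k <- carbonate_constants(sst[i], settings$salinity)
    co2aq <- k$K0 * co2_ppm[i] * 1e-6
    b <- k$K1 * co2aq            # [HCO3-] = b / h
    a <- 2 * k$K1 * k$K2 * co2aq # 2[CO3--] = a / h^2
    h <- 1e-8
    for (it in 1:8) {
      # carbonate alkalinity after removing borate/water terms at current h
      ca <- ta - k$BT * k$KB / (k$KB + h) - k$KW / h + h
      if (ca <= 0) stopf("alkalinity too low for a stable carbonate solution")
      u <- (-b + sqrt(b^2 + 4 * a * ca)) / (2 * a) # u = 1/h, positive root
      h <- 1 / u
    }
    co3 <- k$K1 * k$K2 * co2aq / h^2
    k$Ca * co3 / k$Ksp
  }, numeric(1))
}

#' Annual aragonite-saturation series for a scenario
#'
#' Convenience wrapper: evaluates [aragonite_saturation()] year by year over
#' an annual CO2 series and an annual mean-SST series.
#'
#' @param co2 an [annual_series] of CO2 ppm.
#' @param sst_annual an [annual_series] of annual-mean SST (degrees C), or a
#'   scalar used for every year.
#' @param settings a [carbonate_settings()].
#' @return An [annual_series] of Omega_a.
#' @export
omega_series <- function(co2, sst_annual, settings = carbonate_settings()) {
  if (length(sst_annual) == 1) sst_annual <- rep(sst_annual, n_sim_years())
  annual_series(aragonite_saturation(as.numeric(co2),
                                     as.numeric(sst_annual), settings))
}
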