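# Independent oracles and small fixture builders shared across tests.

# Brute-force carbonate-system oracle: solves the full total-alkalinity
# balance (HCO3 + 2*CO3 + B(OH)4 + OH - H = TA) for pH by root bracketing,
# then evaluates the aragonite saturation state. Deliberately a different
# numerical route from the package's quadratic/fixed-point solver.
oracle_omega <- function(co2_ppm, t_c, ta_umol = 2300, sal = 35) {
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
  log10Ksp <- -171.945 - 0.077993 * TK + 2903.293 / TK + 71.595 * log10(TK) +
    (-0.068393 + 0.0017276 * TK + 88.135 / TK) * sqrt(sal) -
    0.10018 * sal + 0.0059415 * sal^1.5
  K0 <- exp(lnK0); K1 <- 10^(-pK1); K2 <- 10^(-pK2)
  KB <- exp(lnKB); KW <- exp(lnKW); Ksp <- 10^log10Ksp
  BT <- 4.157e-4 * sal / 35; Ca <- 0.01028 * sal / 35
  ta <- ta_umol * 1e-6
  co2aq <- K0 * co2_ppm * 1e-6
  resid <- function(ph) {
    h <- 10^(-ph)
    hco3 <- K1 * co2aq / h
    co3 <- K2 * hco3 / h
    (hco3 + 2 * co3 + BT * KB / (KB + h) + KW / h - h) - ta
  }
  ph <- stats::uniroot(resid, c(4, 11), tol = 1e-12)$root
  h <- 10^(-ph)
  Ca * (K1 * K2 * co2aq / h^2) / Ksp
}

# Brute-force two-point linear interpolation: for each target year find the
# bracketing anchors by scanning and interpolate with the line equation.
oracle_interp <- function(anchors_year, anchors_value, years) {
  vapply(years, function(y) {
    if (y <= min(anchors_year)) {
      return(anchors_value[which.min(anchors_year)])
    }
    if (y >= max(anchors_year)) {
      return(anchors_value[which.max(anchors_year)])
    }
    ord <- order(anchors_year)
    ay <- anchors_year[ord]; av <- anchors_value[ord]
    i <- max(which(ay <= y))
    if (ay[i] == y) return(av[i])
    av[i] + (av[i + 1] - av[i]) * (y - ay[i]) / (ay[i + 1] - ay[i])
  }, numeric(1))
}

# A flat climatology: every month at `mean_c`, interannual SD `sd_c`.
# Month 9 is nudged up a hair so the "warmest month" is well defined.
flat_climatology <- function(mean_c, sd_c, warm_bump = 1e-6) {
  means <- rep(mean_c, 12)
  means[9] <- means[9] + warm_bump
  monthly_climatology(means, sd_c)
}

zero_warming <- function() annual_series(rep(0, 101))

constant_series <- function(x) annual_series(rep(x, 101))

# A one-cell fixture far below any bleaching threshold.
quiet_cell <- function(initial_cover = 38.4, mean_c = 20, sd_c = 0.3) {
  reef_cell("quiet", "hawaii", initial_cover, 1,
            flat_climatology(mean_c, sd_c))
}
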