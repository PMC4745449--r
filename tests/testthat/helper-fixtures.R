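# shared fixtures: the reference tabulation setting (n = 0.8, k = 1.2,
# Q = 1, converging taper) and an independent bisection root finder

table_fluid <- function(tau_y) hb_fluid(n = 0.8, k = 1.2, tau_y = tau_y)

R_STEN <- 0.78    # stenosis-throat radius: 0.975 * (1 - 0.2)
R_DILA <- 1.134   # dilatation-crest radius: 0.945 * (1 + 0.2)

# reference pressure-gradient tabulation (numerical / analytical) at both
# abnormal-segment midpoints of the default converging-tapered vessel
TAB_TAU_Y <- c(0.05, 0.1, 0.4, 0.8, 1.2, 1.6, 2, 2.4)
TAB_STEN_NUM <- c(17.9423, 18.1099, 19.1145, 20.4511, 21.7841, 23.1127,
                  24.4368, 25.7559)
TAB_STEN_ANA <- c(17.9424, 18.1104, 19.124, 20.4895, 21.8712, 23.2692,
                  24.6834, 26.1137)
TAB_DILA_NUM <- c(5.0954, 5.2106, 5.9001, 6.8133, 7.7185, 8.6152,
                  9.5037, 10.3845)
TAB_DILA_ANA <- c(5.0956, 5.2116, 5.9163, 6.8799, 7.8709, 8.8892,
                  9.9349, 11.008)

# plain bisection on the implicit-relation residual: independent of the
# Newton-Raphson path (no derivative, no analytical initial guess)
bisect_pressure_gradient <- function(R, Q, fluid, tol = 1e-13) {
  f <- function(x) flow_rate_residual(x, R, Q, fluid)
  lo <- 2 * fluid$tau_y / R + 1e-10
  hi <- lo + 1
  while (f(hi) > 0) hi <- hi * 2            # residual > 0 below the root
  while ((hi - lo) / hi > tol) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
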