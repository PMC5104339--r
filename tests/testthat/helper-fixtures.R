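# Shared fixtures: all data used by the tests is generated in code.

# Strip all between-subject and residual variability from a bundle, so that
# simulated "observations" are exact model predictions.
novar <- function(p) {
  p$variability$omega2[] <- 0
  p$variability$sigma2[] <- 0
  p
}

# A deliberately near-linear, near-one-compartment chain: absorption and
# plasma disposition much faster than the anabolite elimination half-life T
# (1 day), no saturation (huge SC50), no recycling. The anabolite then
# behaves like a bolus one-compartment system with t1/2 = T, the regime in
# which both operational-half-life criteria must cross ratio = 2 at
# tau = T (the crossing shifts by the anabolite peak delay, here ~0.005 d,
# so agreement is asymptotic in the separation of timescales).
linear_test_chain <- function(T_days = 1) {
  chain_params(
    analyte = "TFV",
    plasma = list(Ka = 2e4, Vc_F = 100, CL_F = 8e4, Vp_F = 1, Q_F = 5),
    ic = list(Kf = 1, SC50 = 1e12, Kel = log(2) / T_days, R = 0),
    dntp = list(dATP = list(R0 = 100, EC50 = 1e9, Emax = 1, Kout = 1,
                            gamma = NA_real_)),
    dose_ug = 1000)
}

# Trapezoid-rule convolution oracle for the linear limit of the IC state:
# with SC50 -> Inf and R = 0,  A4(t) = Kf * int_0^t C(s) exp(-Kel (t-s)) ds.
convolve_ic <- function(params, reg, times, dt = 5e-4) {
  grid <- seq(min(c(0, reg$time)), max(times), by = dt)
  C <- plasma_conc(grid, reg, params$plasma)
  kel <- params$ic$Kel
  vapply(times, function(t) {
    on <- grid <= t
    integrand <- C[on] * exp(-kel * (t - grid[on]))
    params$ic$Kf * sum((head(integrand, -1) + tail(integrand, -1)) / 2) * dt
  }, numeric(1))
}
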