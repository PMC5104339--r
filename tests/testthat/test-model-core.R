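tfv <- tfv_chain_params()
ftc <- ftc_chain_params()

test_that("derivatives honor the structural fixed points of the chain", {
  # all compartments zero: only the dNTP production terms are active
  d0 <- chain_rhs(0, rep(0, 8), tfv)[[1]]
  expect_equal(d0[1:6], rep(0, 6))
  expect_equal(d0[7], tfv$dntp$dATP$R0 * tfv$dntp$dATP$Kout)
  # dNTP pools at baseline with no drug: exact equilibrium
  deq <- chain_rhs(0, c(rep(0, 6), 155, 245), tfv)[[1]]
  expect_equal(deq, rep(0, 8))
  # anabolite at EC50 with pool at baseline: derivative exactly -R0/2
  # (half-maximal inhibition, Emax = Kout = 1); use the non-waning pool
  st <- c(0, 0, 0, 1020, 0, 0, 155, 245)
  d <- chain_rhs(0, st, tfv)[[1]]
  expect_equal(d[7], -0.5 * 155)
  # saturation state at SC50 halves the formation term
  conc <- 50
  st_free <- c(0, conc * tfv$plasma$Vc_F, 0, 0, 0, 0, 155, 245)
  st_sat <- c(0, conc * tfv$plasma$Vc_F, 0, 0, tfv$ic$SC50, 0, 155, 245)
  form_free <- chain_rhs(0, st_free, tfv)[[1]][4]
  form_sat <- chain_rhs(0, st_sat, tfv)[[1]][4]
  expect_equal(form_sat, form_free / 2)
})

test_that("an empty regimen leaves drug at zero and dNTPs flat at baseline", {
  reg <- regimen(numeric(0), numeric(0))
  tt <- seq(0, 20, by = 0.5)
  for (m in c("analytic", "ode")) {
    tr <- simulate_chain(tfv, reg, tt, method = m)
    expect_equal(tr$plasma, rep(0, length(tt)))
    expect_equal(tr$ic, rep(0, length(tt)))
    expect_equal(tr$dATP, rep(155, length(tt)), tolerance = 1e-8)
    expect_equal(tr$dGTP, rep(245, length(tt)), tolerance = 1e-8)
  }
})

test_that("closed-form and event-driven integration routes agree", {
  reg <- daily_regimen(4, 136000, analyte = "TFV")
  tt <- sort(unique(c(seq(0, 6, by = 0.05), 0.02, 0.07)))
  a <- simulate_chain(tfv, reg, tt, method = "analytic")
  o <- simulate_chain(tfv, reg, tt, method = "ode")
  for (col in c("plasma", "ic", "sat", "recycle", "dATP", "dGTP"))
    expect_lt(max(abs(a[[col]] - o[[col]]) / pmax(abs(o[[col]]), 1e-6)), 1e-5)
})

test_that("plasma kinetics are linear (dose superposition within 0.1%)", {
  tt <- seq(0, 8, by = 0.1)
  r1 <- regimen(c(0, 1, 2), c(136000, 136000, 136000))
  r2 <- regimen(c(0.5, 2), c(68000, 204000))
  c1 <- plasma_conc(tt, r1, tfv$plasma)
  c2 <- plasma_conc(tt, r2, tfv$plasma)
  sum_reg <- regimen(c(0, 0.5, 1, 2), c(136000, 68000, 136000, 340000))
  c12 <- plasma_conc(tt, sum_reg, tfv$plasma)
  expect_lt(max(abs(c12 - (c1 + c2)) / pmax(c1 + c2, 1e-9)), 1e-3)
  # and doubling every dose exactly doubles the simulated plasma profile
  tr1 <- simulate_chain(tfv, daily_regimen(3, 136000, analyte = "TFV"), tt)
  tr2 <- simulate_chain(tfv, daily_regimen(3, 272000, analyte = "TFV"), tt)
  nz <- tr1$plasma > 1e-9
  expect_equal(tr2$plasma[nz] / tr1$plasma[nz], rep(2, sum(nz)),
               tolerance = 1e-6)
  # while the anabolite is sub-additive (saturation of formation)
  expect_true(all(tr2$ic[tr1$ic > 1] < 2 * tr1$ic[tr1$ic > 1]))
})

test_that("anabolite steady-state exposure per dose is non-increasing in dose", {
  doses <- c(68000, 136000, 272000, 544000)
  avg <- vapply(doses, function(d) {
    tr <- steady_state_profile(tfv, tau = 1, n_doses = 25, dose_ug = d,
                               dntp = FALSE)
    last <- tr$time >= 24
    mean(tr$ic[last])
  }, numeric(1))
  expect_true(all(diff(avg / doses) < 0))
})

test_that("simulated tail slope matches the closed-form terminal eigenvalue", {
  # single plasma dose: log-slope of the late plasma tail = beta
  reg <- daily_regimen(1, 136000, analyte = "TFV")
  tt <- seq(3, 6, by = 0.25)
  conc <- simulate_chain(tfv, reg, tt, dntp = FALSE)$plasma
  slope <- -coef(lm(log(conc) ~ tt))[[2]]
  expect_equal(slope, plasma_halflives(tfv)$lambda2, tolerance = 1e-3)
})

test_that("all states stay nonnegative across randomized regimens", {
  set.seed(42)
  for (k in 1:5) {
    n <- sample(1:6, 1)
    reg <- regimen(sort(runif(n, 0, 5)), runif(n, 1e4, 5e5))
    tt <- seq(0, 10, by = 0.1)
    tr <- simulate_chain(tfv, reg, tt)
    expect_true(all(as.matrix(tr[, -1]) >= -1e-9))
    # dNTP pools never exceed baseline (inhibition only)
    expect_true(all(tr$dATP <= 155 * (1 + 1e-9)))
  }
})

test_that("dNTP pools return to baseline after washout", {
  # 10 daily doses then washout >> 10/Kout days
  reg <- daily_regimen(10, 136000, analyte = "TFV")
  tr <- simulate_chain(tfv, reg, c(0, 5, 10, 30, 40))
  end <- nrow(tr)
  # remaining anabolite (slow recycling tail) is far below EC50, so the
  # pool has relaxed back to baseline
  expect_lt(tr$ic[end], 1e-3 * tfv$dntp$dATP$EC50)
  expect_equal(tr$dATP[end], 155, tolerance = 0.01)
})

test_that("with no saturation and no recycling the IC state equals the convolution oracle", {
  p <- tfv
  p$ic$SC50 <- 1e12
  p$ic$R <- 0
  reg <- regimen(c(0, 1), c(136000, 136000))
  tt <- c(0.5, 1.5, 2.5, 4)
  sim <- simulate_chain(p, reg, tt, dntp = FALSE)$ic
  oracle <- convolve_ic(p, reg, tt)
  expect_equal(sim, oracle, tolerance = 5e-3)
})

test_that("steady-state profile accumulates and matches single-dose base case", {
  tr <- steady_state_profile(tfv, tau = 1, n_doses = 50, dntp = FALSE)
  first <- tr$time <= 1
  last <- tr$time >= 49
  expect_gt(max(tr$ic[last]) / max(tr$ic[first]), 1)
  # n_doses = 1 reduces to a plain single-dose simulation
  one <- steady_state_profile(tfv, tau = 2, n_doses = 1, dntp = FALSE)
  ref <- simulate_chain(tfv, daily_regimen(1, 136000, analyte = "TFV"),
                        one$time, dntp = FALSE)
  expect_equal(one$ic, ref$ic, tolerance = 1e-9)
  expect_warning(steady_state_profile(tfv, tau = 1, n_doses = 2,
                                      resolution = 0.5, dntp = FALSE),
                 "tau/20")
})

test_that("steady-state plasma interval AUC equals dose/CL within 1%", {
  tr <- steady_state_profile(tfv, tau = 1, n_doses = 50, dntp = FALSE)
  last <- which(tr$time >= 49)
  t <- tr$time[last]; v <- tr$plasma[last]
  auc <- sum(diff(t) * (head(v, -1) + tail(v, -1)) / 2)
  expect_equal(auc, 136000 / 1410, tolerance = 0.01)
})

test_that("regimen and trajectory plumbing validate their inputs", {
  expect_error(regimen(c(2, 1), 1), "nondecreasing")
  expect_error(regimen(c(1, 2), -5), ">= 0")
  reg <- daily_regimen(2, 136000, analyte = "TFV")
  expect_error(simulate_chain(tfv, reg, c(1, 0.5)), "sorted")
  long <- trajectory_long(simulate_chain(tfv, reg, seq(0, 3, 0.5)))
  expect_setequal(unique(long$stream), c("TFV", "TFVDP", "dATP", "dGTP"))
  expect_setequal(unique(long$units), c("ng/mL", "fmol/10^6 cells"))
})
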