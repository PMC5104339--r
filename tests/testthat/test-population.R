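tfv <- tfv_chain_params()
ftc <- ftc_chain_params()

test_that("covariate arithmetic matches the linear covariate models", {
  # male sex raises FTC central volume: 99.4 + 24.3 = 123.7 L (+24.4%)
  m <- apply_covariates(ftc, sex = 1)
  expect_equal(m$plasma$Vc_F, 123.7)
  expect_equal(m$plasma$Vc_F / 99.4 - 1, 0.2444, tolerance = 1e-3)
  # HIV infection raises FTC-TP formation: 41.6 + 31.3 = 72.9 /day (+75.2%)
  h <- apply_covariates(ftc, hiv = 1)
  expect_equal(h$ic$Kf, 72.9)
  expect_equal(h$ic$Kf / 41.6 - 1, 0.7524, tolerance = 1e-3)
  # reference subject: bundle unchanged; TFV chain has no covariates
  expect_equal(apply_covariates(ftc, sex = 0, hiv = 0), ftc)
  expect_equal(apply_covariates(tfv, sex = 1, hiv = 1), tfv)
})

test_that("individual sampling is lognormal around the typical value", {
  z <- novar(tfv)
  s <- sample_individual(z, seed = 1)
  expect_equal(s$params$plasma, z$plasma)
  expect_equal(s$params$ic, z$ic)
  # determinism: same seed, same subject
  s1 <- sample_individual(tfv, seed = 7)
  s2 <- sample_individual(tfv, seed = 7)
  expect_equal(s1, s2)
  expect_false(isTRUE(all.equal(
    s1$etas, sample_individual(tfv, seed = 8)$etas)))
  # median over many draws reproduces the typical value; CV% = 100 sqrt(w2)
  n <- 20000
  set.seed(42)
  draws <- vapply(seq_len(n), function(i)
    sample_individual(tfv)$params$ic$Kf, numeric(1))
  expect_equal(median(draws) / 1.4, 1, tolerance = 0.02)
  cv <- sd(draws) / mean(draws)
  expect_equal(cv, sqrt(exp(0.238) - 1), tolerance = 0.05)
  # the table convention 100*sqrt(omega2) for Vc/F: 0.288 -> 53.7 %CV
  expect_equal(100 * sqrt(0.288), 53.7, tolerance = 1e-3)
})

test_that("population sampling is reproducible and respects covariate distribution", {
  pop1 <- sample_population(50, ftc, seed = 3)
  pop2 <- sample_population(50, ftc, seed = 3)
  expect_equal(pop1, pop2)
  expect_true(all(vapply(pop1, function(s) s$hiv, numeric(1)) == 0))
  sexes <- vapply(sample_population(2000, novar(ftc), seed = 5),
                  function(s) s$sex, numeric(1))
  expect_equal(mean(sexes), 0.675, tolerance = 0.05)
})

test_that("residual error models are unbiased on their natural scale", {
  var <- tfv$variability
  # sigma = 0 returns the prediction unchanged
  v0 <- var; v0$sigma2[] <- 0
  expect_equal(as.numeric(apply_residual_error(c(1, 5), "plasma", v0)),
               c(1, 5))
  # exponential: CV of y/pred over many draws ~ sqrt(exp(s2)-1); for the
  # plasma stream s2 = 0.0745 this is ~27.3% (the table convention
  # 100*sqrt(s2) gives 27.3 directly)
  y <- apply_residual_error(rep(100, 1e5), "plasma", var, seed = 9)
  expect_equal(sd(log(y / 100)), sqrt(0.0745), tolerance = 0.02)
  expect_equal(100 * sqrt(0.0745), 27.3, tolerance = 0.003)
  expect_equal(mean(log(y / 100)), 0, tolerance = 0.01)
  # proportional: linear-scale unbiasedness, clipping at zero flagged
  yp <- apply_residual_error(rep(10, 1e5), "ic", var, seed = 9)
  expect_equal(mean(yp), 10, tolerance = 0.02)
  big <- variability_spec(c(Kf = 0), c(ic = 4), c(ic = "proportional"))
  yc <- apply_residual_error(rep(1, 1000), "ic", big, seed = 1)
  expect_true(any(attr(yc, "clipped")))
  expect_true(all(yc >= 0))
  # exponential model rejects nonpositive predictions
  expect_error(apply_residual_error(c(1, 0), "plasma", var), "positive")
})

test_that("baseline shrinkage estimator interpolates population and observed values", {
  # omega2 = 0: population value wins entirely
  expect_equal(baseline_r0(155, 200, 0, 0.258), 155)
  # sigma2 = 0, eta = 0: observed value trusted fully
  expect_equal(baseline_r0(155, 200, 0.22, 0), 200)
  # hand-computed weighted combination (dATP values)
  w <- 0.220 / (0.220 + 0.258)
  expect_equal(baseline_r0(155, 200, 0.220, 0.258),
               155 * (1 - w) + 200 * w)
  expect_equal(155 * (1 - w) + 200 * w, 175.7113, tolerance = 1e-6)
  # eta scales through the reduced exponent
  expect_equal(baseline_r0(155, 200, 0.220, 0.258, eta = 0.3),
               (155 * (1 - w) + 200 * w) * exp(0.3 * w))
  # with eta = 0 the estimate always lies between the two anchors
  set.seed(11)
  for (k in 1:20) {
    pm <- runif(1, 50, 500); ob <- runif(1, 50, 500)
    o2 <- runif(1, 0, 1); s2 <- runif(1, 1e-6, 1)
    r <- baseline_r0(pm, ob, o2, s2)
    expect_gte(r, min(pm, ob) - 1e-9)
    expect_lte(r, max(pm, ob) + 1e-9)
  }
  # missing observation falls back to the population-deviation form
  fb <- baseline_r0(155, NA, 0.22, 0.258, eta = 0.1)
  expect_true(attr(fb, "fallback"))
  expect_equal(as.numeric(fb), 155 * exp(0.1))
})
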