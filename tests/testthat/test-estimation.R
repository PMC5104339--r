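tfv <- tfv_chain_params()
ftc <- ftc_chain_params()

perturb <- function(p, factor = 1.3) lapply(p, function(x) x * factor)

test_that("plasma stage recovers typical values exactly from noise-free data", {
  tab <- generate_trial(n_neg = 1, n_pos = 0, tfv = novar(tfv),
                        chains = "tfv", lloq = lloq_spec(0, 0, 0, 0),
                        seed = 1)
  fit <- fit_stage(tab, "plasma", analyte = "TFV",
                   init = perturb(tfv$plasma, 1.3), n_starts = 1)
  expect_true(fit$converged)
  expect_equal(fit$estimates[["CL_F"]], 1410, tolerance = 0.01)
  expect_equal(fit$estimates[["Vc_F"]], 390, tolerance = 0.01)
  expect_equal(fit$estimates[["Q_F"]], 5390, tolerance = 0.01)
  expect_equal(fit$estimates[["Vp_F"]], 877, tolerance = 0.01)
  expect_lt(fit$rss, 1e-8)
})

test_that("estimation error vanishes as residual noise goes to zero", {
  # recovery consistency checked at sigma in {0, 0.01}: the sigma = 0 fit
  # is exact (above); a tiny sigma moves estimates only slightly
  small <- novar(tfv)
  small$variability$sigma2["plasma"] <- 0.01^2
  tab <- generate_trial(n_neg = 2, n_pos = 0, tfv = small, chains = "tfv",
                        lloq = lloq_spec(0, 0, 0, 0), seed = 5)
  fit <- fit_stage(tab, "plasma", analyte = "TFV",
                   init = perturb(tfv$plasma, 0.8), n_starts = 1)
  expect_true(fit$converged)
  expect_equal(fit$estimates[["CL_F"]], 1410, tolerance = 0.02)
  expect_equal(fit$estimates[["Vc_F"]], 390, tolerance = 0.05)
})

test_that("intracellular stage recovers the link parameters given fixed plasma", {
  tab <- generate_trial(n_neg = 1, n_pos = 0, tfv = novar(tfv),
                        chains = "tfv", lloq = lloq_spec(0, 0, 0, 0),
                        seed = 2)
  fit <- fit_stage(tab, "intracellular", analyte = "TFV",
                   fixed_upstream = tfv$plasma,
                   init = list(Kf = 1.8, SC50 = 5, Kel = 0.3, R = 0.1),
                   n_starts = 1)
  expect_true(fit$converged)
  expect_equal(fit$estimates[["Kf"]], 1.4, tolerance = 0.01)
  expect_equal(fit$estimates[["SC50"]], 6.55, tolerance = 0.02)
  expect_equal(fit$estimates[["Kel"]], 0.228, tolerance = 0.02)
  expect_equal(fit$estimates[["R"]], 0.0582, tolerance = 0.1)
})

test_that("dNTP stage recovers baseline and potency, and flags the no-information case", {
  tab <- generate_trial(n_neg = 1, n_pos = 0, tfv = novar(tfv),
                        chains = "tfv", lloq = lloq_spec(0, 0, 0, 0),
                        seed = 3)
  up <- list(plasma = tfv$plasma, ic = tfv$ic)
  fit <- fit_stage(tab, "dntp", analyte = "TFV", dntp_stream = "dATP",
                   fixed_upstream = up,
                   init = list(R0 = 120, EC50 = 2000), n_starts = 1)
  expect_true(fit$converged)
  expect_equal(fit$estimates[["R0"]], 155, tolerance = 0.01)
  expect_equal(fit$estimates[["EC50"]], 1020, tolerance = 0.05)
  # upstream with zero anabolite exposure: EC50 not identifiable
  no_drug <- up
  no_drug$ic$Kf <- 1e-12
  flagged <- fit_stage(tab, "dntp", analyte = "TFV", dntp_stream = "dATP",
                       fixed_upstream = no_drug, n_starts = 1)
  expect_false(flagged$converged)
  expect_match(flagged$message, "not identifiable")
  expect_null(flagged$estimates)
})

test_that("sequential contract: the plasma stage is unaffected by downstream fitting", {
  tab <- generate_trial(n_neg = 1, n_pos = 0, tfv = novar(tfv),
                        chains = "tfv", lloq = lloq_spec(0, 0, 0, 0),
                        seed = 8)
  f1 <- fit_stage(tab, "plasma", analyte = "TFV", n_starts = 1)
  invisible(fit_stage(tab, "intracellular", analyte = "TFV",
                      fixed_upstream = f1$estimates |> as.list(),
                      n_starts = 1))
  f2 <- fit_stage(tab, "plasma", analyte = "TFV", n_starts = 1)
  expect_equal(f1$estimates, f2$estimates)
})

test_that("covariate likelihood-ratio thresholds follow the staged selection rules", {
  # forward selection at alpha = 0.01: include iff OFV drops by >= 6.64
  expect_equal(lrt_covariate(100, 100 - 6.76, "forward")$decision, "include")
  expect_equal(lrt_covariate(100, 100 - 6.0, "forward")$decision, "exclude")
  expect_equal(lrt_covariate(100, 100 - 20.5, "forward")$decision, "include")
  # backward elimination at alpha = 0.001: retain iff removal raises OFV
  # by more than 10.8
  expect_equal(lrt_covariate(100, 100 - 10.9, "backward")$decision, "retain")
  expect_equal(lrt_covariate(100, 100 - 10.0, "backward")$decision, "drop")
  # non-converged fits are refused
  bad <- structure(list(converged = FALSE, objective = 1),
                   class = "fit_result")
  expect_error(lrt_covariate(bad, 90, "forward"), "converge")
})

test_that("MAP step pulls individual plasma parameters toward the data", {
  tab <- generate_trial(n_neg = 3, n_pos = 0, chains = "tfv", seed = 21)
  maps <- map_plasma_individuals(tab, tfv, "TFV")
  expect_length(maps, 3)
  expect_setequal(names(maps), unique(tab$ID))
  # individual estimates deviate from the typical values but stay within a
  # plausible lognormal range
  cl <- vapply(maps, `[[`, numeric(1), "CL_F")
  expect_true(any(abs(log(cl / 1410)) > 0.01))
  expect_true(all(abs(log(cl / 1410)) < 4 * sqrt(0.117)))
})
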