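# Kinetic summaries: closed-form phase half-lives of the plasma and
# intracellular two-compartment systems, the simulation-based operational
# multiple-dosing half-life, and dNTP pool reduction profiles.

phase_halflives <- function(lambda1, lambda2, degenerate = FALSE) {
  structure(list(
    lambda1 = lambda1, lambda2 = lambda2,
    alpha_days = log(2) / lambda1,
    beta_days = if (is.na(lambda2)) NA_real_ else log(2) / lambda2,
    alpha_hours = 24 * log(2) / lambda1,
    beta_hours = if (is.na(lambda2)) NA_real_ else 24 * log(2) / lambda2,
    degenerate = degenerate), class = "phase_halflives")
}

#' @export
print.phase_halflives <- function(x, ...) {
  cat(sprintf("alpha half-life: %.3g h (lambda1 = %.4g /day)\n",
              x$alpha_hours, x$lambda1))
  if (!is.na(x$lambda2))
    cat(sprintf("beta  half-life: %.3g h = %.3g d (lambda2 = %.4g /day)\n",
                x$beta_hours, x$beta_days, x$lambda2))
  else cat("single phase (degenerate system)\n")
  invisible(x)
}

#' Plasma distribution/terminal half-lives (two-compartment)
#'
#' Eigenvalues of the disposition matrix with micro-rates
#' `k10 = CL/Vc`, `k12 = Q/Vc`, `k21 = Q/Vp`:
#' `lambda = (s +/- sqrt(s^2 - 4p))/2`, `s = k10 + k12 + k21`,
#' `p = k10 * k21`; half-lives are `ln 2 / lambda`. With `Q = 0` the system
#' degenerates to one compartment with a single eigenvalue `CL/Vc`.
#'
#' @param plasma plasma parameter list (see [chain_params()]), or a full
#'   `chain_params` bundle.
#' @return A `phase_halflives` object with `lambda1` (alpha) and `lambda2`
#'   (beta) in 1/day and half-lives in hours and days.
#' @export
plasma_halflives <- function(plasma) {
  if (inherits(plasma, "chain_params")) plasma <- plasma$plasma
  if (plasma$Q_F == 0)
    return(phase_halflives(plasma$CL_F / plasma$Vc_F, NA_real_,
                           degenerate = TRUE))
  m <- plasma_micro(plasma)
  phase_halflives(m$alpha, m$beta)
}

#' Intracellular anabolite phase half-lives
#'
#' The IC central + recycling pair is a linear two-compartment system with
#' elimination `k40 = (1 - R) * Kel` and symmetric exchange
#' `k46 = k64 = R * Kel`, giving `s = Kel (1 + R)` and
#' `p = R (1 - R) Kel^2`. The fast eigenvalue sets the alpha (initial
#' decline) half-life, the slow one the beta (terminal) half-life carried by
#' the recycling compartment. With `R = 0` the system is a single phase
#' (`alpha = ln2/Kel`, beta undefined and flagged degenerate).
#'
#' @param ic intracellular parameter list with `Kel` and `R`, or a full
#'   `chain_params` bundle.
#' @return A `phase_halflives` object.
#' @export
ic_halflives <- function(ic) {
  if (inherits(ic, "chain_params")) ic <- ic$ic
  if (ic$R == 0)
    return(phase_halflives(ic$Kel, NA_real_, degenerate = TRUE))
  s <- ic$Kel * (1 + ic$R)
  p <- ic$R * (1 - ic$R) * ic$Kel^2
  disc <- sqrt(s^2 - 4 * p)
  phase_halflives((s + disc) / 2, (s - disc) / 2)
}

#' Operational multiple-dosing half-life
#'
#' Simulation-based half-life for nonlinear kinetics: the dosing interval
#' `tau` at which a steady-state accumulation ratio equals 2. Two criteria
#' are supported: `"max_over_fd"` (`Cmax,ss : Cmax,fd = 2`, doubling of the
#' peak from first dose to steady state) and `"max_over_min"`
#' (`Cmax,ss : Cmin,ss = 2`, 50% peak-to-trough elimination at steady
#' state). For each candidate `tau`, `n_doses` doses of the typical subject
#' are simulated and the ratio read from the first and last dosing
#' intervals; the crossing of ratio = 2 is refined by bisection until
#' `|ratio - 2| < tol`, making the result independent of any coarse grid.
#'
#' @param params a `chain_params` bundle (typical individual).
#' @param criterion `"max_over_min"` or `"max_over_fd"`.
#' @param tau_range search interval in days; defaults to 1-9 d for the TFV
#'   chain and 0.05-2.5 d for the FTC chain, which bracket the crossings of
#'   both criteria at the shipped parameter sets.
#' @param n_doses doses per simulation (default 50, ensuring steady state).
#' @param stream trajectory column whose accumulation is measured
#'   (default `"ic"`, the anabolite).
#' @param tol tolerance on `|ratio - 2|`.
#' @return `tau*` in days, with attributes `criterion` and `evaluations`
#'   (the tau/ratio pairs visited).
#' @export
operational_halflife <- function(params,
                                 criterion = c("max_over_min", "max_over_fd"),
                                 tau_range = NULL, n_doses = 50,
                                 stream = "ic", tol = 1e-4) {
  criterion <- match.arg(criterion)
  if (is.null(tau_range))
    tau_range <- if (params$analyte == "TFV") c(1, 9) else c(0.05, 2.5)
  evals <- list()
  ratio <- function(tau) {
    m <- accumulation_metrics(params, tau, n_doses, stream = stream)
    r <- if (criterion == "max_over_min") m$Cmax_ss / m$Cmin_ss
         else m$Cmax_ss / m$Cmax_fd
    evals[[length(evals) + 1L]] <<- c(tau = tau, ratio = r)
    r
  }
  lo <- tau_range[1L]; hi <- tau_range[2L]
  f_lo <- ratio(lo) - 2; f_hi <- ratio(hi) - 2
  if (f_lo * f_hi > 0)
    stop(sprintf(
      "ratio - 2 does not change sign on [%g, %g] days (ratios %.4g, %.4g)",
      lo, hi, f_lo + 2, f_hi + 2), call. = FALSE)
  mid <- (lo + hi) / 2
  for (i in seq_len(80L)) {
    mid <- (lo + hi) / 2
    f_mid <- ratio(mid) - 2
    if (abs(f_mid) < tol || (hi - lo) < 1e-6) break
    if (f_mid * f_lo < 0) { hi <- mid; f_hi <- f_mid }
    else { lo <- mid; f_lo <- f_mid }
  }
  structure(mid, criterion = criterion,
            evaluations = do.call(rbind, evals))
}

#' dNTP pool reduction under repeated dosing
#'
#' Simulates the typical subject under `n_doses` doses at interval `tau` and
#' returns the fractional reduction `1 - A7/R0` of each requested pool over
#' time. The summary attribute reports the reduction at the steady-state
#' trough (`n_doses * tau`, i.e. one interval after the last dose), the
#' timepoint matching trough-oriented sampling. When a list of
#' `virtual_subject`s is supplied, their individual trough reductions are
#' summarized as 5/50/95 percentiles.
#'
#' @param params typical `chain_params` bundle.
#' @param pools dNTP names to report (default: all in the bundle).
#' @param tau dosing interval, days.
#' @param n_doses number of doses (default 30, the trial treatment length).
#' @param resolution output grid spacing in days.
#' @param subjects optional list of `virtual_subject`s for population
#'   percentiles.
#' @return Data frame `time`, `pool`, `reduction`, with attribute
#'   `trough_reduction` (named vector) and, when `subjects` is given,
#'   `population_quantiles`.
#' @export
dntp_reduction_profile <- function(params, pools = names(params$dntp),
                                   tau = 1, n_doses = 30, resolution = 0.05,
                                   subjects = NULL) {
  horizon <- n_doses * tau
  times <- sort(unique(c(seq(0, horizon, by = resolution), horizon)))
  reg <- daily_regimen(n_doses, params$dose_ug, tau = tau,
                       analyte = params$analyte)
  one <- function(p) {
    traj <- simulate_chain(p, reg, times)
    vapply(pools, function(nm) 1 - traj[[nm]] / p$dntp[[nm]]$R0,
           numeric(length(times)))
  }
  red <- one(params)
  out <- data.frame(
    time = rep(times, length(pools)),
    pool = rep(pools, each = length(times)),
    reduction = as.vector(red))
  trough <- red[length(times), , drop = TRUE]
  names(trough) <- pools
  attr(out, "trough_reduction") <- trough
  if (!is.null(subjects)) {
    tr <- vapply(subjects, function(s) {
      r <- one(s$params)
      r[length(times), , drop = TRUE]
    }, numeric(length(pools)))
    tr <- matrix(tr, nrow = length(pools))
    qs <- apply(tr, 1L, quantile, probs = c(0.05, 0.5, 0.95))
    colnames(qs) <- pools
    attr(out, "population_quantiles") <- qs
  }
  out
}
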