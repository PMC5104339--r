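# Monte-Carlo simulation of analog:dNTP molar ratios under on-demand
# (event-driven) PrEP dosing: a double dose 2-24 h before coitus, then
# single doses 24 h and 48 h after coitus.

#' On-demand PrEP dosing regimen relative to a coitus event at t = 0
#'
#' The two pre-coitus tablets are administered together as one double-dose
#' event at `-offset_h` hours; single doses follow at +24 h and +48 h.
#'
#' @param params a `chain_params` bundle (supplies the tablet dose).
#' @param offset_h hours between the double dose and coitus (2-24).
#' @return A [regimen()].
#' @export
prep_regimen <- function(params, offset_h = 24) {
  if (offset_h < 2 || offset_h > 24)
    stop("pre-coitus offset must lie in [2, 24] hours", call. = FALSE)
  regimen(c(-offset_h / 24, 1, 2),
          c(2 * params$dose_ug, params$dose_ug, params$dose_ug),
          analyte = params$analyte)
}

#' Default molar-ratio efficacy thresholds
#'
#' In-vitro CD4 T-cell viral-suppression thresholds for the analog:dNTP
#' molar ratios: TFV-DP:dATP EC50 = 0.086; FTC-TP:dCTP EC50 = 0.022 and
#' EC90 = 0.07.
#'
#' @return Named numeric vector (extensible map of thresholds).
#' @export
ratio_thresholds <- function() {
  c(tfvdp_datp_ec50 = 0.086, ftctp_dctp_ec50 = 0.022,
    ftctp_dctp_ec90 = 0.07)
}

#' Monte-Carlo simulation of analog:dNTP ratios under on-demand PrEP
#'
#' Simulates `n` virtual HIV-negative subjects under the on-demand regimen
#' over a one-week horizon and returns the pointwise molar ratios of the
#' analog to its competing substrate: TFV-DP:dATP for the TFV chain and
#' FTC-TP:dCTP for the FTC chain (both in fmol/10^6 cells, so the ratio is
#' dimensionless). The denominator is the subject's own simulated pool,
#' including its drug-induced reduction. The time grid runs every 0.1 days
#' plus early points 1e-4, 1e-3 and 1e-2 days after the first dose and the
#' coitus time itself.
#'
#' @param n number of virtual subjects.
#' @param offset_h hours from the double dose to coitus (2-24).
#' @param tfv,ftc chain bundles with variability.
#' @param chains which chains to simulate.
#' @param horizon days simulated after coitus (>= 2).
#' @param p_male male fraction of the virtual population.
#' @param seed integer seed; results are reproducible given it.
#' @return Data frame `subject, sex, ratio, time, value` of class
#'   `prep_sim` with attribute `offset_h`.
#' @export
simulate_prep <- function(n = 1000, offset_h = 24,
                          tfv = tfv_chain_params(), ftc = ftc_chain_params(),
                          chains = c("tfv", "ftc"), horizon = 7,
                          p_male = 0.675, seed = NULL) {
  stopifnot(n >= 1, horizon >= 2)
  bundles <- list(tfv = tfv, ftc = ftc)[chains]
  t0 <- -offset_h / 24
  times <- sort(unique(c(t0, t0 + c(1e-4, 1e-3, 1e-2),
                         seq(t0, horizon, by = 0.1), 0, 1, 2, horizon)))
  ratio_names <- c(tfv = "TFVDP:dATP", ftc = "FTCTP:dCTP")
  denom_pool <- c(tfv = "dATP", ftc = "dCTP")
  with_seed(seed, {
    sex <- rbinom(n, 1, p_male)
    out <- vector("list", n * length(bundles))
    k <- 0L
    for (i in seq_len(n)) {
      for (ch in names(bundles)) {
        par <- bundles[[ch]]
        subj <- sample_individual(par, sex = sex[i], hiv = 0,
                                  id = sprintf("S%04d", i))
        reg <- prep_regimen(par, offset_h)
        traj <- simulate_chain(subj$params, reg, times)
        denom <- traj[[denom_pool[[ch]]]]
        if (any(denom <= 0))
          stop("dNTP pool hit zero during simulation", call. = FALSE)
        k <- k + 1L
        out[[k]] <- data.frame(subject = i, sex = sex[i],
                               ratio = ratio_names[[ch]], time = times,
                               value = traj$ic / denom)
      }
    }
    structure(do.call(rbind, out), offset_h = offset_h,
              class = c("prep_sim", "data.frame"))
  })
}

#' Percentage of subjects with a ratio above a threshold
#'
#' @param sim a `prep_sim` from [simulate_prep()].
#' @param threshold molar-ratio threshold (> 0 gives a discriminating
#'   summary; 0 returns 100 for any dosed subject).
#' @param at_time evaluation time in days (0 = coitus); must be on the
#'   simulation grid.
#' @param ratio which ratio (`"TFVDP:dATP"` or `"FTCTP:dCTP"`).
#' @return Percentage (0-100) of subjects exceeding the threshold.
#' @export
percent_above <- function(sim, threshold, at_time = 0,
                          ratio = "TFVDP:dATP") {
  d <- sim[sim$ratio == ratio & abs(sim$time - at_time) < 1e-9, ]
  if (!nrow(d)) stop("no simulated values at time ", at_time,
                     " for ratio ", ratio, call. = FALSE)
  100 * mean(d$value > threshold)
}

#' Pointwise percentile bands of the simulated ratios
#'
#' @param sim a `prep_sim`.
#' @param probs percentiles (default 5th to 95th by 5).
#' @return Data frame `ratio, time, prob, value` (empirical quantiles per
#'   ratio and timepoint).
#' @export
percentile_bands <- function(sim, probs = seq(0.05, 0.95, by = 0.05)) {
  n <- length(unique(sim$subject))
  if (n < 20 && (min(probs) <= 0.05 || max(probs) >= 0.95))
    warning("outer percentiles unstable below 20 subjects", call. = FALSE)
  out <- list()
  for (rt in unique(sim$ratio)) {
    d <- sim[sim$ratio == rt, ]
    for (tt in sort(unique(d$time))) {
      q <- quantile(d$value[d$time == tt], probs = probs, names = FALSE)
      out[[length(out) + 1L]] <- data.frame(ratio = rt, time = tt,
                                            prob = probs, value = q)
    }
  }
  do.call(rbind, out)
}
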