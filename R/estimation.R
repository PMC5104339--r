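# Sequential-link estimation at desk scale.
#
# The population analysis this package emulates fits each link of the chain
# in sequence, fixing upstream parameters before estimating the downstream
# model. Here the estimation surface is deliberately simpler than a full
# marginal-likelihood mixed-effects fit: typical values are estimated by
# pooled nonlinear least squares on the residual-error scale (log residuals
# for exponential streams, relative residuals for proportional streams),
# optionally followed by per-subject MAP (empirical-Bayes) estimates given
# the between-subject variances. The objective reported is the
# -2 log-likelihood surrogate n*log(RSS/n).

stage_streams <- function(stage, analyte) {
  switch(stage,
         plasma = analyte,
         intracellular = if (analyte == "TFV") "TFVDP" else "FTCTP",
         stop("stage must be 'plasma', 'intracellular' or 'dntp'",
              call. = FALSE))
}

# theta <-> natural-scale parameter transforms per stage (log scale for
# positive parameters; logit for the recycling fraction R in (0,1))
stage_transform <- function(stage, gamma = FALSE) {
  switch(stage,
    plasma = list(
      names = c("Ka", "Vc_F", "CL_F", "Vp_F", "Q_F"),
      to_theta = function(p) log(unlist(p[c("Ka", "Vc_F", "CL_F",
                                            "Vp_F", "Q_F")])),
      from_theta = function(th) as.list(setNames(exp(th),
        c("Ka", "Vc_F", "CL_F", "Vp_F", "Q_F")))),
    intracellular = list(
      names = c("Kf", "SC50", "Kel", "R"),
      to_theta = function(p) c(log(p$Kf), log(p$SC50), log(p$Kel),
                               qlogis(p$R)),
      from_theta = function(th) list(Kf = exp(th[1]), SC50 = exp(th[2]),
                                     Kel = exp(th[3]), R = plogis(th[4]))),
    dntp = if (gamma) list(
      names = c("R0", "EC50", "gamma"),
      to_theta = function(p) log(c(p$R0, p$EC50, p$gamma)),
      from_theta = function(th) list(R0 = exp(th[1]), EC50 = exp(th[2]),
                                     gamma = exp(th[3])))
    else list(
      names = c("R0", "EC50"),
      to_theta = function(p) log(c(p$R0, p$EC50)),
      from_theta = function(th) list(R0 = exp(th[1]), EC50 = exp(th[2]))))
}

# Predicted intracellular anabolite at `times` given plasma params and
# candidate IC params (forced 3-state integration, no dNTP states).
predict_ic <- function(plasma, ic, reg, times) {
  conc <- function(t) plasma_conc(t, reg, plasma)
  k10 <- plasma$CL_F / plasma$Vc_F
  rhs <- function(t, y, p) {
    C <- conc(t)
    dA4 <- ic$Kf * C / (1 + y[2] / ic$SC50) - ic$Kel * y[1] +
      y[3] * ic$Kel * ic$R
    dA5 <- C * ic$Kf - y[2] * k10
    dA6 <- (y[1] - y[3]) * ic$Kel * ic$R
    list(c(dA4, dA5, dA6))
  }
  t0 <- min(c(times[1], reg$time))
  solve_t <- sort(unique(c(t0, times)))
  sol <- deSolve::lsoda(c(0, 0, 0), solve_t, rhs, NULL,
                        rtol = 1e-8, atol = 1e-10)
  sol[match(times, sol[, 1]), 2L]
}

# Predicted dNTP level given an anabolite forcing function a4fun.
predict_dntp <- function(block, a4fun, times, t_first_dose) {
  rhs <- function(t, y, p) {
    A4 <- a4fun(t)
    w <- dntp_waning(t, block$gamma, t_first_dose)
    list(block$R0 * block$Kout *
           (1 - w * block$Emax * A4 / (A4 + block$EC50)) - y * block$Kout)
  }
  t0 <- min(c(times[1], t_first_dose))
  solve_t <- sort(unique(c(t0, times)))
  sol <- deSolve::lsoda(block$R0, solve_t, rhs, NULL,
                        rtol = 1e-10, atol = 1e-12)
  sol[match(times, sol[, 1]), 2L]
}

#' Fit one stage of the sequential link model
#'
#' Minimizes the pooled sum of squared residuals on the stream's
#' error-model scale across all quantifiable observations of the stage's
#' stream (BLQ rows are excluded as missing). Upstream parameters are held
#' fixed: a single bundle applies one parameterization to every subject,
#' while a named list (per subject ID) fixes individual upstream parameters
#' as in sequential linking. Optimization uses Levenberg-Marquardt on
#' transformed parameters (log scale; logit for the recycling fraction)
#' with multi-start jitter to guard against local minima.
#'
#' @param table long dataset (see [generate_trial()]).
#' @param stage `"plasma"`, `"intracellular"` or `"dntp"`.
#' @param analyte `"TFV"` or `"FTC"` (selects the chain).
#' @param init named list of starting values for the stage's parameters
#'   (defaults: the shipped typical values).
#' @param fixed_upstream for `"intracellular"`: plasma parameter list or
#'   per-ID named list of such lists. For `"dntp"`: list with `plasma` and
#'   `ic` components (or per-ID named list of those).
#' @param dntp_stream for stage `"dntp"`: which pool to fit
#'   (`"dATP"`, `"dGTP"`, `"dCTP"`, `"TTP"`).
#' @param pooling `"pooled"` (one naive NLS over all observations — exact
#'   in the noise-free limit but biased for distribution parameters under
#'   strong lognormal between-subject variability), `"map"` (iterative
#'   two-stage MAP: per-subject empirical-Bayes etas penalized by the
#'   known `omega2` alternate with pooled typical-value updates; the
#'   recommended estimator for noisy multi-subject data), or
#'   `"two_stage"` (independent per-subject fits, typical values as
#'   geometric means — classical but fragile for weakly identified
#'   parameters).
#' @param n_starts number of jittered starts (first start is `init`).
#' @param jitter_sd lognormal jitter standard deviation for extra starts.
#' @param seed seed for the jitter.
#' @return A `fit_result`: list with `estimates` (named, natural scale),
#'   `objective` (`n log(RSS/n)`), `rss`, `n_obs`, `converged`, `message`,
#'   `stage`.
#' @export
fit_stage <- function(table, stage = c("plasma", "intracellular", "dntp"),
                      analyte = "TFV", init = NULL, fixed_upstream = NULL,
                      dntp_stream = NULL,
                      pooling = c("pooled", "map", "two_stage"),
                      n_starts = 5, jitter_sd = 0.3, seed = 1) {
  stage <- match.arg(stage)
  pooling <- match.arg(pooling)
  defaults <- if (analyte == "TFV") tfv_chain_params() else ftc_chain_params()
  err_model <- defaults$variability$error_model
  if (stage == "dntp") {
    if (is.null(dntp_stream) || !dntp_stream %in% names(defaults$dntp))
      stop("stage 'dntp' needs dntp_stream naming a pool of this chain",
           call. = FALSE)
    stream <- dntp_stream
  } else stream <- stage_streams(stage, analyte)
  obs <- table[table$EVID == 0L & table$DVID == stream & table$BLQ == 0L &
                 !is.na(table$DV), ]
  if (!nrow(obs)) stop("no quantifiable observations for stream ", stream,
                       call. = FALSE)
  err <- err_model[[stream_key_of(stream)]]
  ids <- unique(obs$ID)
  per_subject <- lapply(ids, function(id) {
    d <- obs[obs$ID == id, ]
    list(id = id, times = d$TIME, dv = d$DV,
         reg = regimen_from_dataset(table, id, analyte))
  })

  upstream_for <- function(id, component) {
    if (is.null(fixed_upstream)) return(NULL)
    u <- if (!is.null(names(fixed_upstream)) && id %in% names(fixed_upstream))
      fixed_upstream[[id]] else fixed_upstream
    if (!is.null(component) && component %in% names(u)) u[[component]] else u
  }

  has_gamma <- stage == "dntp" &&
    !is.na(defaults$dntp[[stream]]$gamma %||% NA_real_)
  tr <- stage_transform(stage, gamma = has_gamma)

  if (is.null(init)) {
    init <- switch(stage,
      plasma = defaults$plasma,
      intracellular = defaults$ic,
      dntp = {
        b <- defaults$dntp[[stream]]
        if (has_gamma) list(R0 = b$R0, EC50 = b$EC50, gamma = b$gamma)
        else list(R0 = b$R0, EC50 = b$EC50)
      })
  }

  # For the dNTP stage the anabolite trajectory does not depend on the
  # fitted parameters: precompute a forcing interpolant per subject.
  a4funs <- NULL
  if (stage == "dntp") {
    if (is.null(fixed_upstream))
      stop("stage 'dntp' requires fixed_upstream with plasma and ic",
           call. = FALSE)
    a4funs <- lapply(per_subject, function(s) {
      up <- upstream_for(s$id, NULL)
      # dose-aware grid: the anabolite has kinks right after each dose, so
      # cluster nodes there; linear interpolation on this grid keeps the
      # forcing error well below the EC50 sensitivity of the fit
      t_lo <- min(c(0, s$times, s$reg$time))
      t_hi <- max(s$times)
      post <- c(0.01, 0.025, 0.05, 0.1, 0.175, 0.25, 0.375, 0.5, 0.75)
      grid <- sort(unique(c(
        seq(t_lo, t_hi, by = 0.25),
        as.vector(outer(post, s$reg$time, `+`)),
        s$times, t_hi)))
      grid <- grid[grid >= t_lo & grid <= t_hi]
      a4 <- predict_ic(up$plasma, up$ic, s$reg, grid)
      approxfun(grid, a4, rule = 2)
    })
    peak <- max(vapply(a4funs, function(f) max(f(seq(0, 60, by = 0.5))),
                       numeric(1)))
    if (peak < 1e-8)
      return(structure(list(
        stage = stage, estimates = NULL, objective = NA_real_,
        rss = NA_real_, n_obs = nrow(obs), converged = FALSE,
        message = paste("anabolite exposure is identically zero:",
                        "EC50/R0 not identifiable from these data")),
        class = "fit_result"))
  }

  subj_pred <- function(i, p) {
    s <- per_subject[[i]]
    switch(stage,
      plasma = plasma_conc(s$times, s$reg, p),
      intracellular = {
        up <- upstream_for(s$id, "plasma")
        if (is.null(up)) stop("stage 'intracellular' requires ",
                              "fixed_upstream plasma parameters",
                              call. = FALSE)
        predict_ic(up, p, s$reg, s$times)
      },
      dntp = {
        b <- defaults$dntp[[stream]]
        block <- list(R0 = p$R0, EC50 = p$EC50, Emax = b$Emax,
                      Kout = b$Kout,
                      gamma = if (has_gamma) p$gamma else NA_real_)
        predict_dntp(block, a4funs[[i]], s$times,
                     t_first_dose = min(s$reg$time))
      })
  }
  scale_res <- function(i, pred) {
    dv <- per_subject[[i]]$dv
    if (err == "exponential") log(dv) - log(pmax(pred, 1e-12))
    else (dv - pred) / pmax(pred, 1e-12)
  }
  # parameters of this stage that carry between-subject variability
  omega2 <- defaults$variability$omega2
  iiv_names <- tr$names[tr$names %in% names(omega2) |
                          paste0(tr$names, "_", stream) %in% names(omega2)]
  iiv_var <- vapply(iiv_names, function(nm)
    if (nm %in% names(omega2)) omega2[[nm]]
    else omega2[[paste0(nm, "_", stream)]], numeric(1))
  with_etas <- function(p, eta) {
    for (j in seq_along(iiv_names))
      p[[iiv_names[j]]] <- p[[iiv_names[j]]] * exp(eta[j])
    p
  }
  residuals_for <- function(idx, etas = NULL) function(theta) {
    p <- tr$from_theta(theta)
    unlist(lapply(idx, function(i) {
      pi <- if (is.null(etas)) p else with_etas(p, etas[[i]])
      scale_res(i, subj_pred(i, pi))
    }))
  }

  theta0 <- tr$to_theta(init)
  starts <- with_seed(seed, {
    c(list(theta0),
      lapply(seq_len(max(0L, n_starts - 1L)), function(k)
        theta0 + rnorm(length(theta0), 0, jitter_sd)))
  })
  run_lm <- function(fn) {
    best <- NULL
    for (th in starts) {
      fit <- tryCatch(
        # epsfcn keeps the finite-difference step well above the ODE
        # integration noise, so flat directions (e.g. EC50 at low
        # exposure) retain a usable gradient
        minpack.lm::nls.lm(par = th, fn = fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 200, ftol = 1e-12, ptol = 1e-10,
                             epsfcn = 1e-6)),
        error = function(e) NULL)
      if (is.null(fit)) next
      if (is.null(best) || fit$deviance < best$deviance) best <- fit
    }
    best
  }
  failed <- function(msg)
    structure(list(stage = stage, stream = stream, estimates = NULL,
                   objective = NA_real_, rss = NA_real_,
                   n_obs = nrow(obs), converged = FALSE, message = msg),
              class = "fit_result")

  if (pooling == "pooled") {
    best <- run_lm(residuals_for(seq_along(per_subject)))
    if (is.null(best)) return(failed("all optimizer starts failed"))
    theta_hat <- best$par
    rss <- best$deviance
    n <- nrow(obs)
    objective <- n * log(rss / n)
    converged <- best$info %in% 1:4
    msg <- best$message
  } else if (pooling == "map") {
    # iterative two-stage MAP: alternate (a) per-subject empirical-Bayes
    # etas for the parameters with between-subject variance, penalized by
    # eta^2/omega^2, and (b) a pooled update of the typical values with
    # the etas held fixed. Parameters without variability stay common to
    # all subjects, which keeps weakly identified constants (e.g. Ka)
    # from running away in individual fits.
    if (!length(iiv_names))
      return(failed("map pooling needs parameters with omega2 > 0"))
    sigma2 <- defaults$variability$sigma2[[stream_key_of(stream)]]
    if (!length(sigma2) || sigma2 <= 0) sigma2 <- 0.05
    nsub <- length(per_subject)
    etas <- rep(list(numeric(length(iiv_names))), nsub)
    theta_hat <- theta0
    best <- NULL
    for (sweep in 1:8) {
      p_typ <- tr$from_theta(theta_hat)
      etas <- lapply(seq_len(nsub), function(i) {
        fn <- function(eta)
          c(scale_res(i, subj_pred(i, with_etas(p_typ, eta))) /
              sqrt(sigma2), eta / sqrt(iiv_var))
        fit <- tryCatch(suppressWarnings(minpack.lm::nls.lm(
          par = etas[[i]], fn = fn,
          control = minpack.lm::nls.lm.control(maxiter = 100,
                                               epsfcn = 1e-6))),
          error = function(e) NULL)
        if (is.null(fit)) etas[[i]] else fit$par
      })
      upd <- tryCatch(minpack.lm::nls.lm(
        par = theta_hat, fn = residuals_for(seq_len(nsub), etas),
        control = minpack.lm::nls.lm.control(maxiter = 100, ftol = 1e-12,
                                             ptol = 1e-10, epsfcn = 1e-6)),
        error = function(e) NULL)
      if (is.null(upd)) break
      shift <- max(abs(upd$par - theta_hat))
      theta_hat <- upd$par
      best <- upd
      if (shift < 1e-5) break
    }
    if (is.null(best)) return(failed("MAP iteration failed"))
    rss <- best$deviance
    n <- nrow(obs)
    objective <- n * log(rss / n)
    converged <- best$info %in% 1:4
    msg <- sprintf("iterative two-stage MAP, %d subjects", nsub)
  } else {
    fits <- lapply(seq_along(per_subject), function(i)
      run_lm(residuals_for(i)))
    ok <- !vapply(fits, is.null, logical(1))
    if (!any(ok)) return(failed("all per-subject fits failed"))
    thetas <- vapply(fits[ok], `[[`, numeric(length(theta0)), "par")
    thetas <- matrix(thetas, nrow = length(theta0))
    # typical values = mean on the transformed (log / logit) scale,
    # i.e. geometric means for positive parameters
    theta_hat <- rowMeans(thetas)
    rss <- sum(vapply(fits[ok], `[[`, numeric(1), "deviance"))
    n <- nrow(obs)
    objective <- sum(vapply(fits[ok], function(f) {
      ni <- length(f$fvec)
      ni * log(f$deviance / ni)
    }, numeric(1)))
    converged <- all(ok) &&
      all(vapply(fits[ok], function(f) f$info %in% 1:4, logical(1)))
    msg <- sprintf("two-stage: %d/%d subject fits converged", sum(ok),
                   length(fits))
  }
  est <- tr$from_theta(theta_hat)
  structure(list(stage = stage, stream = stream,
                 estimates = setNames(unlist(est), tr$names),
                 objective = objective, rss = rss, n_obs = n,
                 converged = converged,
                 message = msg), class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> stage %s (%s), n = %d, converged: %s\n",
              x$stage, x$stream %||% "-", x$n_obs, x$converged))
  if (!is.null(x$estimates)) {
    est <- x$estimates
    cat(paste(sprintf("  %-5s %.4g", names(est), est), collapse = "\n"), "\n")
    cat(sprintf("  objective (n log RSS/n): %.3f\n", x$objective))
  } else cat("  ", x$message, "\n")
  invisible(x)
}

#' Likelihood-ratio covariate decision
#'
#' Applies the staged covariate-selection thresholds for a single extra
#' parameter: forward inclusion at alpha = 0.01 requires the objective
#' function to drop by at least 6.64; backward retention at alpha = 0.001
#' requires that removing the covariate would raise it by more than 10.8.
#'
#' @param fit_without,fit_with nested `fit_result`s (or bare objective
#'   values); `fit_with` has one extra parameter.
#' @param mode `"forward"` or `"backward"`.
#' @return List with `decision` (`"include"`/`"exclude"` or
#'   `"retain"`/`"drop"`), `delta_ofv` and the threshold applied.
#' @export
lrt_covariate <- function(fit_without, fit_with,
                          mode = c("forward", "backward")) {
  mode <- match.arg(mode)
  ofv <- function(f) {
    if (inherits(f, "fit_result")) {
      if (!isTRUE(f$converged)) stop("fit did not converge", call. = FALSE)
      f$objective
    } else if (is.numeric(f) && length(f) == 1L) f
    else stop("expected a fit_result or a single objective value",
              call. = FALSE)
  }
  delta <- ofv(fit_with) - ofv(fit_without)
  if (mode == "forward") {
    list(decision = if (delta <= -6.64) "include" else "exclude",
         delta_ofv = delta, threshold = -6.64)
  } else {
    list(decision = if (-delta > 10.8) "retain" else "drop",
         delta_ofv = delta, threshold = 10.8)
  }
}

#' Per-subject MAP (empirical-Bayes) parameter estimates
#'
#' Given typical values and the between-subject variances, maximizes for
#' each subject the penalized objective
#' `sum(res^2)/sigma2 + sum(eta^2/omega2)` over the subject's random
#' effects, yielding individual parameter sets for sequential linking.
#' Implemented for the plasma stage (closed-form predictions).
#'
#' @param table long dataset.
#' @param params typical `chain_params` bundle (with variability).
#' @param analyte `"TFV"` or `"FTC"`.
#' @return Named list (by subject ID) of plasma parameter lists.
#' @export
map_plasma_individuals <- function(table, params, analyte = params$analyte) {
  var <- params$variability
  omega2 <- var$omega2[names(var$omega2) %in%
                         c("Ka", "Vc_F", "CL_F", "Vp_F", "Q_F")]
  sigma2 <- var$sigma2[["plasma"]]
  obs <- table[table$EVID == 0L & table$DVID == analyte & table$BLQ == 0L &
                 !is.na(table$DV), ]
  ids <- unique(obs$ID)
  out <- lapply(ids, function(id) {
    d <- obs[obs$ID == id, ]
    reg <- regimen_from_dataset(table, id, analyte)
    typ <- apply_covariates(params, sex = d$SEX[1L], hiv = d$HIV[1L])$plasma
    fn <- function(eta) {
      pl <- typ
      for (j in seq_along(omega2))
        pl[[names(omega2)[j]]] <- typ[[names(omega2)[j]]] * exp(eta[j])
      pred <- pmax(plasma_conc(d$TIME, reg, pl), 1e-12)
      c((log(d$DV) - log(pred)) / sqrt(sigma2), eta / sqrt(omega2))
    }
    fit <- minpack.lm::nls.lm(par = numeric(length(omega2)), fn = fn,
                              control = minpack.lm::nls.lm.control(
                                maxiter = 100))
    pl <- typ
    for (j in seq_along(omega2))
      pl[[names(omega2)[j]]] <- typ[[names(omega2)[j]]] * exp(fit$par[j])
    pl
  })
  names(out) <- ids
  out
}
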