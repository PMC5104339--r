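# Virtual populations: covariate effects, lognormal between-subject
# variability, residual-error models and the shrinkage estimator for the
# individual dNTP baseline.

#' Apply 0/1 covariates to a typical-value bundle
#'
#' Covariate effects are linear on the typical value (additive coefficient
#' switched on when the covariate equals 1), e.g. for the FTC chain
#' `Vc/F = 99.4 + 24.3 * sex` and `Kf = 41.6 + 31.3 * hiv`. The TFV chain
#' carries no covariates, so it is returned unchanged.
#'
#' @param params a `chain_params` bundle with a `covariates` block.
#' @param sex 0 = female, 1 = male.
#' @param hiv 0 = HIV-negative, 1 = HIV-positive.
#' @return The bundle with covariate-adjusted typical values.
#' @export
apply_covariates <- function(params, sex = 0, hiv = 0) {
  stopifnot(sex %in% c(0, 1), hiv %in% c(0, 1))
  vals <- c(sex = sex, hiv = hiv)
  for (nm in names(params$covariates)) {
    cv <- params$covariates[[nm]]
    if (!nm %in% names(vals))
      stop("unknown covariate in bundle: ", nm, call. = FALSE)
    new <- params[[cv$block]][[cv$field]] + cv$coef * vals[[nm]]
    if (new <= 0)
      stop(sprintf("covariate effect drives %s.%s nonpositive",
                   cv$block, cv$field), call. = FALSE)
    params[[cv$block]][[cv$field]] <- new
  }
  validate_chain_params(params)
  params
}

# Map an omega2 key to the list path inside a chain_params bundle.
param_path <- function(params, key) {
  if (key %in% c("Ka", "Vc_F", "CL_F", "Vp_F", "Q_F"))
    return(c("plasma", key))
  if (key %in% c("Kf", "SC50", "Kel", "R")) return(c("ic", key))
  m <- regmatches(key, regexec("^(R0|EC50)_(.+)$", key))[[1]]
  if (length(m) == 3L && m[3] %in% names(params$dntp))
    return(c("dntp", m[3], m[2]))
  stop("omega2 key does not name a chain parameter: ", key, call. = FALSE)
}

#' Sample one virtual subject
#'
#' Covariates are applied to the typical values, then each parameter with a
#' between-subject variance gets an independent lognormal deviation:
#' `param_i = tv * exp(eta)`, `eta ~ N(0, omega2)`.
#'
#' @param params typical-value `chain_params` bundle (with `variability`).
#' @param sex,hiv 0/1 covariates.
#' @param id subject label.
#' @param seed optional integer; if given, sampling is a deterministic
#'   function of it (the caller's RNG state is untouched).
#' @return A `virtual_subject`: list with `id`, `sex`, `hiv`, `etas` and the
#'   resolved `params` bundle.
#' @export
sample_individual <- function(params, sex = 0, hiv = 0, id = "1",
                              seed = NULL) {
  var <- params$variability
  if (is.null(var)) stop("bundle has no variability spec", call. = FALSE)
  base <- apply_covariates(params, sex = sex, hiv = hiv)
  with_seed(seed, {
    etas <- rnorm(length(var$omega2), 0, sqrt(var$omega2))
    names(etas) <- names(var$omega2)
    indiv <- base
    for (key in names(etas)) {
      path <- param_path(indiv, key)
      old <- indiv[[path]]
      indiv[[path]] <- old * exp(etas[[key]])
    }
    validate_chain_params(indiv)
    structure(list(id = id, sex = sex, hiv = hiv, etas = etas,
                   params = indiv),
              class = "virtual_subject")
  })
}

#' Sample a virtual population
#'
#' @param n number of subjects.
#' @param params typical-value bundle.
#' @param hiv scalar 0/1 applied to all subjects, or a length-`n` vector.
#'   Default 0 (HIV-negative, the PrEP simulation population).
#' @param p_male probability that a subject is male (study demographics:
#'   27/40).
#' @param seed integer seed controlling covariates and all deviations.
#' @return List of `virtual_subject`s.
#' @export
sample_population <- function(n, params, hiv = 0, p_male = 0.675,
                              seed = NULL) {
  stopifnot(n >= 1)
  hiv <- rep_len(hiv, n)
  with_seed(seed, {
    sex <- rbinom(n, 1, p_male)
    lapply(seq_len(n), function(i)
      sample_individual(params, sex = sex[i], hiv = hiv[i],
                        id = sprintf("S%03d", i)))
  })
}

#' Apply the residual-error model to model predictions
#'
#' Exponential: `y = pred * exp(eps)`; proportional: `y = pred * (1 + eps)`;
#' `eps ~ N(0, sigma2)` for the stream. Proportional errors can produce
#' negative observations for large `sigma`; those are clipped to zero and
#' flagged in the `"clipped"` attribute (they will typically fall below the
#' quantification limit downstream).
#'
#' @param pred numeric vector of model predictions (strictly positive for
#'   exponential streams).
#' @param stream stream key into the variability spec (`"plasma"`, `"ic"`,
#'   or a dNTP name).
#' @param var a [variability_spec()].
#' @param seed optional integer seed.
#' @return Numeric vector of simulated observations with attribute
#'   `"clipped"` (logical).
#' @export
apply_residual_error <- function(pred, stream, var, seed = NULL) {
  if (!stream %in% names(var$sigma2))
    stop("no residual variance for stream ", stream, call. = FALSE)
  model <- var$error_model[[stream]]
  sd <- sqrt(var$sigma2[[stream]])
  with_seed(seed, {
    eps <- rnorm(length(pred), 0, sd)
    if (model == "exponential") {
      if (any(pred <= 0))
        stop("exponential error model requires positive predictions",
             call. = FALSE)
      y <- pred * exp(eps)
      clipped <- rep(FALSE, length(y))
    } else {
      y <- pred * (1 + eps)
      clipped <- y < 0
      y[clipped] <- 0
    }
    structure(y, clipped = clipped)
  })
}

#' Shrinkage estimator of the individual dNTP baseline
#'
#' Weighted combination of the population mean baseline and the single
#' observed baseline, with weights set by the between-subject (`omega2`)
#' and residual (`sigma2`) variances:
#' \deqn{R_{0i} = \left(\hat R_0 \frac{\sigma^2}{\omega^2+\sigma^2} +
#'   R_{0i,o} \frac{\omega^2}{\omega^2+\sigma^2}\right)
#'   e^{\eta\,\omega^2/(\omega^2+\sigma^2)}}
#' When `omega2 = 0` the population value is returned; when `sigma2 = 0`
#' (and `eta = 0`) the observed value is trusted fully. A missing observed
#' baseline falls back to `pop_mean * exp(eta)` with attribute
#' `"fallback" = TRUE`.
#'
#' @param pop_mean population mean baseline (fmol/10^6 cells).
#' @param observed single observed individual baseline, or `NA`.
#' @param omega2 between-subject variance of the baseline.
#' @param sigma2 residual variance of the stream.
#' @param eta residual random effect (N(0, sigma2) draw), default 0.
#' @return Individual baseline estimate (numeric scalar).
#' @export
baseline_r0 <- function(pop_mean, observed, omega2, sigma2, eta = 0) {
  stopifnot(pop_mean > 0, omega2 >= 0, sigma2 >= 0)
  if (omega2 + sigma2 <= 0)
    stop("omega2 + sigma2 must be positive", call. = FALSE)
  w <- omega2 / (omega2 + sigma2)
  if (is.na(observed))
    return(structure(pop_mean * exp(eta), fallback = TRUE))
  if (observed <= 0) stop("observed baseline must be positive", call. = FALSE)
  (pop_mean * (1 - w) + observed * w) * exp(eta * w)
}
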