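# Parameter containers for one analyte chain:
#   plasma (2-compartment oral) -> intracellular anabolite -> two dNTP pools.
# Units: time in days, volumes in L, clearances in L/day, doses in ug of
# parent-drug equivalents, so A2/Vc_F is ug/L = ng/mL (the plasma assay unit).
# Intracellular anabolite and dNTP levels are fmol per 10^6 PBMC.

#' Construct a full parameter bundle for one analyte chain
#'
#' A chain couples the plasma pharmacokinetics of one analyte (TFV or FTC)
#' to its intracellular anabolite (TFV-DP or FTC-TP) and to the two
#' endogenous dNTP pools the analog competes with or perturbs.
#'
#' @param analyte `"TFV"` or `"FTC"`.
#' @param plasma named list with `Ka` (1/day), `Vc_F` (L), `CL_F` (L/day),
#'   `Vp_F` (L), `Q_F` (L/day); all strictly positive.
#' @param ic named list with `Kf` (1/day), `SC50` (ng/mL), `Kel` (1/day),
#'   `R` (recycling fraction in `[0, 1)`).
#' @param dntp named list of dNTP blocks, each a list with `R0`
#'   (fmol/10^6 cells), `EC50` (fmol/10^6 cells), `Emax` (fixed 1),
#'   `Kout` (fixed 1/day) and optional `gamma` (> 0, time-waning exponent).
#' @param dose_ug standard single-tablet dose in ug parent-drug equivalents.
#' @param covariates named list of covariate effects, each a list with
#'   `block` (`"plasma"` or `"ic"`), `field` and additive `coef` applied when
#'   the 0/1 covariate equals 1.
#' @param variability optional [variability_spec()].
#' @return An object of class `chain_params`.
#' @seealso [tfv_chain_params()], [ftc_chain_params()], [load_params()]
#' @export
chain_params <- function(analyte, plasma, ic, dntp, dose_ug,
                         covariates = list(), variability = NULL) {
  obj <- structure(
    list(analyte = analyte, plasma = plasma, ic = ic, dntp = dntp,
         dose_ug = dose_ug, covariates = covariates,
         variability = variability),
    class = "chain_params")
  validate_chain_params(obj)
  obj
}

#' Validate a `chain_params` bundle
#'
#' Checks all type invariants (positivity, `R` in `[0, 1)`, `Emax` and
#' `Kout` fixed to 1) and reports violations with their field path.
#'
#' @param p a `chain_params` object.
#' @return The bundle, invisibly, if valid; otherwise an error.
#' @export
validate_chain_params <- function(p) {
  stopifnot(inherits(p, "chain_params"))
  if (!p$analyte %in% c("TFV", "FTC"))
    stop("analyte must be 'TFV' or 'FTC'", call. = FALSE)
  need_pos <- function(x, path) {
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
      stop(sprintf("parameter '%s' must be a single positive number", path),
           call. = FALSE)
  }
  pl_fields <- c("Ka", "Vc_F", "CL_F", "Vp_F", "Q_F")
  extra <- setdiff(names(p$plasma), pl_fields)
  if (length(extra))
    stop("unknown plasma field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  for (f in pl_fields) need_pos(p$plasma[[f]], paste0("plasma.", f))
  ic_fields <- c("Kf", "SC50", "Kel", "R")
  extra <- setdiff(names(p$ic), ic_fields)
  if (length(extra))
    stop("unknown intracellular field(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  for (f in c("Kf", "SC50", "Kel")) need_pos(p$ic[[f]], paste0("ic.", f))
  R <- p$ic$R
  if (!is.numeric(R) || length(R) != 1L || is.na(R) || R < 0 || R >= 1)
    stop("ic.R (recycling fraction) must lie in [0, 1)", call. = FALSE)
  if (length(p$dntp) < 1L || is.null(names(p$dntp)))
    stop("dntp must be a named list of dNTP blocks", call. = FALSE)
  for (nm in names(p$dntp)) {
    b <- p$dntp[[nm]]
    extra <- setdiff(names(b), c("R0", "EC50", "Emax", "Kout", "gamma"))
    if (length(extra))
      stop(sprintf("unknown dntp.%s field(s): %s", nm,
                   paste(extra, collapse = ", ")), call. = FALSE)
    need_pos(b$R0, paste0("dntp.", nm, ".R0"))
    need_pos(b$EC50, paste0("dntp.", nm, ".EC50"))
    if (!identical(as.numeric(b$Emax), 1))
      stop(sprintf("dntp.%s.Emax is fixed to 1", nm), call. = FALSE)
    if (!identical(as.numeric(b$Kout), 1))
      stop(sprintf("dntp.%s.Kout is fixed to 1/day", nm), call. = FALSE)
    if (!is.null(b$gamma) && !is.na(b$gamma))
      need_pos(b$gamma, paste0("dntp.", nm, ".gamma"))
  }
  need_pos(p$dose_ug, "dose_ug")
  invisible(p)
}

dntp_block <- function(R0, EC50, gamma = NA_real_) {
  list(R0 = R0, EC50 = EC50, Emax = 1, Kout = 1, gamma = gamma)
}

#' Variability specification (between-subject and residual)
#'
#' @param omega2 named numeric vector of between-subject variances on the
#'   exponential scale; names are parameter keys (`Vc_F`, `CL_F`, `Vp_F`,
#'   `Q_F`, `Kf`, `Kel`, and `R0_<dNTP>` / `EC50_<dNTP>` for dNTP blocks).
#' @param sigma2 named numeric vector of residual variances per observation
#'   stream key (`plasma`, `ic`, or a dNTP name).
#' @param error_model named character vector mapping each stream key to
#'   `"exponential"` or `"proportional"`.
#' @return An object of class `variability_spec`.
#' @export
variability_spec <- function(omega2, sigma2, error_model) {
  if (any(omega2 < 0) || any(sigma2 < 0))
    stop("variances must be nonnegative", call. = FALSE)
  if (!all(names(sigma2) %in% names(error_model)))
    stop("every residual stream needs an error model", call. = FALSE)
  if (!all(error_model %in% c("exponential", "proportional")))
    stop("error models must be 'exponential' or 'proportional'", call. = FALSE)
  structure(list(omega2 = omega2, sigma2 = sigma2, error_model = error_model),
            class = "variability_spec")
}

#' Typical TFV chain parameters (plasma TFV, TFV-DP, dATP/dGTP)
#'
#' Typical values, covariate coefficients and variability for the tenofovir
#' chain: two-compartment plasma TFV, intracellular TFV-DP (hybrid
#' formation/saturation/recycle), and the deoxypurine pools dATP and dGTP
#' (indirect-response inhibition; the dGTP effect wanes with time via a
#' `1/(1 + t^gamma)` factor). Standard tablet: TDF 300 mg = TFV 136 mg.
#'
#' @return A `chain_params` object.
#' @export
tfv_chain_params <- function() {
  chain_params(
    analyte = "TFV",
    plasma = list(Ka = 80.1, Vc_F = 390, CL_F = 1410, Vp_F = 877, Q_F = 5390),
    ic = list(Kf = 1.4, SC50 = 6.55, Kel = 0.228, R = 0.0582),
    dntp = list(dATP = dntp_block(R0 = 155, EC50 = 1020),
                dGTP = dntp_block(R0 = 245, EC50 = 54.6, gamma = 0.928)),
    dose_ug = 136000,
    covariates = list(),
    variability = variability_spec(
      omega2 = c(Vc_F = 0.288, CL_F = 0.117, Q_F = 0.0693,
                 Kf = 0.238, Kel = 0.316,
                 R0_dATP = 0.220, EC50_dATP = 1.70, R0_dGTP = 0.203),
      sigma2 = c(plasma = 0.0745, ic = 0.115, dATP = 0.258, dGTP = 0.267),
      error_model = c(plasma = "exponential", ic = "proportional",
                      dATP = "exponential", dGTP = "exponential")))
}

#' Typical FTC chain parameters (plasma FTC, FTC-TP, dCTP/TTP)
#'
#' Typical values, covariate coefficients and variability for the
#' emtricitabine chain: two-compartment plasma FTC (males have a larger
#' central volume: `Vc/F = 99.4 + 24.3 * sex`), intracellular FTC-TP
#' (HIV-positive subjects form FTC-TP faster: `Kf = 41.6 + 31.3 * hiv`),
#' and the deoxypyrimidine pools dCTP and TTP. Standard tablet: FTC 200 mg.
#'
#' @return A `chain_params` object.
#' @export
ftc_chain_params <- function() {
  chain_params(
    analyte = "FTC",
    plasma = list(Ka = 55.7, Vc_F = 99.4, CL_F = 482, Vp_F = 166, Q_F = 141),
    ic = list(Kf = 41.6, SC50 = 3320, Kel = 1.6, R = 0.16),
    dntp = list(dCTP = dntp_block(R0 = 771, EC50 = 44400),
                TTP = dntp_block(R0 = 335, EC50 = 18800)),
    dose_ug = 200000,
    covariates = list(
      sex = list(block = "plasma", field = "Vc_F", coef = 24.3),
      hiv = list(block = "ic", field = "Kf", coef = 31.3)),
    variability = variability_spec(
      omega2 = c(Vc_F = 0.0319, CL_F = 0.0942, Vp_F = 0.0335,
                 Kf = 0.0358, Kel = 0.0561,
                 R0_dCTP = 0.195, EC50_dCTP = 0.68,
                 R0_TTP = 0.383, EC50_TTP = 1.02),
      sigma2 = c(plasma = 0.122, ic = 0.0942, dCTP = 0.229, TTP = 0.356),
      error_model = c(plasma = "exponential", ic = "proportional",
                      dCTP = "exponential", TTP = "exponential")))
}

#' Load a parameter bundle from a builtin fixture or a YAML file
#'
#' Builtin names are `"tfv_chain.default"` (alias `"tfv"`) and
#' `"ftc_chain.default"` (alias `"ftc"`), shipped as YAML files under
#' `inst/extdata/` and mirrored by [tfv_chain_params()] /
#' [ftc_chain_params()]. Any other string is treated as a path to a YAML
#' file with the same key tree. Unknown keys and invariant violations are
#' reported with their field path.
#'
#' @param name builtin name or file path.
#' @return A validated `chain_params` object.
#' @export
load_params <- function(name) {
  builtin <- c("tfv" = "tfv_chain.yaml", "tfv_chain.default" = "tfv_chain.yaml",
               "ftc" = "ftc_chain.yaml", "ftc_chain.default" = "ftc_chain.yaml")
  path <- if (name %in% names(builtin)) {
    system.file("extdata", builtin[[name]], package = "prepkpd",
                mustWork = TRUE)
  } else {
    if (!file.exists(name)) stop("no such parameter file: ", name,
                                 call. = FALSE)
    name
  }
  raw <- yaml::read_yaml(path)
  known <- c("analyte", "plasma", "ic", "dntp", "dose_ug", "covariates",
             "variability")
  extra <- setdiff(names(raw), known)
  if (length(extra))
    stop("unknown top-level key(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  var <- NULL
  if (!is.null(raw$variability)) {
    v <- raw$variability
    extra <- setdiff(names(v), c("omega2", "sigma2", "error_model"))
    if (length(extra))
      stop("unknown variability key(s): ", paste(extra, collapse = ", "),
           call. = FALSE)
    var <- variability_spec(unlist(v$omega2), unlist(v$sigma2),
                            unlist(v$error_model))
  }
  dntp <- lapply(raw$dntp, function(b)
    dntp_block(R0 = b$R0, EC50 = b$EC50,
               gamma = if (is.null(b$gamma)) NA_real_ else b$gamma))
  chain_params(analyte = raw$analyte, plasma = raw$plasma, ic = raw$ic,
               dntp = dntp, dose_ug = raw$dose_ug,
               covariates = if (is.null(raw$covariates)) list()
                            else raw$covariates,
               variability = var)
}

# Stream naming: plasma stream = analyte; intracellular anabolite stream:
ic_stream <- function(params) if (params$analyte == "TFV") "TFVDP" else "FTCTP"

#' @export
print.chain_params <- function(x, ...) {
  cat(sprintf("<chain_params> %s chain (dose %g ug parent equivalents)\n",
              x$analyte, x$dose_ug))
  cat("  plasma:", paste(sprintf("%s=%g", names(x$plasma),
                                 unlist(x$plasma)), collapse = ", "), "\n")
  cat("  ic:    ", paste(sprintf("%s=%g", names(x$ic), unlist(x$ic)),
                         collapse = ", "), "\n")
  for (nm in names(x$dntp)) {
    b <- x$dntp[[nm]]
    cat(sprintf("  dNTP %s: R0=%g EC50=%g%s\n", nm, b$R0, b$EC50,
                if (is.finite(b$gamma %||% NA_real_) && !is.na(b$gamma))
                  sprintf(" gamma=%g", b$gamma) else ""))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
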