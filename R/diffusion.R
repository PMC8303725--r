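# Diffusion-based affinity estimation: Stejskal-Tanner decays, fast-exchange
# two-state binding, association constants.

#' Gyromagnetic ratio of the proton
#'
#' rad s^-1 T^-1, CODATA value for 1H.
#' @export
GAMMA_1H <- 2.6752218744e8

#' Construct a pulsed-field-gradient decay experiment
#'
#' One resonance's gradient schedule and signal intensities, the raw unit of
#' DOSY fitting. Gradients may be supplied in T/m or G/cm
#' (1 G/cm = 0.01 T/m); they are stored in T/m.
#'
#' @param resonance_id character label for the resonance.
#' @param gradients strictly increasing gradient strengths.
#' @param intensities non-negative signal areas, same length as `gradients`.
#' @param delta gradient pulse duration (s).
#' @param Delta diffusion time (s); must exceed `delta`.
#' @param gamma gyromagnetic ratio (rad s^-1 T^-1), default 1H.
#' @param gradient_unit `"T/m"` or `"G/cm"`.
#' @return object of class `decay_experiment`.
#' @export
decay_experiment <- function(resonance_id, gradients, intensities,
                             delta, Delta, gamma = GAMMA_1H,
                             gradient_unit = c("T/m", "G/cm")) {
  gradient_unit <- match.arg(gradient_unit)
  if (gradient_unit == "G/cm") gradients <- gradients * 0.01
  if (length(gradients) != length(intensities))
    stop("gradients and intensities must have equal length")
  if (length(gradients) < 4L)
    stop("at least 4 gradient points are required")
  if (any(diff(gradients) <= 0))
    stop("gradients must be strictly increasing")
  if (any(intensities < 0))
    stop("intensities must be non-negative")
  if (delta <= 0 || Delta <= 0 || gamma <= 0)
    stop("delta, Delta and gamma must be positive")
  if (delta >= Delta)
    stop("delta must be smaller than Delta")
  structure(list(resonance_id = as.character(resonance_id),
                 gradients = as.numeric(gradients),
                 intensities = as.numeric(intensities),
                 delta = delta, Delta = Delta, gamma = gamma),
            class = "decay_experiment")
}

#' Stejskal-Tanner signal intensity
#'
#' Attenuation of an NMR signal under a pulsed field gradient:
#' I = I0 * exp(-D * gamma^2 * g^2 * delta^2 * (Delta - delta/3)).
#'
#' @param D diffusion coefficient (m^2 s^-1), >= 0.
#' @param I0 zero-gradient intensity.
#' @param g gradient strength (T/m), >= 0.
#' @param delta,Delta gradient pulse duration and diffusion time (s).
#' @param gamma gyromagnetic ratio (rad s^-1 T^-1).
#' @return predicted intensity; vectorised over `g`.
#' @export
stejskal_tanner_intensity <- function(D, I0, g, delta, Delta,
                                      gamma = GAMMA_1H) {
  if (D < 0) stop("invalid parameter: D must be non-negative")
  if (any(g < 0)) stop("invalid parameter: g must be non-negative")
  if (delta <= 0 || Delta <= 0 || gamma <= 0)
    stop("invalid parameter: durations and gamma must be positive")
  if (delta >= Delta) stop("invalid parameter: delta must be < Delta")
  I0 * exp(-D * gamma^2 * g^2 * delta^2 * (Delta - delta / 3))
}

# b-factor of the ST exponent so that I = I0 exp(-D * b * g^2)
st_b_factor <- function(delta, Delta, gamma) {
  gamma^2 * delta^2 * (Delta - delta / 3)
}

#' Fit a diffusion coefficient from a gradient decay
#'
#' Least-squares fit of the Stejskal-Tanner law in (D, I0). The default is
#' nonlinear least squares with I0 free (Levenberg-Marquardt); a log-linear
#' regression of log(I) on g^2 is available for noiseless or
#' uniform-relative-error data.
#'
#' @param exp a [decay_experiment()].
#' @param method `"nls"` (default) or `"loglinear"`.
#' @return object of class `diffusion_estimate` with elements `D`, `I0`,
#'   `stderr_D`, `r_squared`, `resonance_id`.
#' @export
fit_diffusion <- function(exp, method = c("nls", "loglinear")) {
  method <- match.arg(method)
  stopifnot(inherits(exp, "decay_experiment"))
  I <- exp$intensities
  if (diff(range(I)) == 0)
    stop("fit failure: intensities are constant, no decay to fit")
  b <- st_b_factor(exp$delta, exp$Delta, exp$gamma)
  g2 <- exp$gradients^2
  # log-linear start values (positive intensities only)
  pos <- I > 0
  if (sum(pos) < 3L) stop("fit failure: too few positive intensities")
  lf <- stats::lm(log(I[pos]) ~ g2[pos])
  D0 <- -stats::coef(lf)[[2]] / b
  I00 <- exp(stats::coef(lf)[[1]])
  if (method == "loglinear") {
    # noiseless data triggers lm's perfect-fit warning; harmless here
    sm <- suppressWarnings(summary(lf))
    D <- D0
    if (D <= 0) stop("fit failure: non-decaying data (D <= 0)")
    est <- list(D = D, I0 = I00,
                stderr_D = sm$coefficients[2, 2] / b,
                r_squared = sm$r.squared,
                resonance_id = exp$resonance_id)
    class(est) <- "diffusion_estimate"
    return(est)
  }
  if (D0 <= 0) D0 <- 1e-12
  fit <- minpack.lm::nlsLM(
    I ~ I0 * exp(-D * b * g2),
    start = list(D = D0, I0 = I00),
    data = list(I = I, g2 = g2, b = b),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  co <- summary(fit)$coefficients
  D <- co["D", "Estimate"]
  if (D <= 0) stop("fit failure: non-decaying data (D <= 0)")
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((I - mean(I))^2)
  est <- list(D = D, I0 = co["I0", "Estimate"],
              stderr_D = co["D", "Std. Error"],
              r_squared = 1 - ss_res / ss_tot,
              resonance_id = exp$resonance_id)
  class(est) <- "diffusion_estimate"
  est
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("Diffusion estimate [%s]: D = %.4e m^2/s (se %.2e), I0 = %.4g, R^2 = %.5f\n",
              x$resonance_id, x$D, x$stderr_D, x$I0, x$r_squared))
  invisible(x)
}

#' Molar fraction of the free (uncomplexed) species under fast exchange
#'
#' Inverts the population-weighted average
#' D_obs = MF * D_free + (1 - MF) * D_complex. Values slightly outside
#' `[0, 1]` (within `tol`) are clamped with a warning; values further out
#' raise an inconsistency error naming the violated ordering.
#'
#' @param D_obs observed diffusion coefficient (m^2 s^-1).
#' @param D_free diffusion coefficient of the free species.
#' @param D_complex diffusion coefficient of the complex.
#' @param tol absolute clamping tolerance (default 0.05).
#' @return molar fraction in `[0, 1]`, with attribute `"warning"` when
#'   clamped.
#' @export
molar_fraction <- function(D_obs, D_free, D_complex, tol = 0.05) {
  if (D_free == D_complex)
    stop("D_free and D_complex must differ")
  mf <- (D_obs - D_complex) / (D_free - D_complex)
  if (mf < -tol || mf > 1 + tol)
    stop(sprintf(paste0("inconsistent diffusion data: molar fraction %.4f ",
                        "violates ordering D_complex <= D_obs <= D_free"), mf))
  warn <- NULL
  if (mf < 0) { warn <- sprintf("molar fraction %.4f clamped to 0", mf); mf <- 0 }
  if (mf > 1) { warn <- sprintf("molar fraction %.4f clamped to 1", mf); mf <- 1 }
  if (!is.null(warn)) {
    warning(warn)
    attr(mf, "warning") <- warn
  }
  mf
}

#' Complex concentration from the free molar fraction
#'
#' @param MF molar fraction of the uncomplexed species, in `[0, 1]`.
#' @param C initial concentration (mM) of that species.
#' @return complex concentration (mM), `(1 - MF) * C`.
#' @export
complex_concentration <- function(MF, C) {
  if (MF < 0 || MF > 1) stop("MF must lie in [0, 1]")
  if (C <= 0) stop("C must be positive")
  (1 - MF) * C
}

#' Binding system: concentrations and diffusion endpoints
#'
#' @param C_host,C_ligand initial concentrations (mM).
#' @param D_ligand_free,D_host_free free-species diffusion coefficients
#'   (m^2 s^-1); the small guest must diffuse faster than the host.
#' @param D_obs_ligand,D_obs_host observed (population-averaged) diffusion
#'   coefficients.
#' @param tol relative tolerance on the ordering checks.
#' @return object of class `binding_system`.
#' @export
binding_system <- function(C_host, C_ligand, D_ligand_free, D_host_free,
                           D_obs_ligand, D_obs_host, tol = 0.05) {
  if (C_host <= 0 || C_ligand <= 0) stop("concentrations must be positive")
  if (D_ligand_free <= D_host_free)
    stop("D_ligand_free must exceed D_host_free (guest diffuses faster)")
  span <- D_ligand_free - D_host_free
  if (D_obs_ligand < D_host_free - tol * span ||
      D_obs_ligand > D_ligand_free + tol * span)
    stop("D_obs_ligand must lie between D_host_free and D_ligand_free")
  structure(list(C_host = C_host, C_ligand = C_ligand,
                 D_ligand_free = D_ligand_free, D_host_free = D_host_free,
                 D_obs_ligand = D_obs_ligand, D_obs_host = D_obs_host),
            class = "binding_system")
}

#' Association constant under the 1:1 fast-exchange model
#'
#' Takes the complex diffusion coefficient equal to the observed host value
#' (large host approximation), computes the free-ligand molar fraction from
#' the weighted-average law, the complex concentration from the ligand mass
#' balance, and Ka = \[complex\] / ((C_host - \[complex\]) (C_ligand -
#' \[complex\])). If the complex concentration exceeds `C_host`, the 1:1
#' model is inconsistent with the data: Ka is `NA` and a structured
#' stoichiometry warning is returned instead (molar fraction and complex
#' concentration are still reported).
#'
#' @param sys a [binding_system()].
#' @return object of class `binding_result` with elements `MF_ligand`,
#'   `MF_host`, `complex_conc` (mM), `Ka` (mM^-1), `warnings`.
#' @export
binding_constant <- function(sys) {
  stopifnot(inherits(sys, "binding_system"))
  warnings <- character(0)
  D_complex <- sys$D_obs_host
  mf <- withCallingHandlers(
    molar_fraction(sys$D_obs_ligand, sys$D_ligand_free, D_complex),
    warning = function(w) {
      warnings <<- c(warnings, conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  cplx <- complex_concentration(as.numeric(mf), sys$C_ligand)
  mf_host <- if (sys$C_host > 0) max(0, 1 - cplx / sys$C_host) else NA_real_
  Ka <- NA_real_
  if (cplx > sys$C_host) {
    warnings <- c(warnings, "stoichiometry violation (1:1 model)")
  } else if (cplx >= sys$C_ligand || cplx >= sys$C_host) {
    # saturation: denominator zero, Ka unbounded
    warnings <- c(warnings, "saturated binding: Ka unbounded under 1:1 model")
  } else {
    Ka <- cplx / ((sys$C_host - cplx) * (sys$C_ligand - cplx))
  }
  structure(list(MF_ligand = as.numeric(mf), MF_host = mf_host,
                 complex_conc = cplx, Ka = Ka, warnings = warnings),
            class = "binding_result")
}

#' @export
print.binding_result <- function(x, ...) {
  cat(sprintf("MF_ligand = %.4f, MF_host = %.4f, [complex] = %.4f mM, Ka = %s mM^-1\n",
              x$MF_ligand, x$MF_host, x$complex_conc,
              ifelse(is.na(x$Ka), "NA", sprintf("%.3f", x$Ka))))
  for (w in x$warnings) cat("  warning:", w, "\n")
  invisible(x)
}

#' Equilibrium complex concentration for a 1:1 association
#'
#' Forward solver: the root of Ka (C_host - x)(C_ligand - x) = x in
#' `[0, min(C_host, C_ligand)]`, via the closed-form quadratic. Used by the
#' simulators and round-trip tests.
#'
#' @param Ka association constant (mM^-1), >= 0.
#' @param C_host,C_ligand initial concentrations (mM).
#' @return complex concentration (mM).
#' @export
solve_equilibrium <- function(Ka, C_host, C_ligand) {
  if (Ka < 0) stop("Ka must be non-negative")
  if (C_host <= 0 || C_ligand <= 0) stop("concentrations must be positive")
  if (Ka == 0) return(0)
  # Ka x^2 - (Ka (Ch + Cl) + 1) x + Ka Ch Cl = 0; smaller root is physical
  b <- Ka * (C_host + C_ligand) + 1
  disc <- b^2 - 4 * Ka^2 * C_host * C_ligand
  x <- (b - sqrt(disc)) / (2 * Ka)
  min(x, C_host, C_ligand)
}
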