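#' Population pharmacokinetic parameters for ceftazidime
#'
#' Container for the fixed effects, covariate coefficients, inter-individual
#' variability (IIV) and residual-error magnitude of the one-compartment
#' ceftazidime model. The default instance is the final covariate model for
#' adult ward patients: typical clearance scales with eGFR (CKD-EPI) through a
#' power function and is multiplied by a factor when other antibiotics are
#' co-administered,
#' \deqn{CL = \theta_{CL} \cdot (eGFR / eGFR_{ref})^{\gamma} \cdot
#'   \theta_{abx}^{flag},}
#' with log-normal random effects on CL and V and a proportional residual
#' error on observed concentrations.
#'
#' @param theta_cl Typical clearance (L/h) at the reference eGFR without
#'   concomitant antibiotics.
#' @param theta_v Typical volume of distribution (L).
#' @param gamma_egfr Dimensionless exponent of the eGFR power function on CL.
#' @param theta_abx Multiplicative factor on CL for concomitant antibiotic
#'   use (dimensionless, > 0).
#' @param egfr_ref Reference eGFR (mL/min/1.73 m^2) at which `theta_cl` is the
#'   typical clearance.
#' @param cv_cl,cv_v IIV of CL and V expressed as %CV.
#' @param sigma_prop Proportional residual error expressed as % of the
#'   prediction.
#' @param cv_convention How %CV maps to the log-normal SD `omega`:
#'   `"sd"` (the common reporting convention, `omega = CV/100`) or
#'   `"lognormal"` (`omega = sqrt(log(1 + (CV/100)^2))`).
#'
#' @return An object of class `pop_params`: a list with elements `theta_cl`,
#'   `theta_v`, `gamma_egfr`, `theta_abx`, `egfr_ref`, `omega_cl`, `omega_v`
#'   (log-scale SDs), `sigma_prop` (fraction, not %), and the stored
#'   `cv_convention`.
#' @examples
#' p <- pop_params()
#' typical_clearance(76.86, 0, p) # 3.74 L/h
#' @export
pop_params <- function(theta_cl = 3.74,
                       theta_v = 21.8,
                       gamma_egfr = 0.75,
                       theta_abx = 1.56,
                       egfr_ref = 76.86,
                       cv_cl = 31.3,
                       cv_v = 40.2,
                       sigma_prop = 18.6,
                       cv_convention = c("sd", "lognormal")) {
  cv_convention <- match.arg(cv_convention)
  for (nm in c("theta_cl", "theta_v", "theta_abx", "egfr_ref")) {
    check_number(get(nm), nm, lower = 0, strict = TRUE)
  }
  check_number(gamma_egfr, "gamma_egfr")
  check_number(cv_cl, "cv_cl", lower = 0)
  check_number(cv_v, "cv_v", lower = 0)
  check_number(sigma_prop, "sigma_prop", lower = 0)
  out <- list(
    theta_cl = theta_cl, theta_v = theta_v,
    gamma_egfr = gamma_egfr, theta_abx = theta_abx, egfr_ref = egfr_ref,
    omega_cl = cv_to_omega(cv_cl, cv_convention),
    omega_v = cv_to_omega(cv_v, cv_convention),
    sigma_prop = sigma_prop / 100,
    cv_convention = cv_convention
  )
  structure(out, class = "pop_params")
}

#' @export
print.pop_params <- function(x, ...) {
  cat("<pop_params> one-compartment ceftazidime model\n")
  cat(sprintf("  CL = %.4g * (eGFR/%.4g)^%.4g * %.4g^abx  [L/h]\n",
              x$theta_cl, x$egfr_ref, x$gamma_egfr, x$theta_abx))
  cat(sprintf("  V  = %.4g L\n", x$theta_v))
  cat(sprintf("  IIV: CL %.1f %%CV, V %.1f %%CV (%s convention); prop. error %.1f %%\n",
              omega_to_cv(x$omega_cl, x$cv_convention),
              omega_to_cv(x$omega_v, x$cv_convention),
              x$cv_convention, 100 * x$sigma_prop))
  invisible(x)
}

#' Convert between %CV and log-normal omega
#'
#' Two conventions are in circulation for reporting IIV of a log-normally
#' distributed parameter: reporting `sqrt(omega^2) * 100` directly as %CV
#' (`"sd"`), or the exact log-normal CV `sqrt(exp(omega^2) - 1) * 100`
#' (`"lognormal"`). These helpers convert in both directions.
#'
#' @param cv Coefficient of variation in percent.
#' @param omega Log-scale standard deviation.
#' @param convention `"sd"` or `"lognormal"`.
#' @return A numeric scalar (vectorised over the first argument).
#' @export
cv_to_omega <- function(cv, convention = c("sd", "lognormal")) {
  convention <- match.arg(convention)
  f <- cv / 100
  switch(convention, sd = f, lognormal = sqrt(log(1 + f^2)))
}

#' @rdname cv_to_omega
#' @export
omega_to_cv <- function(omega, convention = c("sd", "lognormal")) {
  convention <- match.arg(convention)
  switch(convention, sd = 100 * omega, lognormal = 100 * sqrt(exp(omega^2) - 1))
}

#' Typical (population) clearance from the covariate model
#'
#' Evaluates the final-model clearance equation
#' `CL = theta_cl * (egfr/egfr_ref)^gamma * theta_abx^abx` for one or more
#' subjects.
#'
#' @param egfr eGFR (CKD-EPI) in mL/min/1.73 m^2; must be positive.
#' @param abx 0/1 flag (or logical) for concomitant use of other antibiotics.
#' @param pop A [pop_params()] object.
#' @return Typical clearance in L/h (vectorised).
#' @examples
#' typical_clearance(76.86, 0, pop_params()) # 3.74
#' typical_clearance(76.86, 1, pop_params()) # 3.74 * 1.56
#' @export
typical_clearance <- function(egfr, abx = 0, pop = pop_params()) {
  stopifnot(inherits(pop, "pop_params"))
  if (!is.numeric(egfr) || any(!is.finite(egfr)) || any(egfr <= 0)) {
    abort("`egfr` must be positive and finite.")
  }
  abx <- as.numeric(abx)
  if (any(!abx %in% c(0, 1))) abort("`abx` must be 0/1 or logical.")
  pop$theta_cl * (egfr / pop$egfr_ref)^pop$gamma_egfr * pop$theta_abx^abx
}

#' Individual pharmacokinetic parameters
#'
#' Combines the covariate model with realised log-normal random effects:
#' `CL = typical_clearance(...) * exp(eta_cl)`, `V = theta_v * exp(eta_v)`.
#'
#' @inheritParams typical_clearance
#' @param eta_cl,eta_v Realised random effects on the log scale (0 gives the
#'   typical subject).
#' @return A tibble with columns `cl`, `v`, `ke`, `eta_cl`, `eta_v`
#'   (one row per subject).
#' @export
individual_parameters <- function(egfr, abx = 0, eta_cl = 0, eta_v = 0,
                                  pop = pop_params()) {
  if (any(!is.finite(eta_cl)) || any(!is.finite(eta_v))) {
    abort("Random effects must be finite.")
  }
  cl <- typical_clearance(egfr, abx, pop) * exp(eta_cl)
  v <- pop$theta_v * exp(eta_v)
  tibble(cl = cl, v = v, eta_cl = eta_cl, eta_v = eta_v) |>
    mutate(ke = .data$cl / .data$v) |>
    select("cl", "v", "ke", "eta_cl", "eta_v")
}
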