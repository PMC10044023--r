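#' Renal-function estimates
#'
#' Standard published estimating equations for glomerular filtration rate /
#' creatinine clearance, taking serum creatinine in micromol/L (as reported
#' by Dutch hospital laboratories).
#'
#' * `egfr_ckdepi()`: CKD-EPI creatinine equation, 2009 form by default,
#'   optionally with the race coefficient or the 2021 race-free refit.
#' * `egfr_mdrd()`: IDMS-traceable 4-variable MDRD (175 form).
#' * `egfr_cockcroft_gault()`: Cockcroft-Gault creatinine clearance (mL/min),
#'   needs body weight.
#'
#' All are vectorised and strictly decreasing in serum creatinine.
#'
#' @param scr Serum creatinine (micromol/L), positive.
#' @param age Age in years (>= 18 for these adult equations).
#' @param sex `"female"`/`"male"` (or `"F"`/`"M"`).
#' @param variant CKD-EPI variant: `"2009"` (default), `"2009_race"` (with
#'   the Black-race coefficient applied), or `"2021"` (race-free refit).
#' @param weight Body weight (kg), Cockcroft-Gault only.
#' @return eGFR in mL/min/1.73 m^2 (CKD-EPI, MDRD) or creatinine clearance in
#'   mL/min (Cockcroft-Gault).
#' @examples
#' egfr_ckdepi(scr = 80, age = 60, sex = "female")
#' @export
egfr_ckdepi <- function(scr, age, sex, variant = c("2009", "2009_race", "2021")) {
  variant <- match.arg(variant)
  check_renal_inputs(scr, age)
  female <- parse_sex(sex)
  scr_mgdl <- scr / 88.4
  if (variant == "2021") {
    kappa <- ifelse(female, 0.7, 0.9)
    alpha <- ifelse(female, -0.241, -0.302)
    out <- 142 * pmin(scr_mgdl / kappa, 1)^alpha *
      pmax(scr_mgdl / kappa, 1)^-1.200 * 0.9938^age
    out * ifelse(female, 1.012, 1)
  } else {
    kappa <- ifelse(female, 0.7, 0.9)
    alpha <- ifelse(female, -0.329, -0.411)
    out <- 141 * pmin(scr_mgdl / kappa, 1)^alpha *
      pmax(scr_mgdl / kappa, 1)^-1.209 * 0.993^age
    out <- out * ifelse(female, 1.018, 1)
    if (variant == "2009_race") out * 1.159 else out
  }
}

#' @rdname egfr_ckdepi
#' @export
egfr_mdrd <- function(scr, age, sex) {
  check_renal_inputs(scr, age)
  female <- parse_sex(sex)
  175 * (scr / 88.4)^-1.154 * age^-0.203 * ifelse(female, 0.742, 1)
}

#' @rdname egfr_ckdepi
#' @export
egfr_cockcroft_gault <- function(scr, age, sex, weight) {
  check_renal_inputs(scr, age)
  if (any(!is.finite(weight)) || any(weight <= 0)) {
    abort("`weight` must be positive and finite.")
  }
  female <- parse_sex(sex)
  (140 - age) * weight / (0.815 * scr) * ifelse(female, 0.85, 1)
}

#' Renal-function group from eGFR
#'
#' Classifies eGFR into the three ward dosing groups with half-open
#' intervals: `"adequate"` (eGFR >= 50), `"moderate"` (30 <= eGFR < 50),
#' `"severe"` (eGFR < 30); the boundary 50 belongs to the adequate group.
#'
#' @param egfr eGFR in mL/min/1.73 m^2.
#' @return A factor with levels `adequate`, `moderate`, `severe`.
#' @examples
#' renal_group(c(102.8, 34.3, 18.6, 50))
#' @export
renal_group <- function(egfr) {
  if (any(!is.finite(egfr)) || any(egfr <= 0)) {
    abort("`egfr` must be positive and finite.")
  }
  cut(egfr, breaks = c(-Inf, 30, 50, Inf), right = FALSE,
      labels = c("severe", "moderate", "adequate")) |>
    factor(levels = c("adequate", "moderate", "severe"))
}

check_renal_inputs <- function(scr, age) {
  if (any(!is.finite(scr)) || any(scr <= 0)) {
    abort("`scr` must be positive and finite (micromol/L).")
  }
  if (any(!is.finite(age)) || any(age < 18)) {
    abort("`age` must be >= 18 for the adult equations.")
  }
  invisible(TRUE)
}

parse_sex <- function(sex) {
  s <- tolower(as.character(sex))
  out <- s %in% c("female", "f")
  bad <- !s %in% c("female", "f", "male", "m")
  if (any(bad)) abort("`sex` must be 'female'/'male' (or 'F'/'M').")
  out
}
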