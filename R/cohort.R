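#' Specification of a virtual ward cohort
#'
#' Describes the statistical structure of a ceftazidime ward cohort: three
#' renal-function strata with their guideline regimens, marginal covariate
#' distributions (medians and interquartile ranges), the prevalence of
#' concomitant antibiotic use and fever, the morning-round dose-shift
#' mechanism, the sparse sampling design (one trough plus two random samples
#' within 72 h, a fraction of subjects yielding only two), and the two
#' protocol irregularities seen in practice: one severely impaired subject
#' dosed at 2000 mg q24h instead of 1000 mg q24h, and one adequate-function
#' subject treated for only 24 h.
#'
#' Location/spread targets are parameterised as median and IQR; continuous
#' covariates are drawn from log-normals calibrated to those targets and
#' truncated to plausibility bounds (for eGFR, to the stratum's interval).
#'
#' @param n Subjects per stratum, named `adequate`, `moderate`, `severe`.
#' @param egfr_median,egfr_iqr Per-stratum eGFR medians and IQRs
#'   (mL/min/1.73 m^2); `egfr_iqr` is a list of length-2 vectors.
#' @param egfr_bounds Truncation interval per stratum (list of length-2).
#' @param abx_prevalence,fever_prevalence,female_prevalence,ortho_prevalence,hema_prevalence
#'   Per-stratum probabilities.
#' @param ethnicity_prob Named probabilities for the ethnicity label.
#' @param age_median,age_iqr,weight_median,weight_iqr,height_median,height_iqr
#'   Per-stratum marginal targets (years / kg / cm).
#' @param dose_shift_prob Probability that a subject's follow-up doses shift
#'   onto the morning nurse round (see [apply_dose_shift()]).
#' @param two_sample_prob Probability that only two samples can be drawn.
#' @param misdose Inject the 2000-instead-of-1000 mg q24h severe-stratum
#'   subject?
#' @param short_course Inject the adequate-stratum subject treated only
#'   during the first 24 h?
#' @param t_end Treatment span covered by the generated regimens (h).
#' @param pop True population parameters ([pop_params()]) used to simulate
#'   concentrations.
#' @param lloq,uloq Assay limits (mg/L) applied to simulated observations.
#' @return A `cohort_spec` object (validated list).
#' @export
cohort_spec <- function(n = c(adequate = 25, moderate = 10, severe = 5),
                        egfr_median = c(102.8, 34.3, 18.6),
                        egfr_iqr = list(c(78.1, 124.8), c(30.9, 48.2), c(10.6, 25.9)),
                        egfr_bounds = list(c(50, 200), c(30, 50), c(10, 30)),
                        abx_prevalence = c(19 / 25, 6 / 10, 2 / 5),
                        fever_prevalence = c(7 / 25, 3 / 10, 1 / 5),
                        female_prevalence = c(9 / 25, 6 / 10, 2 / 5),
                        ortho_prevalence = c(10 / 25, 1 / 10, 1 / 5),
                        hema_prevalence = c(7 / 25, 0, 0),
                        ethnicity_prob = c(caucasian = 32, african_american = 4,
                                           asian = 3, hispanic = 1) / 40,
                        age_median = c(56, 72, 64),
                        age_iqr = list(c(40.5, 68.5), c(69.8, 86.0), c(41.5, 73.0)),
                        weight_median = c(80.0, 78.5, 71.7),
                        weight_iqr = list(c(71.8, 89.0), c(67.2, 94.3), c(57.1, 140.6)),
                        height_median = c(180.0, 171.5, 167.0),
                        height_iqr = list(c(168.0, 185.0), c(163.5, 184.3), c(163.0, 179.5)),
                        dose_shift_prob = 0.55,
                        two_sample_prob = 0.125,
                        misdose = TRUE,
                        short_course = TRUE,
                        t_end = 72,
                        pop = pop_params(),
                        lloq = 0.1, uloq = 40) {
  groups <- c("adequate", "moderate", "severe")
  if (!all(groups %in% names(n))) {
    abort("`n` must be named with adequate/moderate/severe.")
  }
  n <- n[groups]
  if (any(n <= 0)) abort("Group sizes must be positive.")
  probs <- list(abx = abx_prevalence, fever = fever_prevalence,
                female = female_prevalence, ortho = ortho_prevalence,
                hema = hema_prevalence,
                shift = dose_shift_prob, two = two_sample_prob)
  for (p in probs) {
    if (any(p < 0 | p > 1)) abort("Prevalences/probabilities must lie in [0, 1].")
  }
  for (g in 1:3) {
    b <- egfr_bounds[[g]]
    if (egfr_median[g] < b[1] || egfr_median[g] > b[2]) {
      abort(sprintf("eGFR median target %.4g for the %s stratum lies outside its interval [%g, %g].",
                    egfr_median[g], groups[g], b[1], b[2]))
    }
  }
  stopifnot(inherits(pop, "pop_params"))
  structure(
    list(n = n, egfr_median = egfr_median, egfr_iqr = egfr_iqr,
         egfr_bounds = egfr_bounds, abx_prevalence = abx_prevalence,
         fever_prevalence = fever_prevalence,
         female_prevalence = female_prevalence,
         ortho_prevalence = ortho_prevalence, hema_prevalence = hema_prevalence,
         ethnicity_prob = ethnicity_prob,
         age_median = age_median, age_iqr = age_iqr,
         weight_median = weight_median, weight_iqr = weight_iqr,
         height_median = height_median, height_iqr = height_iqr,
         dose_shift_prob = dose_shift_prob, two_sample_prob = two_sample_prob,
         misdose = misdose, short_course = short_course,
         t_end = t_end, pop = pop, lloq = lloq, uloq = uloq),
    class = "cohort_spec")
}

# Median/IQR-calibrated log-normal, truncated to [lo, hi] via inverse CDF.
# systematic = TRUE draws one point per probability stratum (jittered
# systematic sampling): same marginal distribution, much lower variance of
# the sample median/spread — used where a small fixed design must match the
# target margins.
rlnorm_mediqr <- function(n, med, iqr, lo = 0, hi = Inf, systematic = FALSE) {
  mu <- log(med)
  sdlog <- log(iqr[2] / iqr[1]) / (2 * stats::qnorm(0.75))
  plo <- stats::plnorm(lo, mu, sdlog)
  phi <- stats::plnorm(hi, mu, sdlog)
  u <- if (systematic) (sample(n) - runif(n)) / n else runif(n)
  stats::qlnorm(plo + u * (phi - plo), mu, sdlog)
}

# Invert the CKD-EPI 2009 equation for serum creatinine given eGFR/age/sex.
scr_from_egfr <- function(egfr, age, sex) {
  vapply(seq_along(egfr), function(i) {
    uniroot(function(s) egfr_ckdepi(s, age[i], sex[i]) - egfr[i],
            lower = 5, upper = 5000, tol = 1e-8)$root
  }, numeric(1))
}

# Sampling design for one subject: one trough (0-15 min before a later dose)
# plus random samples uniform on (infusion end, next dose), all within the
# first 72 h of treatment.
draw_sample_times <- function(reg, n_samples, horizon = 72) {
  times <- reg$time[reg$time < horizon]
  durs <- reg$duration[reg$time < horizon]
  interval <- if (length(reg$time) > 1) diff(reg$time[1:2]) else 24
  ends <- times + durs
  nxt <- pmin(c(times[-1], times[length(times)] + interval), horizon)
  nxt <- pmax(nxt, ends + 0.05)
  if (length(times) > 1) {
    trough_dose <- sample(seq_along(times)[-1], 1)
    trough <- max(times[trough_dose] - runif(1, 0, 0.25), 1e-3)
  } else {
    trough <- times[1] + interval - runif(1, 0, 0.25)
  }
  n_random <- n_samples - 1L
  iv <- if (length(times) == 1L) rep(1L, n_random) else
    sample(seq_along(times), n_random, replace = TRUE)
  rnd <- runif(n_random, ends[iv], nxt[iv])
  out <- sort(round(c(trough, rnd), 4))
  while (anyDuplicated(out)) out[duplicated(out)] <- out[duplicated(out)] + 0.01
  sort(out)
}

#' Generate a virtual cohort with its ground truth
#'
#' Draws covariates per stratum from the [cohort_spec()] margins, derives
#' serum creatinine by inverting the CKD-EPI equation (so all renal markers
#' are mutually consistent), assigns guideline regimens, applies the
#' morning-round dose shift, simulates concentrations from the true
#' individual parameters with proportional residual error, and flags
#' below-LLOQ observations. Deterministic for a fixed seed.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer seed (mandatory for reproducibility).
#' @return A list with elements `data` (a [pk_dataset()] of dose and
#'   observation rows) and `truth` (a tibble of per-subject covariates, true
#'   individual parameters and design flags).
#' @export
sample_cohort <- function(spec, seed) {
  stopifnot(inherits(spec, "cohort_spec"))
  check_number(seed, "seed")
  groups <- c("adequate", "moderate", "severe")
  pop <- spec$pop
  with_seed(seed, {
    subj <- purrr::map_dfr(1:3, function(g) {
      ng <- spec$n[g]
      egfr <- rlnorm_mediqr(ng, spec$egfr_median[g], spec$egfr_iqr[[g]],
                            spec$egfr_bounds[[g]][1], spec$egfr_bounds[[g]][2])
      age <- rlnorm_mediqr(ng, spec$age_median[g], spec$age_iqr[[g]], 18, 95)
      wt <- rlnorm_mediqr(ng, spec$weight_median[g], spec$weight_iqr[[g]], 35, 200)
      ht <- rlnorm_mediqr(ng, spec$height_median[g], spec$height_iqr[[g]], 140, 210)
      tibble(
        group = groups[g],
        sex = ifelse(runif(ng) < spec$female_prevalence[g], "female", "male"),
        age = age, weight = wt, height = ht,
        bmi = wt / (ht / 100)^2,
        egfr_ckdepi = egfr,
        abx = as.integer(runif(ng) < spec$abx_prevalence[g]),
        fever = as.integer(runif(ng) < spec$fever_prevalence[g]),
        ward_ortho = as.integer(runif(ng) < spec$ortho_prevalence[g]),
        ward_hema = as.integer(runif(ng) < spec$hema_prevalence[g]),
        ethnicity = sample(names(spec$ethnicity_prob), ng, replace = TRUE,
                           prob = spec$ethnicity_prob)
      )
    })
    n_tot <- nrow(subj)
    subj <- subj |>
      mutate(
        id = row_number(),
        scr = scr_from_egfr(.data$egfr_ckdepi, .data$age, .data$sex),
        egfr_mdrd = egfr_mdrd(.data$scr, .data$age, .data$sex),
        egfr_cg = egfr_cockcroft_gault(.data$scr, .data$age, .data$sex, .data$weight),
        eta_cl = rnorm(n_tot, 0, pop$omega_cl),
        eta_v = rnorm(n_tot, 0, pop$omega_v),
        shifted = runif(n_tot) < spec$dose_shift_prob,
        first_dose_clock = runif(n_tot, 0, 24),
        two_samples = runif(n_tot) < spec$two_sample_prob,
        misdosed = FALSE, short_course = FALSE
      )
    if (isTRUE(spec$misdose)) {
      sev <- which(subj$group == "severe")[1]
      subj$misdosed[sev] <- TRUE
    }
    if (isTRUE(spec$short_course)) {
      ade <- which(subj$group == "adequate")[1]
      subj$short_course[ade] <- TRUE
    }
    ip <- individual_parameters(subj$egfr_ckdepi, subj$abx,
                                subj$eta_cl, subj$eta_v, pop)
    subj$cl <- ip$cl
    subj$v <- ip$v

    rows <- purrr::map_dfr(seq_len(n_tot), function(i) {
      s <- subj[i, ]
      t_end_i <- if (s$short_course) 24 else spec$t_end
      reg <- guideline_regimen(s$group, t_end = t_end_i)
      if (s$misdosed) reg <- regimen_q(24, 2000, t_end_i, label = "2000 mg q24h (misdose)")
      reg <- apply_dose_shift(reg, s$shifted, s$first_dose_clock)
      n_samp <- if (s$two_samples) 2L else 3L
      obs_t <- draw_sample_times(reg, n_samp, horizon = min(72, spec$t_end))
      prof <- pk_profile(s$cl, s$v, reg)
      f <- pk_concentration(prof, obs_t)
      dv <- pmax(f * (1 + pop$sigma_prop * rnorm(length(f))), 0)
      blq <- as.integer(dv < spec$lloq)
      dose_rows <- tibble(id = s$id, time = reg$time, evid = 1,
                          amt = reg$amount, dur = reg$duration,
                          dv = NA_real_, blq = 0L)
      obs_rows <- tibble(id = s$id, time = obs_t, evid = 0,
                         amt = NA_real_, dur = NA_real_,
                         dv = ifelse(blq == 1, NA_real_, dv), blq = blq)
      bind_rows(dose_rows, obs_rows) |>
        arrange(.data$time) |>
        mutate(group = s$group, sex = s$sex, age = s$age, weight = s$weight,
               height = s$height, bmi = s$bmi, scr = s$scr,
               egfr_ckdepi = s$egfr_ckdepi, egfr_mdrd = s$egfr_mdrd,
               egfr_cg = s$egfr_cg, abx = s$abx, fever = s$fever,
               ward_ortho = s$ward_ortho, ward_hema = s$ward_hema,
               ethnicity = s$ethnicity)
    })
    truth <- subj |>
      select("id", "group", "sex", "age", "weight", "height", "bmi", "scr",
             "egfr_ckdepi", "egfr_mdrd", "egfr_cg", "abx", "fever",
             "ward_ortho", "ward_hema", "ethnicity", "eta_cl", "eta_v",
             "cl", "v", "shifted", "first_dose_clock", "two_samples",
             "misdosed", "short_course")
    list(data = pk_dataset(rows, lloq = spec$lloq, uloq = spec$uloq),
         truth = truth)
  })
}
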