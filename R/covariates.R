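#' Candidate covariates for stepwise selection
#'
#' The default candidate set screened on clearance: serum creatinine, the
#' three renal-function estimates (CKD-EPI, MDRD, Cockcroft-Gault), BMI and
#' age as power functions; Caucasian ethnicity, orthopedic-ward and
#' hematology-ward admission, fever and concomitant antibiotic use as
#' multiplicative factors.
#'
#' @return A tibble with columns `param`, `cov`, `type`.
#' @export
default_candidates <- function() {
  bind_rows(
    tibble(param = "cl",
           cov = c("scr", "egfr_ckdepi", "egfr_mdrd", "egfr_cg", "bmi", "age"),
           type = "power"),
    tibble(param = "cl",
           cov = c("caucasian", "ward_ortho", "ward_hema", "fever", "abx"),
           type = "factor")
  )
}

# The mutually collinear renal-function markers: at most one may be retained.
renal_markers <- c("scr", "egfr_ckdepi", "egfr_mdrd", "egfr_cg")

#' Stepwise covariate analysis
#'
#' Univariate screen followed by a multivariate analysis, as in conventional
#' pharmacometric model development. Each candidate is first added alone to
#' the base model and kept when the objective function drops by at least
#' `threshold_uni` (default 3.84, p < 0.05 on 1 df). If several collinear
#' renal-function markers pass, only the one with the largest drop is
#' carried forward (with a warning). All carried candidates are then fitted
#' jointly and removed backwards until every remaining covariate worsens the
#' objective by at least `threshold_multi` (default 6.63, p < 0.01 on 1 df)
#' upon removal.
#'
#' @param data A cleaned [pk_dataset()].
#' @param base_fit A converged `popk_fit` of the base (covariate-free)
#'   model.
#' @param candidates Tibble of candidates (`param`, `cov`, `type`); defaults
#'   to [default_candidates()].
#' @param threshold_uni,threshold_multi Objective-function drop (points of
#'   -2 log likelihood) required at the univariate screen / multivariate
#'   retention stage.
#' @return A `covariate_step` object: the per-candidate report
#'   (`$report`), the final fit (`$final_fit`), and the IIV %CV trajectory
#'   (`$iiv_trajectory`).
#' @export
covariate_step <- function(data, base_fit, candidates = default_candidates(),
                           threshold_uni = qchisq(0.95, 1),
                           threshold_multi = qchisq(0.99, 1)) {
  stopifnot(inherits(base_fit, "popk_fit"))
  if (!base_fit$converged) abort("The base fit did not converge.")
  data <- ensure_derived_covariates(data, candidates$cov)
  base_model <- base_fit$model
  refit <- function(model) {
    fit_popk(data, model, init = base_fit$init, fixed = base_fit$fixed,
             compute_se = FALSE)
  }

  report <- candidates |>
    mutate(delta_ofv_uni = NA_real_, p_uni = NA_real_,
           screen_pass = FALSE, carried = FALSE,
           delta_ofv_multi = NA_real_, p_multi = NA_real_, retained = FALSE)

  uni_fits <- vector("list", nrow(report))
  for (i in seq_len(nrow(report))) {
    m <- add_term(base_model, report$param[i], report$cov[i], report$type[i])
    f <- refit(m)
    uni_fits[[i]] <- f
    report$delta_ofv_uni[i] <- base_fit$ofv - f$ofv
    report$p_uni[i] <- pchisq(max(report$delta_ofv_uni[i], 0), 1,
                              lower.tail = FALSE)
    report$screen_pass[i] <- isTRUE(f$converged) &&
      report$delta_ofv_uni[i] >= threshold_uni
  }

  report$carried <- report$screen_pass
  renal_pass <- which(report$carried & report$cov %in% renal_markers &
                        report$param == "cl")
  if (length(renal_pass) > 1) {
    best <- renal_pass[which.max(report$delta_ofv_uni[renal_pass])]
    dropped <- setdiff(renal_pass, best)
    report$carried[dropped] <- FALSE
    warn(sprintf(
      "Collinear renal markers passed the screen (%s); carrying only `%s` (largest drop).",
      paste(report$cov[renal_pass], collapse = ", "), report$cov[best]))
  }

  # multivariate backward elimination among the carried candidates
  current <- which(report$carried)
  if (length(current) == 0) {
    final_fit <- base_fit
  } else {
    build <- function(idx) {
      m <- base_model
      for (i in idx) m <- add_term(m, report$param[i], report$cov[i], report$type[i])
      m
    }
    full_fit <- if (length(current) == 1) uni_fits[[current]] else refit(build(current))
    repeat {
      drops <- vapply(seq_along(current), function(k) {
        reduced <- if (length(current) == 1) base_fit else refit(build(current[-k]))
        reduced$ofv - full_fit$ofv
      }, numeric(1))
      for (k in seq_along(current)) {
        report$delta_ofv_multi[current[k]] <- drops[k]
        report$p_multi[current[k]] <- pchisq(max(drops[k], 0), 1,
                                             lower.tail = FALSE)
      }
      if (all(drops >= threshold_multi)) break
      worst <- which.min(drops)
      report$delta_ofv_multi[current[worst]] <- drops[worst]
      current <- current[-worst]
      if (length(current) == 0) break
      full_fit <- refit(build(current))
    }
    report$retained[current] <- TRUE
    final_fit <- if (length(current) == 0) base_fit else {
      fit_popk(data, build(current), init = base_fit$init,
               fixed = base_fit$fixed, compute_se = TRUE)
    }
  }

  iiv <- tibble(
    stage = c("base", "final"),
    iiv_cl_cv = c(omega_to_cv(base_fit$params$omega_cl, base_fit$cv_convention),
                  omega_to_cv(final_fit$params$omega_cl, final_fit$cv_convention)),
    iiv_v_cv = c(omega_to_cv(base_fit$params$omega_v, base_fit$cv_convention),
                 omega_to_cv(final_fit$params$omega_v, final_fit$cv_convention))
  )
  structure(list(report = report, final_fit = final_fit,
                 iiv_trajectory = iiv,
                 thresholds = c(uni = threshold_uni, multi = threshold_multi)),
            class = "covariate_step")
}

#' @export
print.covariate_step <- function(x, ...) {
  cat("<covariate_step>\n")
  r <- x$report |>
    mutate(across(c("delta_ofv_uni", "delta_ofv_multi"), ~ round(.x, 2)))
  print(as.data.frame(r), row.names = FALSE)
  cat(sprintf("IIV CL: %.1f%% -> %.1f%% CV\n",
              x$iiv_trajectory$iiv_cl_cv[1], x$iiv_trajectory$iiv_cl_cv[2]))
  invisible(x)
}

#' @export
tidy.covariate_step <- function(x, ...) x$report

# Derived 0/1 covariates that tests may reference (currently: caucasian
# from the ethnicity label).
ensure_derived_covariates <- function(data, covs) {
  if ("caucasian" %in% covs && !"caucasian" %in% names(data) &&
      "ethnicity" %in% names(data)) {
    lloq <- attr(data, "lloq"); uloq <- attr(data, "uloq")
    d <- as_tibble(data) |>
      mutate(caucasian = as.integer(.data$ethnicity == "caucasian"))
    data <- pk_dataset(d, lloq = lloq, uloq = uloq)
  }
  data
}
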