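#' Population model structure
#'
#' Describes which covariates enter the model and how. Continuous covariates
#' enter as power functions normalised to a reference value (the dataset
#' median unless given in `refs`): `TV = theta * (x/ref)^gamma`. Binary
#' covariates enter as multiplicative factors: `TV = theta * beta^flag`.
#' Random effects are log-normal on CL and V (diagonal), the residual error
#' is proportional.
#'
#' @param cl_power,cl_factor,v_power,v_factor Character vectors of covariate
#'   column names entering clearance / volume as power terms or factors.
#' @param refs Named list of reference values for power covariates;
#'   covariates not named here are normalised to their dataset median.
#' @return A `popk_model` object.
#' @examples
#' # the final ward model: eGFR power function and antibiotic factor on CL
#' final_model()
#' popk_model() # covariate-free structural model
#' @export
popk_model <- function(cl_power = character(), cl_factor = character(),
                       v_power = character(), v_factor = character(),
                       refs = list()) {
  terms <- bind_rows(
    tibble(param = "cl", cov = as.character(cl_power), type = "power"),
    tibble(param = "cl", cov = as.character(cl_factor), type = "factor"),
    tibble(param = "v", cov = as.character(v_power), type = "power"),
    tibble(param = "v", cov = as.character(v_factor), type = "factor")
  )
  if (anyDuplicated(paste(terms$param, terms$cov))) {
    abort("A covariate may enter a given parameter only once.")
  }
  structure(list(terms = terms, refs = refs), class = "popk_model")
}

#' @rdname popk_model
#' @export
final_model <- function(refs = list(egfr_ckdepi = 76.86)) {
  popk_model(cl_power = "egfr_ckdepi", cl_factor = "abx", refs = refs)
}

#' @export
print.popk_model <- function(x, ...) {
  cat("<popk_model> 1-compartment, IIV on CL and V, proportional error\n")
  if (nrow(x$terms) == 0) {
    cat("  no covariates\n")
  } else {
    for (i in seq_len(nrow(x$terms))) {
      cat(sprintf("  %s: %s (%s)\n", toupper(x$terms$param[i]),
                  x$terms$cov[i], x$terms$type[i]))
    }
  }
  invisible(x)
}

add_term <- function(model, param, cov, type) {
  t2 <- bind_rows(model$terms, tibble(param = param, cov = cov, type = type))
  structure(list(terms = t2, refs = model$refs), class = "popk_model")
}

drop_term <- function(model, param, cov) {
  keep <- !(model$terms$param == param & model$terms$cov == cov)
  structure(list(terms = model$terms[keep, ], refs = model$refs),
            class = "popk_model")
}

# ---- data preparation -----------------------------------------------------

# One row per subject with covariates; per-subject event lists for the
# likelihood; subjects ordered by id so the objective is order-invariant.
prepare_fit_data <- function(data, model) {
  stopifnot(inherits(data, "pk_dataset"))
  d <- as_tibble(data)
  obs <- d |> filter(.data$evid == 0)
  if (any(is.na(obs$dv))) {
    abort("Observations contain missing `dv`; run `clean_dataset()` first.")
  }
  ids <- sort(unique(d$id))
  covs <- unique(model$terms$cov)
  missing_cov <- setdiff(covs, names(d))
  if (length(missing_cov) > 0) {
    abort(sprintf("Covariate column(s) not in dataset: %s.",
                  paste(missing_cov, collapse = ", ")))
  }
  subj <- d |>
    group_by(.data$id) |>
    summarise(across(all_of(covs), first), .groups = "drop") |>
    arrange(.data$id)
  split_by <- function(df, col) {
    lapply(ids, function(i) df[[col]][df$id == i])
  }
  doses <- d |> filter(.data$evid == 1)
  list(
    ids = ids,
    subj = subj,
    y = split_by(obs, "dv"),
    t = split_by(obs, "time"),
    dose_t = split_by(doses, "time"),
    dose_amt = split_by(doses, "amt"),
    dose_dur = split_by(doses, "dur")
  )
}

# Resolve power-term reference values: user-supplied or dataset median.
resolve_refs <- function(model, subj) {
  pows <- model$terms$cov[model$terms$type == "power"]
  refs <- model$refs
  for (cv in pows) {
    if (is.null(refs[[cv]])) refs[[cv]] <- median(subj[[cv]])
  }
  refs
}

# Typical values per subject given natural-scale parameters.
typical_values <- function(model, refs, subj, theta_cl, theta_v, coefs) {
  tv <- list(cl = rep(theta_cl, nrow(subj)), v = rep(theta_v, nrow(subj)))
  tm <- model$terms
  for (i in seq_len(nrow(tm))) {
    x <- subj[[tm$cov[i]]]
    cf <- coefs[[paste(tm$param[i], tm$cov[i], sep = ".")]]
    fac <- if (tm$type[i] == "power") {
      (x / refs[[tm$cov[i]]])^cf
    } else {
      cf^as.numeric(x)
    }
    tv[[tm$param[i]]] <- tv[[tm$param[i]]] * fac
  }
  tv
}

# ---- parameter vector bookkeeping ----------------------------------------

par_skeleton <- function(model, init) {
  tm <- model$terms
  coef_names <- if (nrow(tm) > 0) paste(tm$param, tm$cov, sep = ".") else character()
  nm <- c("theta_cl", "theta_v", coef_names, "omega_cl", "omega_v", "sigma_prop")
  start <- c(log(init$theta_cl), log(init$theta_v),
             rep(0, length(coef_names)),
             log(init$omega_cl), log(init$omega_v), log(init$sigma_prop))
  names(start) <- nm
  list(names = nm, start = start, coef_names = coef_names,
       coef_types = tm$type)
}

# transformed vector -> natural-scale parameter list
unpack_pars <- function(par, skel) {
  coefs <- list()
  for (i in seq_along(skel$coef_names)) {
    nm <- skel$coef_names[i]
    coefs[[nm]] <- if (skel$coef_types[i] == "factor") exp(par[[nm]]) else par[[nm]]
  }
  list(theta_cl = exp(par[["theta_cl"]]), theta_v = exp(par[["theta_v"]]),
       coefs = coefs,
       omega_cl = exp(par[["omega_cl"]]), omega_v = exp(par[["omega_v"]]),
       sigma_prop = exp(par[["sigma_prop"]]))
}

# natural-scale fixed values -> transformed scale
transform_fixed <- function(fixed, skel) {
  out <- numeric(0)
  for (nm in names(fixed)) {
    if (!nm %in% skel$names) abort(sprintf("Unknown parameter `%s` in `fixed`.", nm))
    i <- match(nm, skel$coef_names)
    out[nm] <- if (!is.na(i) && skel$coef_types[i] == "power") {
      fixed[[nm]]
    } else {
      log(fixed[[nm]])
    }
  }
  out
}

# ---- fitting --------------------------------------------------------------

#' Fit the population pharmacokinetic model
#'
#' Maximises the Laplace-approximated marginal likelihood of the
#' one-compartment infusion model: an inner Newton optimisation of each
#' subject's random effects (run in compiled code) nested inside an outer
#' quasi-Newton optimisation of the population parameters. Below-LLOQ
#' observations are expected to have been imputed at half the LLOQ by
#' [clean_dataset()].
#'
#' @param data A cleaned [pk_dataset()].
#' @param model A [popk_model()].
#' @param init A [pop_params()] supplying starting values for the fixed
#'   effects, IIV and residual error (covariate coefficients start at the
#'   neutral value 0 on the working scale).
#' @param fixed Named list of parameters to hold fixed at natural-scale
#'   values, e.g. `list(omega_cl = 1e-3)`.
#' @param compute_se Compute the numerically differentiated Hessian for
#'   relative standard errors? (Skipped automatically inside bootstraps.)
#' @param control Passed to [stats::nlminb()].
#' @return A `popk_fit` object: parameter estimates with RSEs and
#'   shrinkage, the objective function value (`ofv`, -2 log likelihood),
#'   empirical Bayes eta estimates, convergence diagnostics, and the model /
#'   data bookkeeping needed by downstream stages.
#' @export
fit_popk <- function(data, model = popk_model(), init = pop_params(),
                     fixed = list(), compute_se = TRUE,
                     control = list(iter.max = 400, eval.max = 600,
                                    rel.tol = 1e-8)) {
  fd <- prepare_fit_data(data, model)
  refs <- resolve_refs(model, fd$subj)
  skel <- par_skeleton(model, init)
  fixed_t <- transform_fixed(fixed, skel)
  free_names <- setdiff(skel$names, names(fixed_t))
  if (length(free_names) == 0) abort("All parameters are fixed; nothing to fit.")
  n <- length(fd$ids)

  full_par <- function(p_free) {
    p <- skel$start
    p[names(fixed_t)] <- fixed_t
    p[free_names] <- p_free
    p
  }
  # inner optimisations start from eta = 0 every evaluation, so the
  # objective is a deterministic function of the parameters
  objective <- function(p_free) {
    p <- unpack_pars(full_par(p_free), skel)
    tv <- typical_values(model, refs, fd$subj, p$theta_cl, p$theta_v, p$coefs)
    res <- cpp_laplace_nll(tv$cl, tv$v, p$omega_cl^2, p$omega_v^2,
                           p$sigma_prop^2, fd$y, fd$t, fd$dose_t,
                           fd$dose_amt, fd$dose_dur, matrix(0, n, 2))
    if (!is.finite(res$nll)) return(1e10)
    res$nll
  }

  opt <- nlminb(skel$start[free_names], objective, control = control)
  if (opt$convergence != 0) { # polish restart from the located optimum
    opt2 <- nlminb(opt$par, objective, control = control)
    if (opt2$objective <= opt$objective || opt2$convergence == 0) opt <- opt2
  }
  converged <- opt$convergence == 0 && is.finite(opt$objective)
  if (!converged && is.finite(opt$objective) && length(free_names) > 1) {
    # verify the optimum with a derivative-free polish: if Nelder-Mead
    # cannot improve the objective, the point is accepted as converged
    nm <- optim(opt$par, objective, method = "Nelder-Mead",
                control = list(maxit = 500, reltol = 1e-10))
    if (nm$value < opt$objective - 1e-4) {
      opt3 <- nlminb(nm$par, objective, control = control)
      if (opt3$objective <= nm$value) {
        opt3$convergence <- 0L
        opt <- opt3
      } else {
        opt$par <- nm$par
        opt$objective <- nm$value
        opt$convergence <- 0L
      }
      converged <- TRUE
    } else {
      opt$convergence <- 0L
      converged <- TRUE
    }
  }
  if (!converged) {
    warn(sprintf("Fit did not converge cleanly (nlminb code %d: %s).",
                 opt$convergence, opt$message %||% ""))
  }

  p_hat <- unpack_pars(full_par(opt$par), skel)
  # final inner pass at the optimum for the empirical Bayes etas
  tv <- typical_values(model, refs, fd$subj, p_hat$theta_cl, p_hat$theta_v,
                       p_hat$coefs)
  res <- cpp_laplace_nll(tv$cl, tv$v, p_hat$omega_cl^2, p_hat$omega_v^2,
                         p_hat$sigma_prop^2, fd$y, fd$t, fd$dose_t,
                         fd$dose_amt, fd$dose_dur, matrix(0, n, 2))
  eta <- res$eta
  colnames(eta) <- c("eta_cl", "eta_v")

  rse <- rep(NA_real_, length(skel$names))
  names(rse) <- skel$names
  if (compute_se && converged) {
    H <- fd_hessian(objective, opt$par)
    V <- try(2 * solve(H), silent = TRUE)
    if (!inherits(V, "try-error") && all(is.finite(diag(V))) &&
        all(diag(V) > 0)) {
      se_t <- sqrt(diag(V))
      for (j in seq_along(free_names)) {
        nm <- free_names[j]
        i <- match(nm, skel$coef_names)
        est_nat <- if (!is.na(i) && skel$coef_types[i] == "power") {
          opt$par[[nm]]
        } else {
          NA # log-scale: RSE% ~ 100 * sd(log)
        }
        rse[nm] <- if (!is.na(i) && skel$coef_types[i] == "power") {
          100 * se_t[j] / abs(est_nat)
        } else {
          100 * se_t[j]
        }
      }
    }
  }

  shrink <- c(
    cl = 100 * (1 - sd(eta[, 1]) / p_hat$omega_cl),
    v = 100 * (1 - sd(eta[, 2]) / p_hat$omega_v)
  )
  shrink <- pmin(pmax(shrink, 0), 100)

  estimates <- tibble(
    parameter = skel$names,
    estimate = c(p_hat$theta_cl, p_hat$theta_v,
                 unlist(p_hat$coefs, use.names = FALSE),
                 p_hat$omega_cl, p_hat$omega_v, p_hat$sigma_prop),
    rse = rse[skel$names],
    fixed = skel$names %in% names(fixed_t)
  )

  structure(list(
    estimates = estimates, params = p_hat, ofv = opt$objective,
    converged = converged, opt = opt[c("convergence", "message",
                                       "iterations", "evaluations")],
    eta = as_tibble(eta) |> mutate(id = fd$ids, .before = 1),
    shrinkage = shrink, model = model, refs = refs, subj = fd$subj,
    ids = fd$ids, data = data, init = init, fixed = fixed,
    cv_convention = init$cv_convention
  ), class = "popk_fit")
}

# Common bridge: accept either a fitted object or bare population
# parameters (assumed to follow the final covariate structure).
fit_bridge <- function(fit) {
  if (inherits(fit, "pop_params")) {
    list(model = final_model(refs = list(egfr_ckdepi = fit$egfr_ref)),
         params = list(theta_cl = fit$theta_cl, theta_v = fit$theta_v,
                       coefs = list(cl.egfr_ckdepi = fit$gamma_egfr,
                                    cl.abx = fit$theta_abx),
                       omega_cl = fit$omega_cl, omega_v = fit$omega_v,
                       sigma_prop = fit$sigma_prop),
         refs = list(egfr_ckdepi = fit$egfr_ref))
  } else if (inherits(fit, "popk_fit")) {
    list(model = fit$model, params = fit$params, refs = fit$refs)
  } else {
    abort("Expected a `popk_fit` or `pop_params` object.")
  }
}

# Central-difference Hessian (the objective is -2 log likelihood).
fd_hessian <- function(f, x, h = 1e-3) {
  p <- length(x)
  H <- matrix(NA_real_, p, p)
  f0 <- f(x)
  step <- pmax(abs(x), 1) * h
  for (i in seq_len(p)) {
    for (j in i:p) {
      ei <- ej <- numeric(p)
      ei[i] <- step[i]; ej[j] <- step[j]
      if (i == j) {
        H[i, i] <- (f(x + ei) - 2 * f0 + f(x - ei)) / step[i]^2
      } else {
        H[i, j] <- H[j, i] <-
          (f(x + ei + ej) - f(x + ei - ej) - f(x - ei + ej) + f(x - ei - ej)) /
          (4 * step[i] * step[j])
      }
    }
  }
  H
}

#' @export
print.popk_fit <- function(x, ...) {
  cat(sprintf("<popk_fit> OFV %.3f (%s)\n", x$ofv,
              if (x$converged) "converged" else "NOT CONVERGED"))
  est <- x$estimates
  est$estimate <- signif(est$estimate, 4)
  print(as.data.frame(est), row.names = FALSE)
  cat(sprintf("Eta shrinkage: CL %.1f%%, V %.1f%%\n",
              x$shrinkage["cl"], x$shrinkage["v"]))
  invisible(x)
}

#' @export
tidy.popk_fit <- function(x, ...) {
  x$estimates |>
    mutate(rse = .data$rse,
           cv = dplyr::case_when(
             .data$parameter %in% c("omega_cl", "omega_v") ~
               omega_to_cv(.data$estimate, x$cv_convention),
             .data$parameter == "sigma_prop" ~ 100 * .data$estimate,
             TRUE ~ NA_real_
           ))
}

#' @export
glance.popk_fit <- function(x, ...) {
  tibble(ofv = x$ofv, converged = x$converged,
         n_subjects = length(x$ids),
         n_obs = sum(as_tibble(x$data)$evid == 0),
         iiv_cl_cv = omega_to_cv(x$params$omega_cl, x$cv_convention),
         iiv_v_cv = omega_to_cv(x$params$omega_v, x$cv_convention),
         shrinkage_cl = x$shrinkage[["cl"]], shrinkage_v = x$shrinkage[["v"]])
}

#' Population parameters implied by a fit
#'
#' Maps a fitted final-structure model (eGFR power term and antibiotic
#' factor on CL) onto a [pop_params()] object for downstream simulation.
#' Terms absent from the model map to neutral values (exponent 0, factor 1).
#'
#' @param fit A `popk_fit`.
#' @return A [pop_params()].
#' @export
fit_pop_params <- function(fit) {
  stopifnot(inherits(fit, "popk_fit"))
  p <- fit$params
  gamma <- p$coefs[["cl.egfr_ckdepi"]] %||% 0
  beta <- p$coefs[["cl.abx"]] %||% 1
  pop_params(
    theta_cl = p$theta_cl, theta_v = p$theta_v,
    gamma_egfr = gamma, theta_abx = beta,
    egfr_ref = fit$refs[["egfr_ckdepi"]] %||% 76.86,
    cv_cl = omega_to_cv(p$omega_cl, fit$cv_convention),
    cv_v = omega_to_cv(p$omega_v, fit$cv_convention),
    sigma_prop = 100 * p$sigma_prop,
    cv_convention = fit$cv_convention
  )
}

#' Empirical Bayes individual parameters
#'
#' Posterior-mode (MAP) random effects for each subject given population
#' parameters: penalised least squares on the log-parameters under the
#' proportional-error likelihood. Subjects with no observations return
#' `eta = 0`, i.e. population typical values.
#'
#' @param data A cleaned [pk_dataset()].
#' @param fit Either a `popk_fit` (its model and estimates are used) or a
#'   [pop_params()] (the final covariate structure is assumed).
#' @return A tibble with one row per subject: `id`, `eta_cl`, `eta_v`,
#'   `cl`, `v`.
#' @export
empirical_bayes <- function(data, fit) {
  br <- fit_bridge(fit)
  model <- br$model; params <- br$params; refs <- br$refs
  fd <- prepare_fit_data(data, model)
  tv <- typical_values(model, refs, fd$subj, params$theta_cl, params$theta_v,
                       params$coefs)
  res <- cpp_laplace_nll(tv$cl, tv$v, params$omega_cl^2, params$omega_v^2,
                         params$sigma_prop^2, fd$y, fd$t, fd$dose_t,
                         fd$dose_amt, fd$dose_dur,
                         matrix(0, length(fd$ids), 2))
  eta <- res$eta
  tibble(id = fd$ids,
         eta_cl = eta[, 1], eta_v = eta[, 2],
         cl = tv$cl * exp(eta[, 1]),
         v = tv$v * exp(eta[, 2]))
}
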