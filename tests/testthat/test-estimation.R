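# A small noise-free cohort: fixed design, typical-value observations.
noise_free_cohort <- function(seed = 5) {
  spec <- cohort_spec(pop = pop_params(cv_cl = 0, cv_v = 0, sigma_prop = 0),
                      misdose = FALSE, short_course = FALSE, lloq = 1e-9)
  quiet_clean(sample_cohort(spec, seed = seed)$data)
}

test_that("degenerate identifiability: noise-free, zero-IIV data recover the thetas", {
  d <- noise_free_cohort()
  fit <- fit_popk(
    d, final_model(),
    fixed = list(omega_cl = 1e-3, omega_v = 1e-3, sigma_prop = 0.01),
    compute_se = FALSE
  )
  expect_true(fit$converged)
  expect_equal(fit$params$theta_cl, 3.74, tolerance = 1e-3)
  expect_equal(fit$params$theta_v, 21.8, tolerance = 1e-3)
  expect_equal(fit$params$coefs[["cl.egfr_ckdepi"]], 0.75, tolerance = 2e-3)
  expect_equal(fit$params$coefs[["cl.abx"]], 1.56, tolerance = 2e-3)
})

test_that("the fit is invariant to subject ordering", {
  co <- sample_cohort(cohort_spec(), seed = 9)
  d <- quiet_clean(co$data)
  f1 <- fit_popk(d, popk_model(), compute_se = FALSE)
  shuffled <- tibble::as_tibble(d) |>
    dplyr::arrange(factor(id, levels = sample(unique(id))), time)
  d2 <- pk_dataset(shuffled)
  f2 <- fit_popk(d2, popk_model(), compute_se = FALSE)
  expect_equal(f1$ofv, f2$ofv, tolerance = 1e-8)
  expect_equal(f1$params$theta_cl, f2$params$theta_cl, tolerance = 1e-6)
})

test_that("with variances forced to zero the optimum matches a pooled regression oracle", {
  d <- noise_free_cohort(seed = 13)
  fit <- fit_popk(
    d, popk_model(),
    fixed = list(omega_cl = 1e-4, omega_v = 1e-4, sigma_prop = 0.02),
    compute_se = FALSE
  )
  # independent oracle: pooled proportional least squares via optim
  dd <- tibble::as_tibble(d)
  obs <- dd[dd$evid == 0, ]
  doses <- dd[dd$evid == 1, ]
  sse <- function(par) {
    cl0 <- exp(par[1]); v0 <- exp(par[2])
    sum(vapply(seq_len(nrow(obs)), function(k) {
      dk <- doses[doses$id == obs$id[k], ]
      f <- pk_concentration(pk_profile(cl0, v0, regimen(dk$time, dk$amt, dk$dur)),
                            obs$time[k])
      ((obs$dv[k] - f) / max(f, 1e-4))^2
    }, numeric(1)))
  }
  o <- optim(log(c(4, 20)), sse, control = list(reltol = 1e-12))
  # pooled model has no covariates, so the oracle fits the same criterion
  expect_equal(fit$params$theta_cl, exp(o$par[1]), tolerance = 5e-3)
  expect_equal(fit$params$theta_v, exp(o$par[2]), tolerance = 5e-3)
})

test_that("empirical Bayes estimates have the right limits", {
  pop <- pop_params()
  d <- quiet_clean(sample_cohort(cohort_spec(), seed = 31)$data)
  # prior-dominated limit: omega -> 0 collapses etas to zero
  pop0 <- pop_params(cv_cl = 1e-4, cv_v = 1e-4)
  eb0 <- empirical_bayes(d, pop0)
  expect_lt(max(abs(c(eb0$eta_cl, eb0$eta_v))), 1e-4)

  # likelihood-dominated limit: noise-free data, wide prior -> truth
  spec <- cohort_spec(pop = pop_params(sigma_prop = 0),
                      misdose = FALSE, short_course = FALSE, lloq = 1e-9)
  co <- sample_cohort(spec, seed = 17)
  d_nf <- quiet_clean(co$data)
  wide <- pop_params(cv_cl = 500, cv_v = 500, sigma_prop = 1)
  eb <- empirical_bayes(d_nf, wide)
  three_obs <- tibble::as_tibble(d_nf) |>
    dplyr::filter(evid == 0) |>
    dplyr::count(id) |>
    dplyr::filter(n >= 3) |>
    dplyr::pull(id)
  keep <- eb$id %in% three_obs
  err_cl <- abs(eb$cl[keep] - co$truth$cl[co$truth$id %in% three_obs]) /
    co$truth$cl[co$truth$id %in% three_obs]
  expect_lt(median(err_cl), 0.01)

  # subjects without observations sit at the population typical values
  dd <- tibble::as_tibble(d)
  no_obs <- dplyr::bind_rows(dd, dd[dd$evid == 1 & dd$id == 1, ] |>
                               dplyr::mutate(id = 999))
  eb2 <- empirical_bayes(pk_dataset(no_obs), pop)
  expect_equal(eb2$eta_cl[eb2$id == 999], 0)
  expect_equal(eb2$eta_v[eb2$id == 999], 0)
})

test_that("seeded bootstrap is deterministic and counts failures", {
  d <- quiet_clean(sample_cohort(cohort_spec(), seed = 3)$data)
  b1 <- bootstrap_popk(d, final_model(), n_replicates = 2, seed = 88)
  b2 <- bootstrap_popk(d, final_model(), n_replicates = 2, seed = 88)
  expect_identical(b1$replicates, b2$replicates)
  expect_true(all(c("median", "ci_lo", "ci_hi") %in% names(b1$summary)))
  expect_lte(b1$n_failed, 2)
})

test_that("bootstrap confidence intervals shrink with a larger cohort", {
  small <- quiet_clean(sample_cohort(cohort_spec(), seed = 57)$data)
  big_spec <- cohort_spec(n = c(adequate = 100, moderate = 40, severe = 20))
  big <- quiet_clean(sample_cohort(big_spec, seed = 57)$data)
  bs <- bootstrap_popk(small, final_model(), n_replicates = 12, seed = 4)
  bb <- bootstrap_popk(big, final_model(), n_replicates = 12, seed = 4)
  w <- function(b) {
    s <- b$summary[b$summary$parameter == "theta_cl", ]
    s$ci_hi - s$ci_lo
  }
  expect_lt(w(bb), w(bs))
})
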