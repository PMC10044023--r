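test_that("the default virtual cohort reproduces the study layout", {
  co <- sample_cohort(cohort_spec(), seed = 101)
  expect_equal(nrow(co$truth), 40)
  expect_equal(unname(table(co$truth$group)[c("adequate", "moderate", "severe")]),
               c(25, 10, 5), ignore_attr = TRUE)
  # eGFR samples stay inside their stratum's interval
  expect_true(all(co$truth$egfr_ckdepi[co$truth$group == "adequate"] >= 50))
  rng_mod <- range(co$truth$egfr_ckdepi[co$truth$group == "moderate"])
  expect_true(rng_mod[1] >= 30 && rng_mod[2] < 50)
  expect_true(all(co$truth$egfr_ckdepi[co$truth$group == "severe"] < 30))
  # exactly one mis-dosed severe subject and one 24 h-only adequate subject
  expect_equal(sum(co$truth$misdosed), 1)
  expect_equal(co$truth$group[co$truth$misdosed], "severe")
  expect_equal(sum(co$truth$short_course), 1)
  d <- tibble::as_tibble(co$data)
  mis_id <- co$truth$id[co$truth$misdosed]
  expect_equal(unique(d$amt[d$id == mis_id & d$evid == 1]), 2000)
  sc_id <- co$truth$id[co$truth$short_course]
  expect_lt(max(d$time[d$id == sc_id & d$evid == 1]), 24)
  # renal markers are mutually consistent (scr inverted from eGFR)
  expect_equal(egfr_ckdepi(co$truth$scr, co$truth$age, co$truth$sex),
               co$truth$egfr_ckdepi, tolerance = 1e-6)
})

test_that("cohorts are byte-identical under a fixed seed", {
  a <- sample_cohort(cohort_spec(), seed = 77)
  b <- sample_cohort(cohort_spec(), seed = 77)
  expect_identical(as.data.frame(a$data), as.data.frame(b$data))
  expect_identical(a$truth, b$truth)
  c <- sample_cohort(cohort_spec(), seed = 78)
  expect_false(identical(as.data.frame(a$data), as.data.frame(c$data)))
})

test_that("the noise-free limit reproduces typical-value predictions exactly", {
  spec <- cohort_spec(pop = pop_params(cv_cl = 0, cv_v = 0, sigma_prop = 0),
                      misdose = FALSE, short_course = FALSE)
  co <- sample_cohort(spec, seed = 5)
  d <- tibble::as_tibble(co$data)
  obs <- d[d$evid == 0 & d$blq == 0, ]
  pred <- vapply(seq_len(nrow(obs)), function(k) {
    i <- obs$id[k]
    doses <- d[d$id == i & d$evid == 1, ]
    tv_cl <- typical_clearance(obs$egfr_ckdepi[k], obs$abx[k], spec$pop)
    pr <- pk_profile(tv_cl, spec$pop$theta_v,
                     regimen(doses$time, doses$amt, doses$dur))
    pk_concentration(pr, obs$time[k])
  }, numeric(1))
  expect_equal(obs$dv, pred, tolerance = 1e-12)
})

test_that("marginal prevalences calibrate to the cohort targets", {
  spec <- cohort_spec(n = c(adequate = 125, moderate = 50, severe = 25))
  co <- sample_cohort(spec, seed = 33)
  # binomial 95% bounds around the overall 27/40 antibiotic prevalence
  p_hat <- mean(co$truth$abx)
  bounds <- qbinom(c(0.025, 0.975), 200, 27 / 40) / 200
  expect_gte(p_hat, bounds[1])
  expect_lte(p_hat, bounds[2])
  # per-group eGFR medians within 15% of their targets
  med <- tapply(co$truth$egfr_ckdepi, co$truth$group, median)
  expect_equal(as.vector(med[c("adequate", "moderate", "severe")]),
               c(102.8, 34.3, 18.6), tolerance = 0.15)
})

test_that("infeasible specs are rejected up front", {
  expect_error(cohort_spec(egfr_median = c(102.8, 60, 18.6)), "interval")
  expect_error(cohort_spec(dose_shift_prob = 1.2), "0, 1")
  expect_error(cohort_spec(n = c(adequate = 0, moderate = 10, severe = 5)),
               "positive")
})

test_that("the morning-round shift adds an administration in the first day", {
  reg <- regimen_q(24, 1000, t_end = 72)
  expect_identical(apply_dose_shift(reg, FALSE, 22), reg)
  # first dose at 22:00, q24h: extra dose ~10 h later, then q24h from there
  sh <- apply_dose_shift(reg, TRUE, 22)
  expect_equal(sh$time, c(0, 10, 34, 58))
  # flagged q8h regimens give at least 4 administrations in the first 24 h
  for (clock in c(1, 5.5, 9, 14, 18, 22.25)) {
    sh8 <- apply_dose_shift(regimen_q(8, 2000, t_end = 72), TRUE, clock)
    expect_gte(sum(sh8$time < 24), 4)
  }
})
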