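test_that("covariate clearance equation reproduces its reference values", {
  p <- pop_params()
  expect_equal(typical_clearance(76.86, 0, p), 3.74)
  expect_equal(typical_clearance(76.86, 1, p), 3.74 * 1.56)
  # frozen hand evaluation of 3.74 * (18.6/76.86)^0.75
  expect_equal(typical_clearance(18.6, 0, p), 1.2904198211, tolerance = 1e-9)
  # monotone increasing in eGFR for a positive exponent
  egfr <- sort(runif(20, 5, 150))
  expect_true(all(diff(typical_clearance(egfr, 0, p)) > 0))
  expect_error(typical_clearance(0, 0, p), "positive")
  expect_error(typical_clearance(-5, 0, p), "positive")
})

test_that("individual parameters follow the log-normal construction", {
  p <- pop_params()
  ip0 <- individual_parameters(60, 1, 0, 0, p)
  expect_equal(ip0$cl, typical_clearance(60, 1, p))
  expect_equal(ip0$v, p$theta_v)
  ip2 <- individual_parameters(60, 1, log(2), 0, p)
  expect_equal(ip2$cl, 2 * ip0$cl)
  expect_error(individual_parameters(60, 0, NaN, 0, p), "finite")
})

test_that("sampled clearance CV matches the chosen CV convention", {
  withr::with_seed(11, {
    p_ln <- pop_params(cv_convention = "lognormal")
    eta <- rnorm(1e5, 0, p_ln$omega_cl)
    cl <- typical_clearance(76.86, 0, p_ln) * exp(eta)
    cv_emp <- 100 * sd(cl) / mean(cl)
    # lognormal convention: empirical CV within 1% (relative) of 31.3%
    expect_equal(cv_emp, 31.3, tolerance = 0.01)
    # sd convention: omega is the reported fraction itself
    p_sd <- pop_params(cv_convention = "sd")
    expect_equal(p_sd$omega_cl, 0.313)
    cl_sd <- exp(rnorm(1e5, 0, p_sd$omega_cl))
    expect_equal(100 * sd(cl_sd) / mean(cl_sd),
                 omega_to_cv(0.313, "lognormal"), tolerance = 0.01)
  })
})

test_that("concentration is zero before dosing and reaches the bolus limit", {
  pr <- pk_profile(4, 20, regimen(c(0, 8), 1000, 0.5))
  expect_equal(pk_concentration(pr, c(-1, 0)), c(0, 0))
  # duration -> 0: concentration just after dosing tends to amount / V
  pr_bolus <- pk_profile(4, 20, regimen(0, 1000, 1e-7))
  expect_equal(pk_concentration(pr_bolus, 1e-7), 1000 / 20, tolerance = 1e-5)
})

test_that("analytic concentrations match the ODE oracle", {
  skip_if_not_installed("deSolve")
  withr::with_seed(21, {
    for (k in 1:12) {
      inst <- random_instance()
      t_eval <- sort(runif(15, 0.05, inst$horizon))
      ana <- pk_concentration(inst$profile, t_eval)
      ode <- ode_concentration(inst$reg, inst$cl, inst$v, t_eval)
      keep <- ode > 1e-6
      expect_lt(max(abs(ana[keep] - ode[keep]) / ode[keep]), 1e-6)
    }
  })
})

test_that("analytic AUC is exact: quadrature oracle, additivity, mass balance", {
  withr::with_seed(22, {
    for (k in 1:5) {
      inst <- random_instance()
      a <- runif(1, 0, inst$horizon / 2)
      b <- runif(1, inst$horizon / 2 + 0.5, inst$horizon)
      expect_equal(pk_auc(inst$profile, a, b), grid_auc(inst$profile, a, b),
                   tolerance = 1e-4)
      m <- (a + b) / 2
      expect_equal(pk_auc(inst$profile, a, m) + pk_auc(inst$profile, m, b),
                   pk_auc(inst$profile, a, b), tolerance = 1e-10)
    }
  })
  # steady state: AUC over one full inter-dose interval equals dose/CL
  reg <- regimen_q(12, 1000, t_end = 1000)
  pr <- pk_profile(3, 20, reg)
  expect_equal(pk_auc(pr, 960, 972), 1000 / 3, tolerance = 1e-9)
  expect_error(pk_auc(pr, 24, 12), "window")
})

test_that("time above MIC: closed form agrees with the grid oracle", {
  pr <- pk_profile(3.74, 21.8, regimen_q(8, 2000, t_end = 24))
  expect_equal(pk_time_above_mic(pr, 0, 0, 24), 24)
  expect_equal(pk_time_above_mic(pr, 0, -5, 24), 24) # first dose at 0
  expect_equal(pk_time_above_mic(pr, 1e6, 0, 24), 0) # above any Cmax
  expect_error(pk_time_above_mic(pr, -1, 0, 24), "non-negative")
  withr::with_seed(23, {
    for (k in 1:8) {
      inst <- random_instance()
      mic <- runif(1, 0.5, 40)
      expect_equal(
        pk_time_above_mic(inst$profile, mic, 0, inst$horizon),
        grid_time_above(inst$profile, mic, 0, inst$horizon),
        tolerance = 2e-3
      )
    }
  })
})

test_that("dose linearity, superposition and monotonicity hold", {
  withr::with_seed(24, {
    for (k in 1:10) {
      inst <- random_instance()
      t_eval <- sort(runif(10, 0, inst$horizon))
      kf <- runif(1, 0.2, 3)
      scaled <- pk_profile(inst$cl, inst$v,
                           regimen(inst$reg$time, inst$reg$amount * kf,
                                   inst$reg$duration))
      expect_equal(pk_concentration(scaled, t_eval),
                   kf * pk_concentration(inst$profile, t_eval),
                   tolerance = 1e-12)
      # superposition: sum of single-dose profiles
      singles <- Reduce(`+`, lapply(seq_len(nrow(inst$reg)), function(d) {
        one <- pk_profile(inst$cl, inst$v,
                          regimen(inst$reg$time[d], inst$reg$amount[d],
                                  inst$reg$duration[d]))
        pk_concentration(one, t_eval)
      }))
      expect_equal(pk_concentration(inst$profile, t_eval), singles,
                   tolerance = 1e-12)
      # time above MIC non-increasing in MIC, non-decreasing in dose
      mics <- sort(runif(5, 0.1, 60))
      th <- vapply(mics, function(m) {
        pk_time_above_mic(inst$profile, m, 0, inst$horizon)
      }, numeric(1))
      expect_true(all(diff(th) <= 1e-9))
      th_hi <- pk_time_above_mic(scaled, mics[3], 0, inst$horizon)
      th_lo <- pk_time_above_mic(inst$profile, mics[3], 0, inst$horizon)
      if (kf >= 1) expect_gte(th_hi, th_lo - 1e-9) else
        expect_lte(th_hi, th_lo + 1e-9)
    }
  })
})

test_that("regimens validate and flag overlapping infusions", {
  expect_error(regimen(c(0, 8, 8), 1000), "strictly increasing")
  expect_error(regimen(0, -10), "positive")
  expect_message(regimen(c(0, 0.2), 500, 0.5), "Overlapping")
  r <- regimen_q(8, 2000, t_end = 24)
  expect_equal(r$time, c(0, 8, 16))
})
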