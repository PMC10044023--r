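small_sim_cohort <- function(seed = 19) {
  spec <- cohort_spec(n = c(adequate = 6, moderate = 4, severe = 3),
                      misdose = FALSE, short_course = FALSE)
  quiet_clean(sample_cohort(spec, seed = seed)$data)
}

test_that("the simulation is deterministic under a fixed seed", {
  d <- small_sim_cohort()
  s1 <- simulate_pta(d, pop_params(), n_replicates = 20, mic = c(1, 8), seed = 6)
  s2 <- simulate_pta(d, pop_params(), n_replicates = 20, mic = c(1, 8), seed = 6)
  expect_identical(s1$pooled, s2$pooled)
  expect_identical(s1$per_replicate, s2$per_replicate)
  s3 <- simulate_pta(d, pop_params(), n_replicates = 20, mic = c(1, 8), seed = 7)
  expect_false(identical(s1$pooled, s3$pooled))
})

test_that("without variability an above-target typical profile attains always", {
  d <- small_sim_cohort()
  pop0 <- pop_params(cv_cl = 0, cv_v = 0)
  s <- simulate_pta(d, pop0, n_replicates = 5, mic = 0.125, seed = 2)
  expect_true(all(s$pooled$pta == 1))
  expect_true(all(s$per_replicate$pta == 1))
})

test_that("PTA is monotone in MIC and non-increasing when doses are halved", {
  d <- small_sim_cohort()
  s <- simulate_pta(d, pop_params(), n_replicates = 40,
                    mic = c(0.5, 2, 8, 32, 128), seed = 11)
  for (g in unique(s$pooled$group)) {
    expect_true(all(diff(s$pooled$pta[s$pooled$group == g]) <= 1e-12))
  }
  halved <- tibble::as_tibble(d) |>
    dplyr::mutate(amt = ifelse(evid == 1, amt / 2, amt))
  s_half <- simulate_pta(pk_dataset(halved), pop_params(), n_replicates = 40,
                         mic = c(0.5, 2, 8, 32, 128), seed = 11)
  cmp <- dplyr::left_join(s$pooled, s_half$pooled, by = c("group", "mic"),
                          suffix = c("", "_half"))
  expect_true(all(cmp$pta_half <= cmp$pta + 1e-12))
})

test_that("replicate-mean PTA noise scales roughly as 1/sqrt(n)", {
  d <- small_sim_cohort()
  s <- simulate_pta(d, pop_params(), n_replicates = 400, mic = 8, seed = 21)
  pr <- s$per_replicate |>
    dplyr::filter(group == "severe") |>
    dplyr::arrange(replicate) |>
    dplyr::pull(pta)
  block_sd <- function(size) {
    sd(vapply(split(pr, ceiling(seq_along(pr) / size)), mean, numeric(1)))
  }
  ratio <- block_sd(4) / block_sd(16)
  expect_gt(ratio, 1.3)
  expect_lt(ratio, 3.1)
})

test_that("a cohort-spec source draws covariates once, honouring the margins", {
  spec <- cohort_spec()
  s <- simulate_pta(spec, pop_params(), n_replicates = 3, mic = 8, seed = 12)
  counts <- s$pooled |> dplyr::group_by(group) |> dplyr::summarise(n = sum(n))
  expect_equal(counts$n[counts$group == "adequate"], 25 * 3)
  expect_equal(counts$n[counts$group == "moderate"], 10 * 3)
  expect_equal(counts$n[counts$group == "severe"], 5 * 3)
})

test_that("shift-vs-exact comparison isolates the extra morning dose", {
  # unshifted cohort: the administered and exact-interval regimens coincide
  spec0 <- cohort_spec(dose_shift_prob = 0, misdose = FALSE,
                       short_course = FALSE,
                       n = c(adequate = 4, moderate = 3, severe = 2))
  co0 <- sample_cohort(spec0, seed = 8)
  cmp0 <- compare_shift_vs_exact(quiet_clean(co0$data), co0$truth)
  expect_equal(cmp0$subjects$t_above_observed, cmp0$subjects$t_above_exact,
               tolerance = 1e-9)

  # an always-shifted q24h stratum: the observed arm has an extra dose in
  # the first day, which can only increase time above MIC there
  spec1 <- cohort_spec(dose_shift_prob = 1, misdose = FALSE,
                       short_course = FALSE,
                       n = c(adequate = 1, moderate = 1, severe = 6))
  co1 <- sample_cohort(spec1, seed = 9)
  cmp1 <- compare_shift_vs_exact(quiet_clean(co1$data), co1$truth, mic = 8)
  sev <- cmp1$subjects[cmp1$subjects$group == "severe", ]
  expect_true(all(sev$t_above_observed >= sev$t_above_exact - 1e-9))
  expect_true(all(c("pta_observed", "pta_exact") %in% names(cmp1$summary)))
})
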