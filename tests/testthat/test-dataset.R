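test_that("the packaged example cohort reads as three subjects", {
  path <- system.file("extdata", "example_cohort.csv", package = "ceftapk")
  d <- read_pk_dataset(path)
  expect_equal(length(unique(d$id)), 3)
  expect_equal(sum(d$evid == 1), 4)
  expect_equal(attr(d, "lloq"), 0.1)
})

test_that("the CSV dialect round-trips", {
  d <- toy_dataset()
  expect_equal(length(unique(d$id)), 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_pk_dataset(d, path)
  d2 <- read_pk_dataset(path)
  expect_equal(as.data.frame(d2), as.data.frame(d), tolerance = 1e-12)
})

test_that("missing required columns produce errors naming the column", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_pk_dataset(toy_dataset(), path)
  raw <- readr::read_csv(path, show_col_types = FALSE)
  readr::write_csv(raw[setdiff(names(raw), "DV")], path)
  expect_error(read_pk_dataset(path), "DV")
  expect_error(read_pk_dataset("no-such-file.csv"), "not found")
  # column remapping recovers a renamed concentration column
  raw2 <- raw
  names(raw2)[names(raw2) == "DV"] <- "CONC"
  readr::write_csv(raw2, path)
  expect_equal(read_pk_dataset(path, col_map = c(DV = "CONC"))$dv,
               toy_dataset()$dv)
})

test_that("dataset validation catches malformed rows", {
  base <- tibble::as_tibble(toy_dataset())
  bad_time <- base
  bad_time$time[2] <- -1
  expect_error(pk_dataset(bad_time), "0")
  shuffled <- base
  shuffled$time[shuffled$id == 2] <- c(12, 0, 2, 6)
  expect_error(pk_dataset(shuffled), "non-decreasing")
  expect_error(pk_dataset(base[setdiff(names(base), "blq")]), "blq")
})

blq_fixture <- function(blq_times) {
  rows <- dplyr::bind_rows(
    tibble::tibble(id = 1, time = 0, evid = 1, amt = 1000, dur = 0.5,
                   dv = NA_real_, blq = 0L),
    tibble::tibble(id = 1, time = c(2, 10, 24, 30), evid = 0,
                   amt = NA_real_, dur = NA_real_,
                   dv = c(20, 5, 0.3, 0.2), blq = 0L)
  )
  rows$blq[rows$evid == 0 & rows$time %in% blq_times] <- 1L
  rows$dv[rows$blq == 1] <- NA_real_
  pk_dataset(rows)
}

test_that("BLQ handling imputes the first of a run and drops the rest", {
  one <- apply_blq_rule(blq_fixture(24), quiet = TRUE)
  expect_equal(one$dv[one$evid == 0 & one$time == 24], 0.05)
  expect_equal(sum(one$evid == 0), 4)

  # 24 h and 30 h are consecutive BLQ: first imputed, second removed
  two <- apply_blq_rule(blq_fixture(c(24, 30)), quiet = TRUE)
  expect_equal(two$dv[two$evid == 0 & two$time == 24], 0.05)
  expect_false(30 %in% two$time[two$evid == 0])
  expect_equal(sum(two$evid == 0), 3)

  none <- blq_fixture(numeric())
  expect_equal(as.data.frame(apply_blq_rule(none, quiet = TRUE)),
               as.data.frame(none))
})

test_that("duplicate observation timepoints collapse to the first record", {
  rows <- tibble::tibble(
    id = 1, time = c(0, 2, 2, 2, 5), evid = c(1, 0, 0, 0, 0),
    amt = c(500, NA, NA, NA, NA), dur = c(0.5, NA, NA, NA, NA),
    dv = c(NA, 8, 9, 10, 3), blq = 0L
  )
  d <- drop_duplicate_timepoints(pk_dataset(rows), quiet = TRUE)
  obs2 <- d$dv[d$evid == 0 & d$time == 2]
  expect_equal(obs2, 8) # three-fold duplicate leaves one (the first)
  expect_equal(sum(d$evid == 0), 2)
  distinct <- pk_dataset(rows[c(1, 2, 5), ])
  expect_equal(as.data.frame(drop_duplicate_timepoints(distinct, quiet = TRUE)),
               as.data.frame(distinct))
})

test_that("cleaning is idempotent and never touches dose rows", {
  d <- blq_fixture(c(24, 30))
  once <- clean_dataset(d, quiet = TRUE)
  twice <- clean_dataset(once, quiet = TRUE)
  expect_equal(as.data.frame(twice), as.data.frame(once))
  doses_before <- dplyr::filter(tibble::as_tibble(d), evid == 1)
  doses_after <- dplyr::filter(tibble::as_tibble(once), evid == 1)
  expect_equal(as.data.frame(doses_after), as.data.frame(doses_before))
})
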