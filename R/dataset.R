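#' Longitudinal analysis datasets
#'
#' The analysis dataset follows the common pharmacometric event-record
#' layout: one row per dose or observation event per subject. The CSV dialect
#' uses upper-case NONMEM-style headers `ID, TIME, EVID, AMT, DUR, DV, BLQ`
#' plus covariate columns; in R the dataset is a tibble with lower-case
#' column names and attributes `lloq` / `uloq` for the assay limits
#' (defaults 0.1 and 40 mg/L).
#'
#' Required columns: `id`, `time` (h since the subject's first dose), `evid`
#' (1 = dose, 0 = observation), `amt` (mg, doses), `dur` (h, infusion
#' duration), `dv` (mg/L, observations), `blq` (0/1). Covariate columns are
#' carried through untouched.
#'
#' @param data A data frame of event rows (lower-case names as above).
#' @param lloq,uloq Assay quantification limits (mg/L).
#' @return A `pk_dataset` tibble.
#' @export
pk_dataset <- function(data, lloq = 0.1, uloq = 40) {
  data <- as_tibble(data)
  required <- c("id", "time", "evid", "amt", "dur", "dv", "blq")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(sprintf("Dataset is missing required column(s): %s.",
                  paste(missing_cols, collapse = ", ")))
  }
  if (any(!is.finite(data$time)) || any(data$time < 0)) {
    bad <- which(!is.finite(data$time) | data$time < 0)[1]
    abort(sprintf("Row %d: times must be finite and >= 0.", bad))
  }
  if (any(!data$evid %in% c(0, 1))) {
    abort(sprintf("Row %d: `evid` must be 0 (observation) or 1 (dose).",
                  which(!data$evid %in% c(0, 1))[1]))
  }
  mono <- data |>
    group_by(.data$id) |>
    summarise(ok = !is.unsorted(.data$time), .groups = "drop")
  if (any(!mono$ok)) {
    abort(sprintf("Subject %s: times are not non-decreasing.",
                  mono$id[!mono$ok][1]))
  }
  obs <- data$evid == 0
  bad_dv <- obs & !(data$blq %in% 1) & (is.na(data$dv) | data$dv < 0)
  if (any(bad_dv)) {
    abort(sprintf("Row %d: observations must have `dv` >= 0 or be BLQ-flagged.",
                  which(bad_dv)[1]))
  }
  if (any(data$evid == 1 & (is.na(data$amt) | data$amt <= 0))) {
    abort("Dose rows must carry a positive `amt`.")
  }
  structure(data, lloq = lloq, uloq = uloq,
            class = c("pk_dataset", class(data)))
}

#' Read / write the event-record CSV dialect
#'
#' `read_pk_dataset()` reads a NONMEM-style CSV (headers `ID, TIME, EVID,
#' AMT, DUR, DV, BLQ`, covariates in additional columns) into a
#' [pk_dataset()]; `write_pk_dataset()` writes one back. The pair
#' round-trips: `read_pk_dataset(write_pk_dataset(d, f))` equals `d` up to
#' float formatting.
#'
#' @param path File path.
#' @param col_map Optional named character vector remapping non-standard
#'   headers, e.g. `c(DV = "CONC")` if concentrations are in a column CONC.
#' @inheritParams pk_dataset
#' @return `read_pk_dataset()` returns a `pk_dataset`;
#'   `write_pk_dataset()` returns `path` invisibly.
#' @export
read_pk_dataset <- function(path, lloq = 0.1, uloq = 40, col_map = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (col_map[[std]] %in% names(raw)) {
        names(raw)[names(raw) == col_map[[std]]] <- std
      }
    }
  }
  required <- c("ID", "TIME", "EVID", "AMT", "DUR", "DV", "BLQ")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(sprintf("%s is missing required column(s): %s.",
                  basename(path), paste(missing_cols, collapse = ", ")))
  }
  names(raw) <- tolower(names(raw))
  pk_dataset(raw, lloq = lloq, uloq = uloq)
}

#' @rdname read_pk_dataset
#' @export
write_pk_dataset <- function(data, path) {
  stopifnot(inherits(data, "pk_dataset"))
  out <- as_tibble(data)
  names(out) <- toupper(names(out))
  readr::write_csv(out, path, na = "")
  invisible(path)
}

#' Impute and prune below-quantification observations
#'
#' The first below-LLOQ observation in a within-subject run is set to half
#' the LLOQ (0.05 mg/L at the default 0.1 mg/L limit); any BLQ observation
#' immediately following another BLQ observation from the same subject
#' carries no additional information and is removed.
#'
#' @param data A [pk_dataset()].
#' @param quiet Suppress the per-rule messages?
#' @return The cleaned `pk_dataset`.
#' @export
apply_blq_rule <- function(data, quiet = FALSE) {
  stopifnot(inherits(data, "pk_dataset"))
  lloq <- attr(data, "lloq")
  d <- as_tibble(data) |> mutate(.row = row_number())
  obs <- d |>
    filter(.data$evid == 0) |>
    group_by(.data$id) |>
    arrange(.data$time, .by_group = TRUE) |>
    mutate(.prev_blq = lag(.data$blq %in% 1, default = FALSE),
           .drop = (.data$blq %in% 1) & .data$.prev_blq) |>
    ungroup()
  drop_rows <- obs$.row[obs$.drop]
  impute_rows <- obs$.row[(obs$blq %in% 1) & !obs$.drop]
  if (!quiet && length(impute_rows) > 0) {
    inform(sprintf("BLQ rule: %d observation(s) imputed at %.3g mg/L.",
                   length(impute_rows), lloq / 2))
  }
  if (!quiet && length(drop_rows) > 0) {
    inform(sprintf("BLQ rule: %d consecutive BLQ observation(s) dropped.",
                   length(drop_rows)))
  }
  d$dv[d$.row %in% impute_rows] <- lloq / 2
  d$blq[d$.row %in% impute_rows] <- 0
  d <- d |> filter(!.data$.row %in% drop_rows) |> select(-".row")
  pk_dataset(d, lloq = lloq, uloq = attr(data, "uloq"))
}

#' Drop duplicated observation timepoints
#'
#' Observations collected at exactly the same time in the same subject add
#' no information; only the first is kept. Dose rows are never touched.
#'
#' @inheritParams apply_blq_rule
#' @return The cleaned `pk_dataset`.
#' @export
drop_duplicate_timepoints <- function(data, quiet = FALSE) {
  stopifnot(inherits(data, "pk_dataset"))
  d <- as_tibble(data)
  is_obs <- d$evid == 0
  key <- paste(d$id, signif(d$time, 12))
  dup <- is_obs & duplicated(ifelse(is_obs, key, paste0("dose-", seq_along(key))))
  if (!quiet && any(dup)) {
    inform(sprintf("Dropped %d duplicate observation timepoint(s).", sum(dup)))
  }
  pk_dataset(d[!dup, , drop = FALSE],
             lloq = attr(data, "lloq"), uloq = attr(data, "uloq"))
}

#' Apply all sample-handling rules
#'
#' Duplicate-timepoint removal followed by the BLQ imputation/pruning rule.
#' The combination is idempotent.
#'
#' @inheritParams apply_blq_rule
#' @return The cleaned `pk_dataset`.
#' @export
clean_dataset <- function(data, quiet = FALSE) {
  out <- data |>
    drop_duplicate_timepoints(quiet = quiet) |>
    apply_blq_rule(quiet = quiet)
  counts <- as_tibble(out) |>
    group_by(.data$id) |>
    summarise(n_dose = sum(.data$evid == 1), n_obs = sum(.data$evid == 0),
              .groups = "drop")
  if (any(counts$n_dose < 1 | counts$n_obs < 2)) {
    warn(sprintf("%d subject(s) have < 1 dose or < 2 observations after cleaning.",
                 sum(counts$n_dose < 1 | counts$n_obs < 2)))
  }
  out
}
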