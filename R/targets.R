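#' PK/PD target definitions
#'
#' A target is a time window plus a required time above MIC. The half-window
#' targets ("50% T>MIC") require strictly more than half the window above
#' the MIC (e.g. >12 h of the first 24 h). The full-window target over the
#' first 24 h ("100% T>MIC") is defined as at least 23.5 h above the MIC,
#' since the concentration is necessarily below the MIC for part of the
#' 0.5 h first infusion.
#'
#' @param window_start,window_end Window bounds, hours since first dose.
#' @param fraction Either 0.5 (half-window target, strict inequality) or 1
#'   (full-window target, `window - 0.5` h required, non-strict).
#' @return A `pkpd_target` object with fields `window`, `required_hours`,
#'   `strict` and `primary` (the 50% 0-24 h target is the primary endpoint).
#' @examples
#' pkpd_target(0, 24, 0.5)  # primary: > 12 h of the first 24 h
#' pkpd_target(0, 24, 1)    # >= 23.5 h of the first 24 h
#' pkpd_target(24, 48, 0.5) # > 12 h of the second day
#' @export
pkpd_target <- function(window_start = 0, window_end = 24, fraction = 0.5) {
  if (!fraction %in% c(0.5, 1)) abort("`fraction` must be 0.5 or 1.")
  if (window_end <= window_start) abort("Empty target window.")
  len <- window_end - window_start
  required <- if (fraction == 1) len - 0.5 else len / 2
  if (required > len) abort("Required hours exceed the window length.")
  structure(list(window = c(window_start, window_end),
                 required_hours = required,
                 strict = fraction == 0.5,
                 fraction = fraction,
                 primary = fraction == 0.5 && window_start == 0 &&
                   window_end == 24,
                 label = sprintf("%d%% T%g-%g>MIC", as.integer(100 * fraction),
                                 window_start, window_end)),
            class = "pkpd_target")
}

#' @export
print.pkpd_target <- function(x, ...) {
  cat(sprintf("<pkpd_target> %s (%s%g h of [%g, %g] h)%s\n", x$label,
              if (x$strict) ">" else ">=", x$required_hours,
              x$window[1], x$window[2],
              if (x$primary) " [primary]" else ""))
  invisible(x)
}

#' Does an individual profile attain a target?
#'
#' @param profile A [pk_profile()] covering the target window.
#' @param mic MIC (mg/L).
#' @param target A [pkpd_target()].
#' @return Logical.
#' @export
attains_target <- function(profile, mic, target = pkpd_target()) {
  stopifnot(inherits(target, "pkpd_target"))
  th <- pk_time_above_mic(profile, mic, target$window[1], target$window[2])
  if (target$strict) th > target$required_hours else th >= target$required_hours
}

#' Per-subject profiles for target-attainment work
#'
#' Combines individual parameters (empirical Bayes estimates or simulation
#' truths) with each subject's administered regimen from the dataset into
#' the table consumed by [pta_table()] and [exposure_summary()].
#'
#' @param data A [pk_dataset()] (dose rows supply each subject's regimen;
#'   `egfr_ckdepi` supplies the renal group).
#' @param params A tibble with columns `id`, `cl`, `v` (e.g. from
#'   [empirical_bayes()]); optional logical columns `misdosed` and
#'   `short_course` drive the exclusion bookkeeping.
#' @return A tibble with one row per subject: `id`, `group`, `cl`, `v`,
#'   `profile` (list-column of [pk_profile()]s) and any flag columns.
#' @export
subject_profiles <- function(data, params) {
  stopifnot(inherits(data, "pk_dataset"))
  if (!all(c("id", "cl", "v") %in% names(params))) {
    abort("`params` needs columns id, cl, v.")
  }
  d <- as_tibble(data)
  if (!"egfr_ckdepi" %in% names(d)) {
    abort("`data` needs an `egfr_ckdepi` column for renal grouping.")
  }
  subj <- d |>
    group_by(.data$id) |>
    summarise(egfr = first(.data$egfr_ckdepi), .groups = "drop") |>
    mutate(group = renal_group(.data$egfr))
  doses <- d |> filter(.data$evid == 1)
  keep_cols <- intersect(c("id", "cl", "v", "misdosed", "short_course"),
                         names(params))
  out <- subj |>
    left_join(params[keep_cols], by = "id") |>
    mutate(profile = purrr::map(.data$id, function(i) {
      dd <- doses |> filter(.data$id == i)
      pk_profile(params$cl[params$id == i], params$v[params$id == i],
                 regimen(dd$time, dd$amt, dd$dur))
    }))
  for (fl in c("misdosed", "short_course")) {
    if (!fl %in% names(out)) out[[fl]] <- FALSE
  }
  out
}

# Eligibility under the endpoint bookkeeping: the mis-dosed subject stays in
# for the primary endpoint but is excluded from all secondary endpoints; a
# subject treated only during the first 24 h cannot contribute to 24-48 h
# endpoints.
eligible_subjects <- function(subjects, target) {
  ok <- rep(TRUE, nrow(subjects))
  if (!isTRUE(target$primary)) ok <- ok & !subjects$misdosed
  if (target$window[1] >= 24) ok <- ok & !subjects$short_course
  ok
}

#' Probability of target attainment across a MIC grid
#'
#' Fraction of eligible subjects attaining the target at each MIC, per
#' renal-function group, with numerators and denominators. A PTA of at
#' least `adequacy` (default 90%) is flagged adequate.
#'
#' @param subjects Output of [subject_profiles()] (or a compatible tibble
#'   with `group` and a `profile` list-column).
#' @param mic MIC grid (mg/L); defaults to the EUCAST-style grid
#'   0.125-8 mg/L.
#' @param target A [pkpd_target()].
#' @param adequacy Minimal adequate PTA (fraction).
#' @return A tibble: `group`, `mic`, `n_attained`, `n_eligible`, `pta`,
#'   `adequate`.
#' @export
pta_table <- function(subjects, mic = c(0.125, 0.25, 0.5, 1, 2, 4, 8),
                      target = pkpd_target(), adequacy = 0.9) {
  stopifnot(inherits(target, "pkpd_target"))
  keep <- eligible_subjects(subjects, target)
  sub <- subjects[keep, , drop = FALSE]
  empty <- setdiff(levels(subjects$group), unique(as.character(sub$group)))
  if (length(empty) > 0) {
    warn(sprintf("No eligible subjects in group(s): %s; omitted.",
                 paste(empty, collapse = ", ")))
  }
  tidyr::expand_grid(group = unique(as.character(sub$group)), mic = mic) |>
    mutate(purrr::map2_dfr(.data$group, .data$mic, function(g, m) {
      pr <- sub$profile[as.character(sub$group) == g]
      att <- vapply(pr, attains_target, logical(1), mic = m, target = target)
      tibble(n_attained = sum(att), n_eligible = length(att))
    })) |>
    mutate(pta = .data$n_attained / .data$n_eligible,
           adequate = .data$pta >= adequacy) |>
    arrange(factor(.data$group, levels = c("adequate", "moderate", "severe")),
            .data$mic)
}

#' Drug-exposure summary with a rank test across renal groups
#'
#' Computes each eligible subject's analytic AUC over the requested windows,
#' summarises per renal group (median, IQR), and compares groups with the
#' Kruskal-Wallis rank-sum test.
#'
#' @inheritParams pta_table
#' @param windows List of `c(start, end)` windows in hours; defaults to the
#'   first and second day of treatment.
#' @return An `exposure_summary` object: `$auc` per subject and window,
#'   `$by_group` summaries, `$tests` with the Kruskal-Wallis statistic and
#'   p-value per window.
#' @export
exposure_summary <- function(subjects, windows = list(c(0, 24), c(24, 48))) {
  auc <- purrr::map_dfr(windows, function(w) {
    tgt <- pkpd_target(w[1], w[2], 1) # AUC is a secondary endpoint
    keep <- eligible_subjects(subjects, tgt)
    sub <- subjects[keep, , drop = FALSE]
    tibble(window = sprintf("%g-%g", w[1], w[2]),
           id = sub$id, group = sub$group,
           auc = vapply(sub$profile, pk_auc, numeric(1),
                        t_start = w[1], t_end = w[2]))
  })
  if (dplyr::n_distinct(auc$group) < 2) {
    abort("Exposure comparison needs at least two non-empty renal groups.")
  }
  by_group <- auc |>
    group_by(.data$window, .data$group) |>
    summarise(n = n(), median = median(.data$auc),
              q25 = unname(quantile(.data$auc, 0.25)),
              q75 = unname(quantile(.data$auc, 0.75)), .groups = "drop")
  tests <- auc |>
    group_by(.data$window) |>
    summarise({
      kt <- kruskal.test(auc, factor(group))
      tibble(statistic = unname(kt$statistic), df = unname(kt$parameter),
             p_value = kt$p.value)
    }, .groups = "drop")
  structure(list(auc = auc, by_group = by_group, tests = tests),
            class = "exposure_summary")
}

#' @export
print.exposure_summary <- function(x, ...) {
  cat("<exposure_summary>\n")
  print(as.data.frame(x$by_group |>
                        mutate(across(c("median", "q25", "q75"), ~ round(.x, 1)))),
        row.names = FALSE)
  print(as.data.frame(x$tests |> mutate(across(-"window", ~ signif(.x, 3)))),
        row.names = FALSE)
  invisible(x)
}

#' @export
tidy.exposure_summary <- function(x, ...) x$by_group
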