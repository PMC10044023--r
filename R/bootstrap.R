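#' Nonparametric bootstrap of the population model
#'
#' Subjects are resampled with replacement, stratified by renal-function
#' group so each replicate keeps the cohort's case mix, and the model is
#' refitted on every replicate. Percentile 95% confidence intervals and
#' replicate medians are reported; replicates whose fit fails to converge
#' are dropped and counted.
#'
#' @param data A cleaned [pk_dataset()] (needs an `egfr_ckdepi` column for
#'   the stratification; set `stratify = FALSE` to resample unstratified).
#' @param model A [popk_model()].
#' @param n_replicates Number of bootstrap replicates (1000 for a
#'   production run; tests use far fewer).
#' @param seed Integer seed (mandatory).
#' @param init,fixed Passed to [fit_popk()].
#' @param stratify Stratify resampling by renal group?
#' @return A `popk_bootstrap` object with `$summary` (per-parameter median
#'   and percentile 95% CI), `$replicates` (per-replicate estimates) and
#'   `$n_failed`.
#' @export
bootstrap_popk <- function(data, model = final_model(), n_replicates = 1000,
                           seed, init = pop_params(), fixed = list(),
                           stratify = TRUE) {
  stopifnot(inherits(data, "pk_dataset"))
  check_number(n_replicates, "n_replicates", lower = 1)
  check_number(seed, "seed")
  d <- as_tibble(data)
  ids <- sort(unique(d$id))
  strata <- if (stratify && "egfr_ckdepi" %in% names(d)) {
    sub <- d |> group_by(.data$id) |>
      summarise(egfr = first(.data$egfr_ckdepi), .groups = "drop")
    as.character(renal_group(sub$egfr[match(ids, sub$id)]))
  } else {
    rep("all", length(ids))
  }
  rows_by_id <- split(seq_len(nrow(d)), d$id)

  reps <- with_seed(seed, {
    purrr::map(seq_len(n_replicates), function(r) {
      pick <- unlist(lapply(unique(strata), function(s) {
        pool <- ids[strata == s]
        sample(pool, length(pool), replace = TRUE)
      }), use.names = FALSE)
      pieces <- lapply(seq_along(pick), function(k) {
        piece <- d[rows_by_id[[as.character(pick[k])]], , drop = FALSE]
        piece$id <- k
        piece
      })
      boot_d <- pk_dataset(bind_rows(pieces), lloq = attr(data, "lloq"),
                           uloq = attr(data, "uloq"))
      f <- try(fit_popk(boot_d, model, init = init, fixed = fixed,
                        compute_se = FALSE), silent = TRUE)
      if (inherits(f, "try-error") || !f$converged) return(NULL)
      f$estimates |> select("parameter", "estimate") |> mutate(replicate = r)
    })
  })
  ok <- !vapply(reps, is.null, logical(1))
  n_failed <- sum(!ok)
  if (n_failed > 0.2 * n_replicates) {
    warn(sprintf("Bootstrap: %d/%d replicates failed to converge.",
                 n_failed, n_replicates))
  }
  replicates <- bind_rows(reps[ok])
  summary <- replicates |>
    group_by(.data$parameter) |>
    summarise(median = median(.data$estimate),
              ci_lo = unname(quantile(.data$estimate, 0.025)),
              ci_hi = unname(quantile(.data$estimate, 0.975)),
              .groups = "drop")
  structure(list(summary = summary, replicates = replicates,
                 n_replicates = n_replicates, n_failed = n_failed),
            class = "popk_bootstrap")
}

#' @export
print.popk_bootstrap <- function(x, ...) {
  cat(sprintf("<popk_bootstrap> %d replicates (%d failed)\n",
              x$n_replicates, x$n_failed))
  s <- x$summary |> mutate(across(-"parameter", ~ signif(.x, 4)))
  print(as.data.frame(s), row.names = FALSE)
  invisible(x)
}

#' @export
tidy.popk_bootstrap <- function(x, ...) x$summary
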