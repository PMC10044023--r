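# Observation-level design extracted once: times, per-subject dose vectors,
# typical values, population and individual predictions.
obs_design <- function(data, fit) {
  br <- fit_bridge(fit)
  fd <- prepare_fit_data(data, br$model)
  tv <- typical_values(br$model, br$refs, fd$subj, br$params$theta_cl,
                       br$params$theta_v, br$params$coefs)
  list(fd = fd, tv = tv, params = br$params, model = br$model,
       refs = br$refs)
}

# Time after the most recent dose, per observation.
time_after_dose <- function(t_obs, t_dose) {
  vapply(t_obs, function(tt) {
    prev <- t_dose[t_dose <= tt]
    if (length(prev) == 0) tt else tt - max(prev)
  }, numeric(1))
}

#' Prediction-corrected visual predictive check
#'
#' Observations and model simulations are normalised by the bin-median
#' population prediction (prediction correction), then the observed
#' 5th/50th/95th percentile curves are compared with 95% confidence bands
#' obtained by simulating the design `n_sim` times from the model.
#' Binning is quantile-based on time after the most recent dose; bins with
#' fewer than `min_bin_n` observations are merged with their neighbour.
#'
#' @param data A cleaned [pk_dataset()].
#' @param fit A `popk_fit` or [pop_params()].
#' @param n_sim Number of simulated replicates for the bands (>= 500 for a
#'   production check).
#' @param seed Integer seed.
#' @param bins Target number of time-after-dose bins.
#' @param min_bin_n Minimal observations per bin before merging.
#' @return A `vpc_result`: `$bins` (one row per bin with observed
#'   percentiles and their simulated 95% bands), `$obs` (prediction-
#'   corrected observations), `$n_sim`.
#' @export
pc_vpc <- function(data, fit, n_sim = 1000, seed, bins = 6, min_bin_n = 5) {
  check_number(n_sim, "n_sim", lower = 1)
  check_number(seed, "seed")
  od <- obs_design(data, fit)
  fd <- od$fd
  p <- od$params
  n_subj <- length(fd$ids)

  obs <- purrr::map_dfr(seq_len(n_subj), function(i) {
    tibble(id = fd$ids[i], time = fd$t[[i]], dv = fd$y[[i]],
           pred = as.numeric(cpp_conc(fd$t[[i]], fd$dose_t[[i]],
                                      fd$dose_amt[[i]], fd$dose_dur[[i]],
                                      od$tv$cl[i], od$tv$v[i])),
           tad = time_after_dose(fd$t[[i]], fd$dose_t[[i]]))
  })
  if (any(obs$pred <= 0)) {
    abort("Population prediction is zero at an observation time; check dose records.")
  }

  edges <- unique(unname(quantile(obs$tad, probs = seq(0, 1, length.out = bins + 1))))
  if (length(edges) < 3) abort("Too few distinct time-after-dose values to bin.")
  edges[1] <- -Inf; edges[length(edges)] <- Inf
  bin_of <- function(tad) cut(tad, edges, labels = FALSE, include.lowest = TRUE)
  obs$bin <- bin_of(obs$tad)
  # merge sparse bins into their left neighbour
  repeat {
    counts <- table(factor(obs$bin, levels = sort(unique(obs$bin))))
    if (all(counts >= min_bin_n) || length(counts) <= 1) break
    small <- as.integer(names(counts)[which.min(counts)])
    ids <- sort(unique(obs$bin))
    tgt <- if (small == min(ids)) ids[which(ids == small) + 1] else
      ids[which(ids == small) - 1]
    obs$bin[obs$bin == small] <- tgt
  }
  if (length(unique(obs$bin)) < 1) {
    abort(sprintf("All bins empty after merging; edges were %s.",
                  paste(signif(edges, 3), collapse = ", ")))
  }
  obs <- obs |>
    group_by(.data$bin) |>
    mutate(pc_factor = median(.data$pred) / .data$pred,
           pc_dv = .data$dv * .data$pc_factor) |>
    ungroup()

  qs <- c(0.05, 0.5, 0.95)
  obs_pct <- obs |>
    group_by(.data$bin) |>
    summarise(n = n(), tad_mid = median(.data$tad),
              p05 = unname(quantile(.data$pc_dv, 0.05)),
              p50 = unname(quantile(.data$pc_dv, 0.50)),
              p95 = unname(quantile(.data$pc_dv, 0.95)), .groups = "drop")

  # per-observation prediction-correction factor, shared by data and sims
  pc_factor <- obs$pc_factor
  sim_pct <- with_seed(derive_seed(seed, "vpc"), {
    purrr::map_dfr(seq_len(n_sim), function(s) {
      eta1 <- rnorm(n_subj, 0, p$omega_cl)
      eta2 <- rnorm(n_subj, 0, p$omega_v)
      ysim <- unlist(lapply(seq_len(n_subj), function(i) {
        f <- cpp_conc(fd$t[[i]], fd$dose_t[[i]], fd$dose_amt[[i]],
                      fd$dose_dur[[i]], od$tv$cl[i] * exp(eta1[i]),
                      od$tv$v[i] * exp(eta2[i]))
        pmax(f * (1 + p$sigma_prop * rnorm(length(f))), 0)
      }), use.names = FALSE)
      tibble(sim = s, bin = obs$bin, pc = ysim * pc_factor) |>
        group_by(.data$sim, .data$bin) |>
        summarise(p05 = unname(quantile(.data$pc, 0.05)),
                  p50 = unname(quantile(.data$pc, 0.50)),
                  p95 = unname(quantile(.data$pc, 0.95)), .groups = "drop")
    })
  })

  bands <- sim_pct |>
    tidyr::pivot_longer(c("p05", "p50", "p95"), names_to = "pct") |>
    group_by(.data$bin, .data$pct) |>
    summarise(lo = unname(quantile(.data$value, 0.025)),
              hi = unname(quantile(.data$value, 0.975)), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "pct",
                       values_from = c("lo", "hi"))

  res <- obs_pct |> left_join(bands, by = "bin")
  structure(list(bins = res, obs = obs, n_sim = n_sim, seed = seed),
            class = "vpc_result")
}

#' @export
print.vpc_result <- function(x, ...) {
  cat(sprintf("<vpc_result> %d bins, %d simulations\n", nrow(x$bins), x$n_sim))
  print(as.data.frame(x$bins |> mutate(across(-c("bin", "n"), ~ signif(.x, 3)))),
        row.names = FALSE)
  invisible(x)
}

#' Goodness-of-fit tables
#'
#' Population (`pred`) and individual (`ipred`, empirical Bayes) predictions
#' for every observation, proportional-error-weighted residuals, and
#' log-scale bias / RMSE summaries.
#'
#' @inheritParams pc_vpc
#' @return A `gof_result`: `$obs` (per-observation table) and `$summary`.
#' @export
gof_tables <- function(data, fit) {
  od <- obs_design(data, fit)
  fd <- od$fd
  eb <- empirical_bayes(data, fit)
  p <- od$params
  obs <- purrr::map_dfr(seq_along(fd$ids), function(i) {
    tibble(
      id = fd$ids[i], time = fd$t[[i]], dv = fd$y[[i]],
      pred = as.numeric(cpp_conc(fd$t[[i]], fd$dose_t[[i]], fd$dose_amt[[i]],
                                 fd$dose_dur[[i]], od$tv$cl[i], od$tv$v[i])),
      ipred = as.numeric(cpp_conc(fd$t[[i]], fd$dose_t[[i]], fd$dose_amt[[i]],
                                  fd$dose_dur[[i]], eb$cl[i], eb$v[i]))
    )
  }) |>
    mutate(pwres = (.data$dv - .data$pred) / (p$sigma_prop * pmax(.data$pred, 1e-4)),
           iwres = (.data$dv - .data$ipred) / (p$sigma_prop * pmax(.data$ipred, 1e-4)))
  pos <- obs$dv > 0 & obs$ipred > 0
  summary <- tibble(
    n_obs = nrow(obs),
    bias_log_ipred = mean(log(obs$dv[pos]) - log(obs$ipred[pos])),
    rmse_log_ipred = sqrt(mean((log(obs$dv[pos]) - log(obs$ipred[pos]))^2)),
    cor_obs_ipred = stats::cor(obs$dv, obs$ipred),
    cor_obs_pred = stats::cor(obs$dv, obs$pred)
  )
  structure(list(obs = obs, summary = summary), class = "gof_result")
}

#' @export
print.gof_result <- function(x, ...) {
  cat("<gof_result>\n")
  print(as.data.frame(x$summary |> mutate(across(dplyr::everything(),
                                                 ~ signif(.x, 4)))),
        row.names = FALSE)
  invisible(x)
}
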