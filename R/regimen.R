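#' Dosing regimens
#'
#' A regimen is a tibble of intravenous infusion events with columns `time`
#' (h since first dose), `amount` (mg) and `duration` (h). Times must be
#' strictly increasing; overlapping infusions are legal (handled by
#' superposition) but flagged with a message.
#'
#' @param time Start times of each infusion (h); `time[1]` is usually 0.
#' @param amount Dose amounts (mg), recycled.
#' @param duration Infusion durations (h), recycled; defaults to the 0.5 h
#'   infusions used on the wards.
#' @param label Optional descriptor (e.g. `"2000 mg q8h"`).
#' @return A tibble of class `pk_regimen`.
#' @examples
#' regimen_q(interval = 8, amount = 2000, t_end = 48)
#' @export
regimen <- function(time, amount, duration = 0.5, label = NULL) {
  if (length(time) == 0L) abort("A regimen needs at least one dose.")
  out <- tibble(time = as.numeric(time), amount = as.numeric(amount),
                duration = as.numeric(duration))
  if (any(!is.finite(out$time)) || any(out$time < 0)) {
    abort("Dose times must be finite and non-negative.")
  }
  if (any(diff(out$time) <= 0)) abort("Dose times must be strictly increasing.")
  if (any(out$amount <= 0)) abort("Dose amounts must be positive.")
  if (any(out$duration <= 0)) abort("Infusion durations must be positive.")
  ends <- out$time + out$duration
  if (nrow(out) > 1L && any(ends[-nrow(out)] > out$time[-1L])) {
    inform("Overlapping infusions in regimen; superposition applies.")
  }
  attr(out, "label") <- label
  class(out) <- c("pk_regimen", class(out))
  out
}

#' @rdname regimen
#' @param interval Dosing interval (h).
#' @param t_end Doses are placed at `0, interval, 2*interval, ...` strictly
#'   before `t_end` (h).
#' @export
regimen_q <- function(interval, amount, t_end = 72, duration = 0.5,
                      label = sprintf("%g mg q%gh", amount, interval)) {
  check_number(interval, "interval", lower = 0, strict = TRUE)
  times <- seq(0, by = interval, length.out = ceiling(t_end / interval))
  regimen(times[times < t_end - 1e-9], amount, duration, label = label)
}

#' Guideline regimen for a renal-function group
#'
#' Ward dosing guidance for ceftazidime: 2000 mg q8h for adequate renal
#' function (eGFR >= 50), 1000 mg q12h for moderate impairment (eGFR 30-50)
#' and 1000 mg q24h for severe impairment (eGFR < 30).
#'
#' @param group `"adequate"`, `"moderate"` or `"severe"` (see [renal_group()]).
#' @inheritParams regimen_q
#' @return A `pk_regimen`.
#' @export
guideline_regimen <- function(group, t_end = 72, duration = 0.5) {
  group <- match.arg(group, c("adequate", "moderate", "severe"))
  switch(group,
    adequate = regimen_q(8, 2000, t_end, duration),
    moderate = regimen_q(12, 1000, t_end, duration),
    severe   = regimen_q(24, 1000, t_end, duration)
  )
}

#' Shift a regimen onto the morning nurse round
#'
#' On general wards, follow-up administrations are planned during routine
#' nurse rounds, so most patients receive an extra administration in the
#' first 24 h: nominal doses continue as prescribed until the next 08:00
#' round after treatment start, an extra administration is given at that
#' round, and subsequent doses follow the prescribed interval anchored on the
#' round. Unflagged regimens are returned unchanged.
#'
#' @param reg A `pk_regimen` with equally spaced doses.
#' @param shift Logical; apply the shift?
#' @param first_dose_clock Clock time (h, 0-24) of the first administration.
#' @return A `pk_regimen` over the same total span.
#' @export
apply_dose_shift <- function(reg, shift, first_dose_clock) {
  stopifnot(inherits(reg, "pk_regimen"))
  if (!isTRUE(shift)) return(reg)
  check_number(first_dose_clock, "first_dose_clock", lower = 0)
  interval <- if (nrow(reg) > 1L) reg$time[2] - reg$time[1] else 24
  t_max <- max(reg$time) + interval
  extra <- (8 - first_dose_clock) %% 24
  if (extra < 1e-9) extra <- 24
  nominal <- reg$time[reg$time < extra - 1e-9]
  anchored <- seq(extra, t_max - 1e-9, by = interval)
  times <- sort(unique(round(c(nominal, anchored), 9)))
  regimen(times, reg$amount[1], reg$duration[1],
          label = paste0(attr(reg, "label") %||% "regimen", " (shifted)"))
}
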