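# Independent numerical oracles. These deliberately avoid the package's
# closed-form machinery: concentrations come from an ODE solver integrated
# segment by segment, AUC from composite trapezoids on a fine grid, and
# time above MIC from a dense grid scan.

# ODE oracle: dC/dt = R(t)/V - ke * C, integrated with lsoda restarted at
# every infusion start/end (input rate is constant within a segment).
ode_concentration <- function(reg, cl, v, t_eval) {
  ke <- cl / v
  bp <- sort(unique(c(0, reg$time, reg$time + reg$duration, t_eval, max(t_eval))))
  bp <- bp[bp >= 0]
  rate_at <- function(tm) {
    act <- reg$time < tm & (reg$time + reg$duration) > tm
    sum(reg$amount[act] / reg$duration[act])
  }
  out_t <- c()
  out_c <- c()
  state <- 0
  for (i in seq_len(length(bp) - 1)) {
    a <- bp[i]; b <- bp[i + 1]
    if (b - a < 1e-12) next
    rate <- rate_at((a + b) / 2)
    inside <- t_eval[t_eval > a & t_eval <= b]
    times <- sort(unique(c(a, inside, b)))
    sol <- deSolve::lsoda(
      y = c(C = state), times = times,
      func = function(t, y, p) list(rate / v - ke * y[1]),
      rtol = 1e-12, atol = 1e-12
    )
    state <- unname(sol[nrow(sol), "C"])
    keep <- sol[, "time"] %in% inside
    out_t <- c(out_t, sol[keep, "time"])
    out_c <- c(out_c, sol[keep, "C"])
  }
  out_c[match(t_eval, out_t)]
}

# Quadrature oracle for AUC: composite trapezoid on a <=1e-3 h grid,
# aligned with the infusion starts/ends so no panel straddles a kink.
grid_auc <- function(profile, t_start, t_end, dt = 1e-3) {
  reg <- profile$reg
  bp <- sort(unique(c(t_start, t_end, reg$time, reg$time + reg$duration)))
  bp <- bp[bp >= t_start & bp <= t_end]
  total <- 0
  for (i in seq_len(length(bp) - 1)) {
    tt <- seq(bp[i], bp[i + 1], length.out = max(2, ceiling((bp[i + 1] - bp[i]) / dt)))
    cc <- pk_concentration(profile, tt)
    total <- total + sum((cc[-1] + cc[-length(cc)]) / 2 * diff(tt))
  }
  total
}

# Grid-scan oracle for time above MIC: sign changes located on a 1e-3 h
# grid, then refined by bisection on the (numerically evaluated)
# concentration function.
grid_time_above <- function(profile, mic, t_start, t_end, dt = 1e-3) {
  tt <- seq(t_start, t_end, by = dt)
  above <- pk_concentration(profile, tt) > mic
  flips <- which(diff(above) != 0)
  crossings <- vapply(flips, function(i) {
    lo <- tt[i]; hi <- tt[i + 1]
    for (it in 1:50) {
      mid <- (lo + hi) / 2
      if ((pk_concentration(profile, mid) > mic) == above[i]) lo <- mid else hi <- mid
    }
    (lo + hi) / 2
  }, numeric(1))
  edges <- c(t_start, crossings, t_end)
  state <- above[1]
  total <- 0
  for (i in seq_len(length(edges) - 1)) {
    if (state) total <- total + (edges[i + 1] - edges[i])
    state <- !state
  }
  total
}

# Random one-compartment instance: parameters and a multi-dose regimen.
random_instance <- function() {
  cl <- runif(1, 0.5, 12)
  v <- runif(1, 8, 50)
  interval <- sample(c(6, 8, 12, 24), 1)
  amount <- runif(1, 250, 3000)
  duration <- runif(1, 0.25, 2)
  n_dose <- sample(2:6, 1)
  reg <- regimen(seq(0, by = interval, length.out = n_dose), amount, duration)
  list(cl = cl, v = v, reg = reg,
       profile = pk_profile(cl, v, reg),
       horizon = interval * n_dose)
}

# A tiny hand-built event-record tibble (3 subjects) used by IO tests.
toy_dataset <- function() {
  rows <- dplyr::bind_rows(
    tibble::tibble(id = 1, time = c(0, 1, 8), evid = c(1, 0, 0),
                   amt = c(2000, NA, NA), dur = c(0.5, NA, NA),
                   dv = c(NA, 52, 18), blq = 0),
    tibble::tibble(id = 2, time = c(0, 12, 2, 6), evid = c(1, 1, 0, 0),
                   amt = c(1000, 1000, NA, NA), dur = c(0.5, 0.5, NA, NA),
                   dv = c(NA, NA, 30, 12), blq = 0),
    tibble::tibble(id = 3, time = c(0, 3, 20), evid = c(1, 0, 0),
                   amt = c(1000, NA, NA), dur = c(0.5, NA, NA),
                   dv = c(NA, 25, NA), blq = c(0, 0, 1))
  ) |> dplyr::arrange(id, time, dplyr::desc(evid))
  rows$egfr_ckdepi <- rep(c(95, 40, 20), times = c(3, 4, 3))
  rows$abx <- rep(c(1, 0, 0), times = c(3, 4, 3))
  pk_dataset(rows)
}

quiet_clean <- function(d) clean_dataset(d, quiet = TRUE)
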