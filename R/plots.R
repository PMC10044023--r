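# ggplot2 graphics for each result type. Figures are byproducts of the
# tabular results; every number shown is available from the tables.

#' Plot a prediction-corrected VPC
#'
#' Observed prediction-corrected percentile curves (5th/50th/95th) over the
#' simulated 95% confidence bands.
#'
#' @param x A `vpc_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_vpc <- function(x, ...) {
  stopifnot(inherits(x, "vpc_result"))
  b <- x$bins
  ggplot2::ggplot(b, ggplot2::aes(x = .data$tad_mid)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo_p05, ymax = .data$hi_p05),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo_p95, ymax = .data$hi_p95),
                         fill = "steelblue", alpha = 0.3) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo_p50, ymax = .data$hi_p50),
                         fill = "firebrick", alpha = 0.3) +
    ggplot2::geom_line(ggplot2::aes(y = .data$p50)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$p05), linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$p95), linetype = 2) +
    ggplot2::geom_point(data = x$obs,
                        ggplot2::aes(x = .data$tad, y = .data$pc_dv),
                        alpha = 0.4, size = 1) +
    ggplot2::labs(x = "Time after dose (h)",
                  y = "Prediction-corrected concentration (mg/L)",
                  title = "Prediction-corrected visual predictive check")
}

#' @export
autoplot.vpc_result <- function(object, ...) plot_vpc(object, ...)

#' Plot PTA across the MIC grid
#'
#' @param x A [pta_table()] result.
#' @param adequacy Reference line (fraction).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_pta <- function(x, adequacy = 0.9, ...) {
  ggplot2::ggplot(x, ggplot2::aes(x = factor(.data$mic), y = .data$pta,
                                  colour = .data$group,
                                  group = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = adequacy, linetype = 3) +
    ggplot2::scale_y_continuous(labels = function(v) paste0(100 * v, "%"),
                                limits = c(0, 1)) +
    ggplot2::labs(x = "MIC (mg/L)", y = "PTA", colour = "Renal function")
}

#' Boxplot of simulated time above MIC by renal group
#'
#' The distribution of per-subject-replicate hours above the MIC from a
#' Monte Carlo PTA simulation, with the 12 h half-window target line.
#'
#' @param x A `pta_simulation`.
#' @param mic Which MIC of the simulated grid to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_tmic <- function(x, mic = 8, ...) {
  stopifnot(inherits(x, "pta_simulation"))
  d <- x$tmic |> filter(.data$mic == !!mic)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$t_above)) +
    ggplot2::geom_boxplot(outlier.alpha = 0.2) +
    ggplot2::geom_hline(yintercept = x$target$required_hours,
                        colour = "darkorange", linetype = 3) +
    ggplot2::labs(x = "Renal function group",
                  y = sprintf("Time above MIC %g mg/L (h)", mic))
}

#' @export
autoplot.pta_simulation <- function(object, ...) plot_tmic(object, ...)

#' Boxplot of individual drug exposure by renal group
#'
#' @param x An `exposure_summary`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_exposure <- function(x, ...) {
  stopifnot(inherits(x, "exposure_summary"))
  ggplot2::ggplot(x$auc, ggplot2::aes(x = .data$group, y = .data$auc)) +
    ggplot2::geom_boxplot() +
    ggplot2::facet_wrap(~window, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Renal function group", y = "AUC (mg h/L)")
}

#' @export
autoplot.exposure_summary <- function(object, ...) plot_exposure(object, ...)

#' Goodness-of-fit panels
#'
#' Observed versus population and individual predictions on the identity
#' line, and weighted residuals against time.
#'
#' @param x A `gof_result`.
#' @param which `"pred"`, `"ipred"` or `"residuals"`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_gof <- function(x, which = c("ipred", "pred", "residuals"), ...) {
  stopifnot(inherits(x, "gof_result"))
  which <- match.arg(which)
  if (which == "residuals") {
    ggplot2::ggplot(x$obs, ggplot2::aes(x = .data$time, y = .data$iwres)) +
      ggplot2::geom_point(alpha = 0.5) +
      ggplot2::geom_hline(yintercept = 0, linetype = 2) +
      ggplot2::geom_smooth(method = "loess", formula = y ~ x, se = FALSE) +
      ggplot2::labs(x = "Time (h)", y = "Individual weighted residual")
  } else {
    xv <- if (which == "pred") "pred" else "ipred"
    ggplot2::ggplot(x$obs, ggplot2::aes(x = .data[[xv]], y = .data$dv)) +
      ggplot2::geom_point(alpha = 0.5) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
      ggplot2::labs(x = sprintf("%s prediction (mg/L)",
                                if (xv == "pred") "Population" else "Individual"),
                    y = "Observed (mg/L)")
  }
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
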