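# Optional ggplot2-based diagnostics; the tables behind them are the primary
# interface, so ggplot2 stays in Suggests.

.need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("ggplot2 is required for plotting", call. = FALSE)
}

#' Goodness-of-fit plot quartet
#'
#' DV vs PRED, DV vs IPRED, CWRES vs PRED and CWRES vs TAD for a fitted
#' model, the standard diagnostic quartet.
#'
#' @param fit a `pkpd_fit`.
#' @return a ggplot object (faceted quartet).
#' @export
gof_plot <- function(fit) {
  .need_ggplot()
  rt <- residual_table(fit)
  long <- rbind(
    data.frame(panel = "DV vs PRED", x = rt$PRED, y = rt$DV, ref = "identity"),
    data.frame(panel = "DV vs IPRED", x = rt$IPRED, y = rt$DV,
               ref = "identity"),
    data.frame(panel = "CWRES vs PRED", x = rt$PRED, y = rt$CWRES,
               ref = "zero"),
    data.frame(panel = "CWRES vs TAD", x = rt$TAD, y = rt$CWRES, ref = "zero"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(data = data.frame(panel = c("DV vs PRED",
                                                     "DV vs IPRED")),
                         ggplot2::aes(slope = 1, intercept = 0),
                         linetype = 2) +
    ggplot2::geom_hline(data = data.frame(panel = c("CWRES vs PRED",
                                                    "CWRES vs TAD")),
                        ggplot2::aes(yintercept = 0)) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::theme_bw()
}

#' pc-VPC plot
#'
#' Observed prediction-corrected percentiles (lines) against the simulated
#' 95% confidence bands for each percentile (ribbons), per time bin.
#'
#' @param vpc a `vpc_result` from [pc_vpc()].
#' @return a ggplot object.
#' @export
vpc_plot <- function(vpc) {
  .need_ggplot()
  b <- vpc$bins
  b$mid <- (b$tad_lo + b$tad_hi) / 2
  ggplot2::ggplot(b, ggplot2::aes(x = .data$mid)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p5_lo, ymax = .data$p5_hi),
                         alpha = 0.2) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p50_lo,
                                      ymax = .data$p50_hi), alpha = 0.2) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$p95_lo,
                                      ymax = .data$p95_hi), alpha = 0.2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p50), color = "red") +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p5), color = "red",
                       linetype = 2) +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_p95), color = "red",
                       linetype = 2) +
    ggplot2::labs(x = "time after dose (min)",
                  y = if (vpc$type == "pk")
                    "prediction-corrected concentration (ng/mL)"
                  else "prediction-corrected BIS") +
    ggplot2::theme_bw()
}

#' BIS time-course plot for a regimen grid
#'
#' Median BIS curves per maintenance rate with the target band shaded.
#'
#' @param summaries list of `regimen_summary` objects
#'   ([simulate_regimen_grid()]).
#' @param band target BIS band to shade.
#' @return a ggplot object.
#' @export
dosesim_plot <- function(summaries, band = c(40, 60)) {
  .need_ggplot()
  long <- do.call(rbind, lapply(summaries, function(s)
    data.frame(rate = sprintf("%.1f mg/kg/h", s$spec$maintenance_mgkg_h),
               time = s$times, bis = s$median)))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time, y = .data$bis,
                                     color = .data$rate)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf, ymin = band[1],
                      ymax = band[2], alpha = 0.15) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (min)", y = "median BIS", color = NULL) +
    ggplot2::theme_bw()
}
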