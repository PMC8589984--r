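# Plot helpers for the two standard audit figures. ggplot2 is suggested,
# not imported; both functions also return their underlying data so the
# CSVs can be emitted without plotting.

#' Hospital-level calibration scatter (observed vs predicted mortality)
#'
#' One point per hospital, colored by bed-size class, with the identity
#' diagonal for reference; points below the diagonal are hospitals where
#' the score overpredicts mortality.
#'
#' @param calib Output of \code{\link{hospital_calibration}}.
#' @return A ggplot object (requires \pkg{ggplot2}); the plotted data is
#'   in \code{calib} itself.
#' @export
plot_hospital_calibration <- function(calib) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting; the data frame passed in is ",
         "the underlying plot data")
  }
  ggplot2::ggplot(calib, ggplot2::aes(x = .data$observed_mortality,
                                      y = .data$predicted_mortality,
                                      color = .data$size_class)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         color = "red") +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = "Observed hospital mortality",
                  y = "Mean predicted mortality", color = "Hospital size") +
    ggplot2::theme_minimal()
}

#' Error rate against ARC bins
#'
#' Binned Type I and Type II error-rate curves against the ARC midpoint;
#' a well-behaved score shows both curves decreasing towards zero as
#' confidence grows.
#'
#' @param bins Output of \code{\link{error_rate_by_arc_bin}}.
#' @return A ggplot object (requires \pkg{ggplot2}).
#' @export
plot_arc_error_rates <- function(bins) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting; the data frame passed in is ",
         "the underlying plot data")
  }
  long <- rbind(
    data.frame(arc_mid = bins$arc_mid, rate = bins$type1_rate,
               error = "Type I (among predicted deaths)"),
    data.frame(arc_mid = bins$arc_mid, rate = bins$type2_rate,
               error = "Type II (among predicted survivors)"))
  ggplot2::ggplot(long[!is.na(long$rate), ],
                  ggplot2::aes(x = .data$arc_mid, y = .data$rate,
                               color = .data$error)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "ARC (bin midpoint)", y = "Error rate",
                  color = NULL) +
    ggplot2::theme_minimal()
}
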