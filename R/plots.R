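# ggplot2 displays for the result types.

#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_line geom_boxplot
#'   geom_abline labs theme_minimal
NULL

#' Plot the WSS distribution by ROI
#' @param object A `wss_field`.
#' @param ... Unused.
#' @return A ggplot: per-ROI boxplot of the vertex WSS values.
#' @export
autoplot.wss_field <- function(object, ...) {
  d <- tidy.wss_field(object)
  d <- d[d$valid & d$roi != "cap", ]
  ggplot(d, aes(x = .data$roi, y = .data$tau)) +
    geom_boxplot(outlier.size = 0.4) +
    labs(x = NULL, y = "WSS (dyne/cm²)",
         title = if (object$averaged) "Time-averaged WSS by ROI"
         else "Instantaneous WSS by ROI") +
    theme_minimal()
}

#' Plot run monitors (flow rate and conservation drifts)
#' @param object A `sim_result`.
#' @param ... Unused.
#' @return A ggplot of flow rate versus time.
#' @export
autoplot.sim_result <- function(object, ...) {
  m <- object$monitors
  ggplot(m, aes(x = .data$t * 1e3, y = .data$Q)) +
    geom_line() +
    labs(x = "t (ms)", y = expression(Q ~ (m^3 / s)),
         title = "Gate flow rate") +
    theme_minimal()
}

#' Plot phase separation against daughter WSS discrepancy
#' @param object A `psep_fit`.
#' @param ... Unused.
#' @return A ggplot with the regression line.
#' @export
autoplot.psep_fit <- function(object, ...) {
  p <- ggplot(object$data, aes(x = .data$dtau, y = .data$phase_sep)) +
    geom_point() +
    labs(x = expression(bar(tau)[RBC, D1] - bar(tau)[RBC, D2] ~
                          (dyne / cm^2)),
         y = expression(N[1]^"*" - Q[1]^"*")) +
    theme_minimal()
  if (!object$degenerate) {
    co <- stats::coef(object$fit)
    p <- p + geom_abline(intercept = co[1], slope = co[2],
                         linetype = "dashed", colour = "red")
  }
  p
}

#' Plot a cross-sectional velocity / hematocrit profile
#' @param profile Output of [cross_section_profiles()].
#' @return A ggplot of the chord profiles.
#' @export
plot_profile <- function(profile) {
  d <- profile$profile
  ggplot(d[d$in_lumen, ], aes(x = .data$s, y = .data$u)) +
    geom_line() +
    geom_point(aes(y = .data$ht * max(abs(d$u))), colour = "red", size = 0.6,
               na.rm = TRUE) +
    labs(x = "chord position (µm)", y = "axial velocity (m/s)",
         subtitle = "red: scaled hematocrit profile") +
    theme_minimal()
}
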