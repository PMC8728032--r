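# ggplot2 visualizations of the benchmark outputs.

#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point geom_hline
#'   geom_col labs facet_wrap theme_bw position_dodge
#' @export
ggplot2::autoplot

#' Plot power curves from a power study
#'
#' One curve per GSA method, power against the mean shift delta, faceted by
#' simulation setting; the dashed line marks the nominal level, so the
#' `delta = 0` points show the type-I error directly.
#'
#' @param object A `gsa_power_table` from [power_study()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gsa_power_table <- function(object, ...) {
  alpha <- object$alpha[1]
  ggplot(object, aes(x = .data$delta, y = .data$power, colour = .data$method)) +
    geom_hline(yintercept = alpha, linetype = "dashed", colour = "grey50") +
    geom_line() +
    geom_point(size = 1.4) +
    facet_wrap(~setting_id) +
    labs(
      x = expression(Delta), y = "Rejection proportion", colour = "GSA test",
      title = "Type-I error (at Δ = 0) and power of the GSA tests"
    ) +
    theme_bw()
}

#' @rdname autoplot.gsa_power_table
#' @export
plot_power_curves <- function(object, ...) autoplot.gsa_power_table(object, ...)

#' Plot rejection rates of the MVN tests
#'
#' Bar chart of the rejection rate Q per test with the nominal level marked;
#' rates near the line are consistent with multivariate normality, rates far
#' above it reject it.
#'
#' @param summaries A tibble with columns `method`, `Q` and `alpha`
#'   (e.g. rows from [q_rejection_rate()] or [mvn_calibration()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_rejection_rates <- function(summaries, ...) {
  ggplot(summaries, aes(x = .data$method, y = .data$Q)) +
    geom_col(fill = "steelblue") +
    geom_hline(aes(yintercept = .data$alpha), linetype = "dashed") +
    labs(
      x = "MVN test", y = "Rejection rate Q",
      title = "Gene-subset rejection rates"
    ) +
    theme_bw()
}

#' @rdname plot_rejection_rates
#' @method autoplot rejection_summary
#' @export
autoplot.rejection_summary <- function(object, ...) plot_rejection_rates(object, ...)

#' Plot the KL-divergence distances of the simulation settings
#'
#' @param object A `kl_table` from [kl_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot kl_table
#' @export
autoplot.kl_table <- function(object, ...) {
  ggplot(object, aes(x = .data$setting_id, y = .data$kl_sum)) +
    geom_col(fill = "indianred") +
    labs(
      x = "Simulation setting",
      y = "KL(case || Np) + KL(control || Np)",
      title = "Distance of each setting from the standard multivariate normal"
    ) +
    theme_bw()
}
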