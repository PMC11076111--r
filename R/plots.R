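#' Plot toy-grid estimator bias
#'
#' One panel per true effect and reliability, showing per-cell mean
#' estimates with +/- 1 s.d. ribbons for each method against the true
#' value (dashed line).
#'
#' @param object A [run_toy_grid()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.he_grid <- function(object, ...) {
  df <- dplyr::mutate(object,
                      cell = paste(selection, discretization, sep = "/"))
  ggplot2::ggplot(df, ggplot2::aes(x = cell, y = mean, colour = method)) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = b_HE), linetype = 2,
                        colour = "grey40") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = mean - sd,
                                          ymax = mean + sd),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::facet_grid(b_HE ~ rho, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "selection / discretization",
                  y = "estimated education effect (IQ points/year)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot bootstrap replicate distributions
#'
#' Histograms of the bootstrap replicates per parameter with the percentile
#' interval and point estimate marked.
#'
#' @param object A [bootstrap_estimates()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.he_boot <- function(object, ...) {
  reps <- tidyr::pivot_longer(object$replicates, dplyr::everything(),
                              names_to = "term", values_to = "estimate")
  marks <- tidy.he_boot(object)
  ggplot2::ggplot(reps, ggplot2::aes(x = estimate)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = estimate), colour = "red") +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = conf.low), linetype = 2) +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = conf.high), linetype = 2) +
    ggplot2::facet_wrap(~term, scales = "free") +
    ggplot2::labs(x = "bootstrap replicate estimate", y = "count") +
    ggplot2::theme_minimal()
}

#' Plot per-level fit diagnostics
#'
#' Mean true-minus-simulated adult IQ per education level across study
#' replicates, with +/- 1 s.d. bars. A near-zero profile indicates the
#' linear model fits; a positive bump at 2 years is the signature of a
#' front-loaded (nonlinear) education effect.
#'
#' @param study A [run_matched_study()] result.
#' @return A ggplot object.
#' @export
plot_diagnostics <- function(study) {
  stopifnot(inherits(study, "he_study"))
  s <- glance.he_study(study)
  ggplot2::ggplot(s, ggplot2::aes(x = factor(level), y = mean_difference)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey60") +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = mean_difference - sd_difference,
      ymax = mean_difference + sd_difference)) +
    ggplot2::labs(x = "years of higher education",
                  y = "observed - simulated mean adult IQ (points)") +
    ggplot2::theme_minimal()
}
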