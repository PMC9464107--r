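#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Coefficient plot for a PMQL fit
#'
#' Point estimates with approximate 95% intervals from the asymptotic
#' standard errors.
#'
#' @param object A `pmql_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pmql_fit <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      xmin = .data$estimate - 1.96 * .data$std.error,
      xmax = .data$estimate + 1.96 * .data$std.error)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "coefficient", y = NULL,
                  title = "PMQL regression coefficients (± 1.96 SE)")
}

#' Liu SMSE decomposition plot
#'
#' The spectral SMSE of the Liu estimator over a grid of `d`, split into its
#' increasing variance term and decreasing squared-bias term; the selected
#' `d` values of the requested selectors are marked.
#'
#' @param fit A converged `pmql_fit`.
#' @param d_grid Grid of Liu parameters.
#' @param selectors Liu selectors to mark.
#' @return A ggplot object.
#' @export
plot_liu_path <- function(fit, d_grid = seq(0, 1, by = 0.01),
                          selectors = c("D1", "D2", "D3", "D4", "D5")) {
  curve <- smse_curve_terms(fit, d_grid) |>
    tidyr::pivot_longer(c("term_variance", "term_bias2", "smse"),
                        names_to = "component", values_to = "value")
  marks <- tibble::tibble(
    selector = selectors,
    d = vapply(selectors, function(s) select_d(fit, s), numeric(1))
  )
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$d, y = .data$value,
                                      colour = .data$component)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(data = marks,
                        ggplot2::aes(xintercept = .data$d), linetype = 3) +
    ggplot2::labs(x = "Liu parameter d", y = "SMSE contribution",
                  title = "Liu SMSE: variance vs squared bias")
}

#' Plot simulation results
#'
#' Estimated SMSE against sample size per estimator, faceted by intercept
#' and correlation; log scale on the SMSE axis.
#'
#' @param results Long results tibble from [sim_factorial()].
#' @return A ggplot object.
#' @export
plot_sim_results <- function(results) {
  ggplot2::ggplot(results, ggplot2::aes(x = .data$n, y = .data$smse,
                                       colour = .data$estimator)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_y_log10() +
    ggplot2::facet_grid(rho ~ beta0, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "sample size", y = "estimated SMSE")
}

#' @importFrom rlang .data
NULL
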