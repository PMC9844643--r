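#' Forest-style plot of the joint genetic-by-metabolic hazard ratios
#'
#' @param joint A `joint_effect` from [joint_effect_table()].
#' @return A ggplot object.
#' @export
plot_joint_effect <- function(joint) {
  d <- joint$cells |>
    tidyr::separate_wider_delim("joint_category", ".",
                                names = c("genetic", "mets"))
  d$genetic <- factor(d$genetic, levels = c("low", "intermediate", "high"))
  d$mets <- factor(d$mets, levels = c("no_mets", "mets"),
                   labels = c("No MetS", "MetS"))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$genetic, y = .data$hr,
                                  fill = .data$mets)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      position = ggplot2::position_dodge(0.8), width = 0.2, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "Genetic risk category", y = "Hazard ratio",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Hazard-ratio gradient across metabolic component counts
#'
#' @param records Classified analysis tibble (see [classify_cohort()]).
#' @param ... Passed to [fit_cox()].
#' @return A ggplot object.
#' @export
plot_component_gradient <- function(records, ...) {
  records$.ncomp <- factor(pmin(records$n_components, 5L))
  f <- fit_cox(records, ".ncomp", ...)
  d <- tidy(f) |> filter(startsWith(.data$term, ".ncomp")) |>
    mutate(n_components = sub("^\\.ncomp", "", .data$term))
  d <- bind_rows(tibble(term = "ref", estimate = 0, std.error = 0, hr = 1,
                        conf.low = NA, conf.high = NA, p.value = NA,
                        n_components = levels(records$.ncomp)[1]), d)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$n_components, y = .data$hr)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      width = 0.15, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::labs(x = "Number of metabolic components", y = "Hazard ratio") +
    ggplot2::theme_minimal()
}

#' Standardized event rates by stratum
#'
#' @param rates Output of [standardized_event_rate()].
#' @return A ggplot object.
#' @export
plot_standardized_rates <- function(rates) {
  ggplot2::ggplot(rates, ggplot2::aes(x = factor(.data$stratum),
                                      y = .data$std_rate)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::labs(x = NULL, y = "Standardized rate (per 100,000 py)") +
    ggplot2::theme_minimal()
}

#' @rdname rcs_dose_response
#' @param object An `rcs_fit`.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.rcs_fit <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$score, y = .data$hr)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$conf.low,
                                      ymax = .data$conf.high), alpha = 0.2) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::geom_rug(data = tibble(k = object$knots),
                      ggplot2::aes(x = .data$k), inherit.aes = FALSE) +
    ggplot2::labs(x = "Standardized composite score", y = "Hazard ratio") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
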