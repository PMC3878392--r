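#' Plot a simulation study report
#'
#' Visualises one metric of a [run_study()] report against sample size, one
#' line per inference method. For `metric = "coverage"` the binomial
#' acceptance band and the nominal level are drawn.
#'
#' @param object A `medhaz_study` tibble.
#' @param metric One of `"coverage"`, `"mean_width"`, `"bias"`, `"mse"`.
#' @param estimand `"mediated"` or `"total"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot medhaz_study
#' @export
autoplot.medhaz_study <- function(object, metric = c("coverage", "mean_width",
                                                     "bias", "mse"),
                                  estimand = "mediated", ...) {
  metric <- match.arg(metric)
  df <- dplyr::filter(object, .data$estimand == !!estimand)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data[[metric]],
                                        colour = .data$method)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "sample size", y = metric, colour = "method") +
    ggplot2::theme_minimal()
  if (metric == "coverage") {
    cfg <- attr(object, "config")
    p <- p +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$band_low,
                                        ymax = .data$band_high),
                           fill = "grey70", alpha = 0.25, colour = NA) +
      ggplot2::geom_hline(yintercept = cfg$level, linetype = "dashed",
                          colour = "grey40")
  }
  if (metric == "bias") {
    p <- p + ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                                 colour = "grey40")
  }
  p
}

#' Plot a single mediation result
#'
#' Point estimates and Wald confidence intervals for the mediated, total and
#' direct effects.
#'
#' @param object A `mediation_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mediation_result
#' @export
autoplot.mediation_result <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$term != "relative_magnitude", ]
  zq <- qnorm(1 - (1 - object$level) / 2)
  df$conf.low[df$term == "direct"] <-
    df$estimate[df$term == "direct"] - zq * df$std.error[df$term == "direct"]
  df$conf.high[df$term == "direct"] <-
    df$estimate[df$term == "direct"] + zq * df$std.error[df$term == "direct"]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$conf.low,
                                         xmax = .data$conf.high),
                            height = 0.15) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "effect on the hazard", y = NULL) +
    ggplot2::theme_minimal()
}
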