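#' Funnel plot data as a ggplot
#'
#' Effect sizes against their standard errors (inverted axis), with the
#' pooled effect and the conventional pseudo-confidence funnel for visual
#' assessment of small-study asymmetry.
#'
#' @param funnel Funnel tibble from [eggers_test()] (`$funnel`).
#' @return A ggplot object.
#' @export
plot_funnel <- function(funnel) {
  pooled <- funnel$pooled_effect[1]
  se_max <- max(funnel$se) * 1.05
  band <- tibble(
    se = seq(0, se_max, length.out = 100),
    lo = pooled - 1.96 * seq(0, se_max, length.out = 100),
    hi = pooled + 1.96 * seq(0, se_max, length.out = 100)
  )
  ggplot2::ggplot(funnel, ggplot2::aes(x = .data$effect, y = .data$se)) +
    ggplot2::geom_line(data = band, ggplot2::aes(x = .data$lo, y = .data$se),
                       linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line(data = band, ggplot2::aes(x = .data$hi, y = .data$se),
                       linetype = "dashed", colour = "grey50") +
    ggplot2::geom_vline(xintercept = pooled, colour = "grey30") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::scale_y_reverse() +
    ggplot2::labs(x = "Log response ratio", y = "Standard error") +
    ggplot2::theme_minimal()
}

#' Distribution of model deviation ratios by response
#'
#' Violin-and-point display of MDRs on a log scale with the additive band
#' (0.5 to 2) marked — values above are synergistic, below antagonistic.
#'
#' @param mdr_results `results` table from [classify_interactions()].
#' @return A ggplot object.
#' @export
plot_mdr <- function(mdr_results) {
  dat <- filter(mdr_results, !.data$noise_excluded, is.finite(.data$mdr))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$response, y = .data$mdr,
                                    fill = .data$response)) +
    ggplot2::geom_violin(alpha = 0.4, colour = NA) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6, size = 1) +
    ggplot2::geom_hline(yintercept = c(0.5, 2), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = 1, linetype = "dotted") +
    ggplot2::scale_y_log10() +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = "Model deviation ratio (log scale)") +
    ggplot2::theme_minimal()
}

#' Predicted BEF relationship by number of stressors
#'
#' Plots the marginal-effect grid from [marginal_effects_grid()]: the
#' fixed-effect prediction of function LRR against diversity LRR, one line
#' per stressor number.
#'
#' @param grid Output of [marginal_effects_grid()].
#' @return A ggplot object.
#' @export
plot_bef_slopes <- function(grid) {
  cov_col <- setdiff(names(grid), c("ns", "predicted", "organism_group",
                                    "function_type", "stressor_combination"))[1]
  ggplot2::ggplot(grid, ggplot2::aes(x = .data[[cov_col]],
                                     y = .data$predicted,
                                     colour = factor(.data$ns))) +
    ggplot2::geom_line(linewidth = 0.8) +
    ggplot2::labs(x = "LRR diversity", y = "Predicted LRR function",
                  colour = "Stressors") +
    ggplot2::theme_minimal()
}

#' Autoplot methods for fitted result objects
#'
#' `bef_lmm` fits plot as the predicted BEF relationship by stressor
#' number; `bef_three_level` fits plot as a funnel.
#'
#' @param object A fitted `bef_lmm` or `bef_three_level` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
#' @rdname autoplot-befstress
autoplot.bef_lmm <- function(object, ...) {
  plot_bef_slopes(marginal_effects_grid(object))
}

#' @exportS3Method ggplot2::autoplot
#' @rdname autoplot-befstress
autoplot.bef_three_level <- function(object, ...) {
  funnel <- tibble(effect = object$fit$yi, se = sqrt(object$fit$vi),
                   pooled_effect = object$mu)
  plot_funnel(funnel)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
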