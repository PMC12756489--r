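# Minimal figure helpers for the forest-plot and trajectory exports.

#' Forest plot of an effects table
#'
#' @param effects Tibble from [effects_table()] or an `srf_strata` `$effects`.
#' @param significant_only Keep only significant predictors (default `TRUE`,
#'   the usual reporting convention).
#' @return A ggplot object.
#' @export
plot_effects <- function(effects, significant_only = TRUE) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("the 'ggplot2' package is required for plotting")
  }
  df <- as.data.frame(effects)
  if (significant_only) df <- df[df$significant, , drop = FALSE]
  if (!nrow(df)) stop("nothing to plot (no significant effects)")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$or, y = .data$category_id,
                                   colour = .data$stratum)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(xmin = .data$ci_low,
                                          xmax = .data$ci_high),
                             position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::labs(x = "Odds ratio (95% CI)", y = NULL, colour = "Stratum") +
    ggplot2::theme_minimal()
}

#' Trajectory plot of odds ratios across chat progress
#'
#' @param trajectories Tibble from [temporal_trajectories()].
#' @param categories Optional subset of category ids to show.
#' @return A ggplot object.
#' @export
plot_trajectories <- function(trajectories, categories = NULL) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("the 'ggplot2' package is required for plotting")
  }
  df <- as.data.frame(trajectories)
  if (!is.null(categories)) df <- df[df$category_id %in% categories, , drop = FALSE]
  if (!nrow(df)) stop("nothing to plot")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction, y = .data$or,
                                   colour = .data$category_id)) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~stratum) +
    ggplot2::labs(x = "Chat progress fraction", y = "Odds ratio",
                  colour = "Construct") +
    ggplot2::theme_minimal()
}
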