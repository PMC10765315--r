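#' Forest plot of a sensitivity battery
#'
#' Primary estimate on top, sensitivity analyses below, each with its 95%
#' interval; a dashed line marks the null.
#'
#' @param object A `sensitivity_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sensitivity_profile <- function(object, ...) {
  d <- tidy(object) |>
    mutate(label = factor(.data$label, levels = rev(unique(.data$label))),
           role = ifelse(.data$label == "primary", "primary", "sensitivity"))
  ggplot(d, aes(x = .data$theta, y = .data$label, colour = .data$role)) +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
    geom_point(aes(shape = .data$role), size = 2.5) +
    scale_colour_manual(values = c(primary = "#67001f", sensitivity = "#d6604d"),
                        guide = "none") +
    scale_shape_manual(values = c(primary = 15, sensitivity = 16), guide = "none") +
    labs(x = "causal estimate per SD of genetically predicted protein",
         y = NULL) +
    theme_minimal()
}

#' Forest plot of primary protein-outcome estimates
#'
#' One row per protein, faceted by outcome, FDR-significant associations
#' coloured by effect direction.
#'
#' @param primary Output tibble of [run_primary()].
#' @return A ggplot.
#' @export
plot_primary <- function(primary) {
  d <- primary |>
    mutate(class = dplyr::case_when(
      !.data$fdr_significant ~ "not significant",
      .data$theta > 0 ~ "risk-increasing",
      .default = "protective"
    ))
  ggplot(d, aes(x = .data$theta, y = .data$protein, colour = .data$class)) +
    geom_vline(xintercept = 0, linetype = "dashed", colour = "grey60") +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high), height = 0.2) +
    geom_point(size = 2) +
    facet_wrap(~outcome) +
    scale_colour_manual(values = c("not significant" = "grey50",
                                   "risk-increasing" = "#b2182b",
                                   "protective" = "#2166ac")) +
    labs(x = "log-odds per SD of genetically predicted protein", y = NULL,
         colour = NULL) +
    theme_minimal()
}
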