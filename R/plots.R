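#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Diverging effect plot for feature-family outcomes
#'
#' Bar chart of the mean-proportion (or abundance) differences between
#' life-history groups: negative effects are oligotroph-enriched,
#' positive copiotroph-enriched; non-significant features are greyed.
#'
#' @param outcomes Outcome tibble from [compare_profiles()].
#' @param top_n Show the `top_n` features with the largest absolute
#'   effects.
#' @return A ggplot object.
#' @export
plot_effect_directions <- function(outcomes, top_n = 25) {
  dat <- dplyr::slice_max(outcomes, abs(.data$effect), n = top_n)
  dat <- dplyr::mutate(
    dat,
    feature = stats::reorder(.data$feature, .data$effect)
  )
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$effect, y = .data$feature, fill = .data$direction)
  ) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = 0, linewidth = 0.3) +
    ggplot2::scale_fill_manual(values = c(
      oligotroph_enriched = "#1b7837",
      copiotroph_enriched = "#762a83",
      ns = "grey70"
    )) +
    ggplot2::labs(
      x = "effect (copiotroph mean - oligotroph mean)",
      y = NULL, fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' @rdname compare_traits
#' @param object A `trait_comparison` object.
#' @export
autoplot.trait_comparison <- function(object, ...) {
  plot_effect_directions(
    dplyr::rename(object$tests, feature = "trait"),
    top_n = nrow(object$tests)
  )
}

#' @rdname consistency_screen
#' @param object A `consistency_screen` object.
#' @export
autoplot.consistency_screen <- function(object, ...) {
  ggplot2::ggplot(
    object$summary,
    ggplot2::aes(x = .data$label, y = .data$n_cogs, fill = .data$label)
  ) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(
      oligotroph_consistent = "#1b7837",
      copiotroph_consistent = "#762a83",
      inconsistent_or_ns = "grey70"
    )) +
    ggplot2::labs(x = NULL, y = "COGs") +
    ggplot2::theme_minimal()
}

#' Classification volcano-style overview
#'
#' Mean relative-abundance difference against adjusted significance for
#' every tested ASV, coloured by label.
#'
#' @param classification Tibble from [classify_asvs()].
#' @return A ggplot object.
#' @export
plot_classification <- function(classification) {
  dat <- dplyr::mutate(
    classification,
    diff = .data$mean_carbon_rich - .data$mean_carbon_limited,
    neglog_p = -log10(pmax(.data$p_adj, 1e-300))
  )
  ggplot2::ggplot(
    dat,
    ggplot2::aes(x = .data$diff, y = .data$neglog_p, colour = .data$group_label)
  ) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(
      oligotroph_associated = "#1b7837",
      copiotroph_associated = "#762a83",
      ns = "grey70"
    )) +
    ggplot2::labs(
      x = "mean relative abundance difference (carbon rich - carbon limited)",
      y = expression(-log[10] ~ "adjusted p"),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
}
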