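#' Plot latent biomarker trajectories
#'
#' One line per individual per biomarker, faceted by biomarker when more
#' than one is simulated. Inactive (`NA`) cells leave gaps.
#'
#' @param biomarker_states long tibble (`i`, `t`, `b`, `value`) from a
#'   `serosurvey_sim` object.
#' @return a ggplot object.
#' @export
plot_biomarker_quantity <- function(biomarker_states) {
  p <- ggplot2::ggplot(
    biomarker_states,
    ggplot2::aes(x = .data$t, y = .data$value, group = .data$i)) +
    ggplot2::geom_line(alpha = 0.3, na.rm = TRUE) +
    ggplot2::labs(x = "time step", y = "latent biomarker quantity") +
    ggplot2::theme_minimal()
  if (length(unique(biomarker_states$b)) > 1) {
    p <- p + ggplot2::facet_wrap(~b, labeller = ggplot2::label_both)
  }
  p
}

#' Heatmap of immune histories or successful-exposure probabilities
#'
#' Individuals on the y axis, time on the x axis, one facet per exposure
#' type; `NA` tiles mark individuals not active at that time.
#'
#' @param long long tibble (`i`, `t`, `x`, `value`) — either
#'   `immune_histories` or `exposure_probabilities` from a
#'   `serosurvey_sim` object.
#' @return a ggplot object.
#' @export
plot_immune_histories <- function(long) {
  ggplot2::ggplot(
    long,
    ggplot2::aes(x = .data$t, y = .data$i, fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~x, labeller = ggplot2::label_both, ncol = 1) +
    ggplot2::labs(x = "time step", y = "individual") +
    ggplot2::theme_minimal()
}

#' @rdname plot_immune_histories
#' @export
plot_exposure_prob <- plot_immune_histories
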