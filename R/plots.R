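#' Plot the observation-weighted length distribution
#'
#' Bar chart of the percentage of chromosome observations falling in each
#' length bin of a catalogue summary.
#'
#' @param summary A `hap_summary` from [summarize_catalogue()].
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(summary) {
  stopifnot(inherits(summary, "hap_summary"))
  bins <- summary$bins
  bins$bin <- factor(bins$bin, levels = bins$bin)
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin, y = .data$percent)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "Haplotype length (nt)",
                  y = "Chromosome observations (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot haplotype length against observation count
#'
#' Scatter of the distinct haplotypes; the expected pattern is an inverse
#' relationship (long haplotypes are observed rarely).
#'
#' @param catalogue A `hap_catalogue`.
#' @return A ggplot object.
#' @export
plot_length_vs_observations <- function(catalogue) {
  ggplot2::ggplot(as_tibble(catalogue),
                  ggplot2::aes(x = .data$length, y = .data$observations)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(x = "Haplotype length (nt)", y = "Observations (n)") +
    ggplot2::theme_minimal()
}

#' @method autoplot hap_summary
#' @export
autoplot.hap_summary <- function(object, ...) {
  plot_length_distribution(object)
}

#' @method autoplot hap_catalogue
#' @export
autoplot.hap_catalogue <- function(object, ...) {
  plot_length_vs_observations(object)
}
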