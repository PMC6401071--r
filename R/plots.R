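#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_ribbon geom_col
#'   geom_hline labs facet_wrap theme_minimal
#' @export
ggplot2::autoplot

#' Plot a regional dysregulation profile
#'
#' Observed smoothed log2 fold-change curve over signed distance from the
#' anchor, with the label-randomization null envelope as a ribbon.
#'
#' @param object A `regional_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.regional_profile <- function(object, ...) {
  ggplot(object$curve, aes(x = .data$distance)) +
    geom_ribbon(aes(ymin = .data$lo, ymax = .data$hi), fill = "grey80") +
    geom_line(aes(y = .data$observed), colour = "firebrick", linewidth = 0.8) +
    geom_hline(yintercept = 0, linetype = "dashed", colour = "grey40") +
    labs(x = "Distance from anchor gene (bp)",
         y = "log2 fold change (fusion-positive vs negative)",
         title = "Regional expression around fusion anchor genes",
         subtitle = sprintf("Envelope: %d label randomizations",
                            object$n_rand)) +
    theme_minimal()
}

#' Plot a breakpoint region profile
#'
#' Proportions of fusion breakpoints in 5'UTR / CDS / 3'UTR by partner end,
#' optionally against the random-breakage expectation.
#'
#' @param profile A `region_profile` tibble.
#' @param expected Optional `regions` tibble from
#'   [expected_region_distribution()].
#' @return A ggplot object.
#' @export
plot_region_profile <- function(profile, expected = NULL) {
  profile$region <- factor(profile$region, levels = c("UTR5", "CDS", "UTR3"))
  p <- ggplot(profile, aes(x = .data$region, y = .data$proportion)) +
    geom_col(fill = "steelblue") +
    facet_wrap(~end) +
    labs(x = "cDNA region", y = "Proportion of breakpoints",
         title = "Breakpoint positions within fused transcripts") +
    theme_minimal()
  if (!is.null(expected)) {
    expected$region <- factor(expected$region, levels = levels(profile$region))
    p <- p + ggplot2::geom_point(data = expected,
                                 aes(x = .data$region, y = .data$proportion),
                                 colour = "firebrick", shape = 95, size = 10)
  }
  p
}

#' Plot the per-sample fusion burden distribution
#'
#' @param burden A `burden_summary`.
#' @return A ggplot object.
#' @export
plot_burden <- function(burden) {
  ggplot(burden$per_sample, aes(x = .data$n)) +
    ggplot2::geom_histogram(binwidth = 2, fill = "steelblue", colour = "white") +
    ggplot2::geom_vline(xintercept = burden$median, colour = "firebrick",
                        linetype = "dashed") +
    labs(x = "Fusion calls per sample", y = "Samples",
         title = sprintf("Fusion burden (median %.0f, IQR %.0f-%.0f)",
                         burden$median, burden$q25, burden$q75)) +
    theme_minimal()
}
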