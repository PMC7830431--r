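#' Plot per-class triage totals
#'
#' Bar chart of cumulative bases per triage class.
#'
#' @param object A `yt_triage` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot yt_triage
#' @export
autoplot.yt_triage <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$label, y = .data$bases / 1e6)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_contigs),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "Mb",
                  title = "Contig triage (label counts above bars)") +
    ggplot2::theme_minimal()
}

#' Plot relative copy-number estimates
#'
#' Bar chart of 2^-ddCt fold changes with standard-deviation whiskers,
#' reference gene highlighted.
#'
#' @param object A `ddct_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ddct_fit
#' @export
autoplot.ddct_fit <- function(object, ...) {
  est <- mutate(object$estimates,
                role = ifelse(.data$gene == object$reference,
                              "reference", "target"))
  ggplot2::ggplot(est, ggplot2::aes(x = stats::reorder(.data$gene,
                                                       -.data$fold_change),
                                    y = .data$fold_change,
                                    fill = .data$role)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$fold_change - .data$sd,
                                        ymax = .data$fold_change + .data$sd),
                           width = 0.25, na.rm = TRUE) +
    ggplot2::scale_fill_manual(values = c(reference = "grey60",
                                          target = "steelblue"),
                               guide = "none") +
    ggplot2::labs(x = NULL, y = "fold change vs reference",
                  title = "Relative copy number (2^-ddCt)") +
    ggplot2::theme_minimal()
}

#' Plot a windowed X-homology profile
#'
#' Coverage per window along the contig; an optional boundary call is drawn
#' as a vertical line.
#'
#' @param profile Profile tibble from [homology_profile()].
#' @param pab Optional PAB call tibble from [detect_boundary()].
#' @return A ggplot object.
#' @export
plot_homology_profile <- function(profile, pab = NULL) {
  p <- ggplot2::ggplot(profile,
                       ggplot2::aes(x = (.data$start + .data$end) / 2e3,
                                    y = .data$covered_fraction)) +
    ggplot2::geom_line(color = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "position (kb)", y = "X coverage",
                  title = "Windowed X-homology profile") +
    ggplot2::theme_minimal()
  if (!is.null(pab) && nrow(pab)) {
    p <- p + ggplot2::geom_vline(xintercept = pab$boundary / 1e3,
                                 linetype = "dashed", color = "firebrick")
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
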