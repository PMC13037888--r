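#' Manhattan plot of an association scan
#'
#' @param scan An `assoc_scan` (or its [tidy.assoc_scan()] tibble).
#' @param alpha_line,fdr_line Draw the Bonferroni (dashed) and FDR (dotted)
#'   thresholds carried by the scan.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(scan, alpha_line = TRUE, fdr_line = TRUE) {
  res <- if (inherits(scan, "assoc_scan")) scan$results else scan
  p <- ggplot2::ggplot(res, ggplot2::aes(x = .data$pos,
                                         y = -log10(.data$p_wald),
                                         colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.9, show.legend = FALSE) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom),
                        scales = "free_x", space = "free_x") +
    ggplot2::labs(x = "position (bp)",
                  y = expression(-log[10](italic(p)))) +
    ggplot2::theme_minimal()
  if (inherits(scan, "assoc_scan")) {
    if (alpha_line) {
      p <- p + ggplot2::geom_hline(yintercept = -log10(scan$bonferroni_threshold),
                                   linetype = "dashed")
    }
    if (fdr_line && !is.na(scan$fdr_threshold)) {
      p <- p + ggplot2::geom_hline(yintercept = -log10(scan$fdr_threshold),
                                   linetype = "dotted")
    }
  }
  p
}

#' Quantile-quantile plot of scan p-values
#'
#' Observed versus expected -log10 p under the uniform null, annotated with
#' the genomic-control lambda.
#'
#' @param scan An `assoc_scan`.
#' @return A ggplot object.
#' @export
plot_qq <- function(scan) {
  pv <- sort(scan$results$p_wald[!is.na(scan$results$p_wald)])
  df <- tibble::tibble(
    expected = -log10(stats::ppoints(length(pv))),
    observed = -log10(pv)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$expected, .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::annotate("text", x = 0.5, y = max(df$observed),
                      hjust = 0, vjust = 1,
                      label = sprintf("lambda[GC] == %.3f", scan$lambda_gc),
                      parse = TRUE) +
    ggplot2::labs(x = expression(expected ~ -log[10](italic(p))),
                  y = expression(observed ~ -log[10](italic(p)))) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_manhattan Autoplot method; `type` selects
#'   `"manhattan"` or `"qq"`.
#' @param object An `assoc_scan`.
#' @param type Plot flavour.
#' @param ... Ignored.
#' @export
autoplot.assoc_scan <- function(object, type = c("manhattan", "qq"), ...) {
  switch(match.arg(type), manhattan = plot_manhattan(object),
         qq = plot_qq(object))
}

#' Depth profile plot with window means
#'
#' @param object A [depth_profile()].
#' @param window,step Window parameters for the overlaid means.
#' @param ... Ignored.
#' @return A ggplot object.
#' @export
autoplot.depth_profile <- function(object, window = 800, step = 400, ...) {
  w <- window_depth(object, window = window, step = step)
  ggplot2::ggplot(w, ggplot2::aes(x = (.data$start + .data$end) / 2,
                                  y = .data$depth)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "position (bp)", y = "mean window depth (reads/bp)") +
    ggplot2::theme_minimal()
}
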