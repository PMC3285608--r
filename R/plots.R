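# ggplot2 views of the main result types.

#' Plot windowed variation-frequency tracks
#'
#' One track per sample and variant type along each chromosome, with the
#' high/low region thresholds drawn as horizontal lines.
#'
#' @param object A `window_scan` object.
#' @param high_fold,low_fold Threshold multipliers to draw (default 4, 20).
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.window_scan <- function(object, high_fold = 4, low_fold = 20,
                                 ...) {
  arg <- compute_arg(object)
  w <- object$windows |>
    filter(!.data$masked) |>
    left_join(arg, by = "group") |>
    mutate(mid = (.data$start + .data$end) / 2)
  ggplot2::ggplot(w, ggplot2::aes(x = .data$mid / 1e3, y = .data$freq,
                                  colour = .data$sample_id)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = high_fold * .data$arg),
                        data = arg, linetype = "dashed") +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$arg / low_fold),
                        data = arg, linetype = "dotted") +
    ggplot2::facet_grid(group ~ chrom, scales = "free") +
    ggplot2::labs(x = "position (kb)", y = "variation frequency (per base)",
                  colour = "sample") +
    ggplot2::theme_minimal()
}

#' Plot comparison class counts
#'
#' Stacked bars of shared / different / unique / partial / ineligible locus
#' counts per variant type.
#'
#' @param object A `variant_comparison` object.
#' @param ... Unused.
#' @return A ggplot.
#' @exportS3Method ggplot2::autoplot
autoplot.variant_comparison <- function(object, ...) {
  df <- object$loci |>
    mutate(group = variant_group(.data$type)) |>
    count(.data$group, .data$class)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$n,
                                   fill = .data$class)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "variant type", y = "loci", fill = "class") +
    ggplot2::theme_minimal()
}

#' Plot a SNP neighbor-joining tree
#'
#' @param tree A `phylo` object (e.g. from [snp_tree()]).
#' @param ... Passed to [ape::plot.phylo()].
#' @return The tree, invisibly (draws on the active device).
#' @export
plot_snp_tree <- function(tree, ...) {
  ape::plot.phylo(ape::unroot(tree), type = "unrooted", ...)
  invisible(tree)
}
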