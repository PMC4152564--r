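#' Manhattan plot of an association scan
#'
#' Plots -log10 raw p-values against genomic position, faceted by trait,
#' with the per-class FDR significance status mapped to colour.
#'
#' @param results A [assoc_scan()] tibble, annotated with `chrom` and `pos`
#'   (or `start`) columns for each variant.
#' @param p_col Which p-value to plot (default `"p_raw"`).
#' @return A ggplot object.
#' @export
plot_manhattan <- function(results, p_col = "p_raw") {
  pos_col <- if ("pos" %in% names(results)) "pos" else "start"
  if (!pos_col %in% names(results) || !"chrom" %in% names(results))
    stop_bad_arg("results must carry 'chrom' and 'pos' (or 'start') columns")
  ggplot2::ggplot(results,
                  ggplot2::aes(x = .data[[pos_col]],
                               y = -log10(.data[[p_col]]),
                               colour = .data$significant)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(trait ~ chrom, scales = "free_x", space = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey40",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "position (bp)", y = expression(-log[10](p)),
                  colour = "significant") +
    ggplot2::theme_minimal()
}

#' Plot pairwise D' for a marker window
#'
#' Heat-map of the pairwise D' matrix of a window, the package's equivalent
#' of an LD triangle view.
#'
#' @param geno Dosage matrix, markers x samples.
#' @param map_window Marker map rows for the window.
#' @return A ggplot object.
#' @export
plot_ld_heatmap <- function(geno, map_window) {
  m <- nrow(geno)
  pairs <- tidyr::expand_grid(i = seq_len(m), j = seq_len(m)) |>
    filter(.data$j > .data$i)
  pairs$Dprime <- purrr::map2_dbl(pairs$i, pairs$j, function(i, j)
    ld_pair(geno[i, ], geno[j, ])$Dprime)
  ggplot2::ggplot(pairs, ggplot2::aes(x = .data$i, y = .data$j,
                                      fill = .data$Dprime)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick",
                                 limits = c(0, 1), na.value = "grey80") +
    ggplot2::labs(x = "marker", y = "marker", fill = "D'") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_manhattan autoplot method for scan objects.
#' @param object A `cnv_scan` object.
#' @param ... Passed to [plot_manhattan()].
#' @exportS3Method ggplot2::autoplot
autoplot.cnv_scan <- function(object, ...) plot_manhattan(object, ...)

#' Tidy an association scan
#'
#' @param x A `cnv_scan` object.
#' @param ... Unused.
#' @return The per-(variant, trait) results as a plain tibble.
#' @exportS3Method generics::tidy
tidy.cnv_scan <- function(x, ...) {
  out <- tibble::as_tibble(x)
  class(out) <- setdiff(class(out), "cnv_scan")
  out
}

#' One-row summary of an association scan
#'
#' @param x A `cnv_scan` object.
#' @param ... Unused.
#' @return Tibble with the number of variants, traits, tests, significant
#'   hits, the variant class and its significance threshold.
#' @exportS3Method generics::glance
glance.cnv_scan <- function(x, ...) {
  vc <- attr(x, "variant_class") %||% "cnv"
  tibble::tibble(
    n_variants = dplyr::n_distinct(x$variant_id),
    n_traits = dplyr::n_distinct(x$trait),
    n_tests = nrow(x),
    n_significant = sum(x$significant, na.rm = TRUE),
    variant_class = vc,
    fdr_threshold = if (vc == "cnv") 0.05 else 1e-8,
    n_perm = attr(x, "n_perm") %||% 0)
}
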