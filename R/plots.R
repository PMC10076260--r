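#' Plot an LD-decay curve
#'
#' @param x an `ld_decay` tibble (or a named list of them for several
#'   groups).
#' @return a ggplot: mean r-squared against distance, with the 0.2 line.
#' @export
plot_ld_decay <- function(x) {
  if (inherits(x, "ld_decay")) x <- list(all = x)
  df <- purrr::imap_dfr(x, function(d, g)
    dplyr::mutate(tibble::as_tibble(d), group = g))
  ggplot2::ggplot(df[!is.na(df$mean_r2), ],
                  ggplot2::aes(x = .data$dist_mid / 1e6, y = .data$mean_r2,
                               colour = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0.2, linetype = "dashed") +
    ggplot2::labs(x = "distance (Mb)", y = expression(mean ~ r^2),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of a selection scan
#'
#' @param per_snp the `per_snp` tibble of [scale_and_extract()].
#' @param regions optional region tibble drawn as shaded bands.
#' @return a ggplot of -log10 p per SNP along the genome.
#' @export
plot_scan <- function(per_snp, regions = NULL) {
  df <- per_snp |>
    dplyr::mutate(logp = -log10(pmax(.data$p_a, 1e-300)))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1e6, y = .data$logp)) +
    ggplot2::geom_point(size = 0.4, alpha = 0.6) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p))) +
    ggplot2::theme_minimal()
  if (!is.null(regions) && nrow(regions)) {
    p <- p + ggplot2::geom_rect(
      data = regions,
      ggplot2::aes(xmin = .data$start / 1e6, xmax = .data$end / 1e6,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "tomato", alpha = 0.2)
  }
  p
}

#' Karyotype-style plot of per-haplotype ancestry windows
#'
#' @param window_map an `ancestry_windows` tibble.
#' @param haplotypes optional subset of haplotype ids to draw.
#' @return a ggplot tiling windows coloured by donor-group label.
#' @export
plot_ancestry_windows <- function(window_map, haplotypes = NULL) {
  df <- tibble::as_tibble(window_map)
  if (!is.null(haplotypes)) df <- df[df$hap_id %in% haplotypes, ]
  ggplot2::ggplot(df, ggplot2::aes(xmin = .data$start / 1e6,
                                   xmax = .data$end / 1e6,
                                   ymin = 0, ymax = 1,
                                   fill = .data$label)) +
    ggplot2::geom_rect() +
    ggplot2::facet_grid(hap_id ~ chrom, scales = "free_x", switch = "y") +
    ggplot2::labs(x = "position (Mb)", y = NULL, fill = "donor group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank(),
                   strip.text.y.left = ggplot2::element_text(angle = 0))
}

#' @method autoplot ld_decay
#' @export
autoplot.ld_decay <- function(object, ...) plot_ld_decay(object)

#' @method autoplot ancestry_windows
#' @export
autoplot.ancestry_windows <- function(object, ...)
  plot_ancestry_windows(object)

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
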