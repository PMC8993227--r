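#' MA plot of a differential-expression result
#'
#' Mean normalized count (log10 x) against log2 fold change, significant
#' units highlighted.
#'
#' @param object An `apa_de` object.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot apa_de
#' @export
autoplot.apa_de <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$base_mean, y = .data$log2fc,
                                  colour = .data$is_de)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6, na.rm = TRUE) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey50",
                                            `TRUE` = "firebrick"),
                                 na.value = "grey80",
                                 name = paste0("padj < ", object$alpha)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "mean normalized count", y = "log2 fold change (ST / CK)")
}

#' Quadrant plot of 3' UTR length change against expression change
#'
#' Direction statistic r (x) against gene-level log2 fold change (y),
#' coloured by length-change class.
#'
#' @param object A `utr_dynamics` object.
#' @param de_gene A gene-level `apa_de` object (or tidy tibble).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot utr_dynamics
#' @export
autoplot.utr_dynamics <- function(object, de_gene = NULL, ...) {
  d <- tidy(object)
  if (!is.null(de_gene)) {
    de <- if (inherits(de_gene, "apa_de")) tidy(de_gene) else de_gene
    d <- d |> left_join(de |> select(gene_id = "unit_id", "log2fc"),
                        by = "gene_id")
  } else {
    d$log2fc <- NA_real_
  }
  ggplot2::ggplot(d, ggplot2::aes(x = .data$r, y = .data$log2fc,
                                  colour = .data$class)) +
    ggplot2::geom_point(size = 0.8, alpha = 0.7, na.rm = TRUE) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(values = c(LENGTHEN = "#1b9e77",
                                            SHORTEN = "#d95f02",
                                            UNCHANGED = "grey70")) +
    ggplot2::labs(x = "3' UTR length-change direction r",
                  y = "gene log2 fold change (ST / CK)")
}

#' Bar chart of the PAC region distribution
#'
#' @param pacs Assigned PAC tibble.
#' @return A ggplot.
#' @export
plot_region_distribution <- function(pacs) {
  d <- region_distribution(pacs)
  d$region <- factor(d$region, levels = d$region)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$region, y = .data$fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "fraction of PACs")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
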