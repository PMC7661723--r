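#' Bar chart of state-category counts
#'
#' @param object A `reprog_state` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.reprog_state <- function(object, ...) {
  counts <- dplyr::count(tibble::as_tibble(object), .data$category,
                         .drop = FALSE)
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$category, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), vjust = -0.3,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "TF genes",
                  title = "Cell-state classification of the TF repertoire") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Stacked verdict bars per response direction
#'
#' @param object A `reprog_legit` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.reprog_legit <- function(object, ...) {
  tb <- dplyr::count(tibble::as_tibble(object), .data$direction,
                     .data$verdict)
  ggplot2::ggplot(tb, ggplot2::aes(x = .data$direction, y = .data$n,
                                   fill = .data$verdict)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(legitimate = "#2a9d8f",
                                          wrong = "#e76f51",
                                          unwanted = "#e9c46a")) +
    ggplot2::labs(x = "response direction", y = "TF genes",
                  title = "Reprogramming legitimacy of responsive TFs") +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression result
#'
#' @param object A `reprog_de` tibble.
#' @param fold,q Thresholds drawn as guides.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.reprog_de <- function(object, fold = 2, q = 0.01, ...) {
  tb <- tibble::as_tibble(object)
  tb$sig <- !is.na(tb$q) & tb$q < q & abs(tb$log2fc) >= log2(fold)
  ggplot2::ggplot(tb[!is.na(tb$p), ],
                  ggplot2::aes(x = .data$log2fc, y = -log10(.data$p),
                               colour = .data$sig)) +
    ggplot2::geom_point(size = 0.6, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(`TRUE` = "firebrick",
                                            `FALSE` = "grey60"),
                                 guide = "none") +
    ggplot2::geom_vline(xintercept = c(-log2(fold), log2(fold)),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  title = attr(object, "contrast")$label) +
    ggplot2::theme_minimal()
}

#' Heat map of log2-normalized counts for a gene set
#'
#' Rows (genes) are ordered by average-linkage hierarchical clustering on
#' correlation distance, the ordering conventionally used to judge whether
#' induced samples cluster with the target or the start state.
#'
#' @param norm A [normalize_counts()] result.
#' @param genes Genes to draw.
#' @param pseudocount Offset for the log2 transform (default 1).
#' @param cluster_rows Order genes by clustering (default TRUE when > 2
#'   genes).
#' @return A ggplot.
#' @export
plot_log2_heatmap <- function(norm, genes, pseudocount = 1,
                              cluster_rows = length(genes) > 2) {
  stopifnot(inherits(norm, "reprog_norm"))
  missing <- setdiff(genes, rownames(norm$values))
  if (length(missing) > 0) {
    stop("genes absent from matrix: ",
         paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
  }
  lg <- log2_matrix(norm, pseudocount)[genes, , drop = FALSE]
  if (cluster_rows) {
    cc <- stats::cor(t(lg))
    cc[!is.finite(cc)] <- 0
    hc <- stats::hclust(stats::as.dist(1 - cc), method = "average")
    lg <- lg[hc$order, , drop = FALSE]
  }
  long <- tidyr::pivot_longer(
    tibble::as_tibble(cbind(tibble::tibble(gene = rownames(lg)),
                            tibble::as_tibble(lg))),
    -"gene", names_to = "sample", values_to = "log2")
  long$gene <- factor(long$gene, levels = rev(rownames(lg)))
  long$sample <- factor(long$sample, levels = norm$design$sample)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample, y = .data$gene,
                                     fill = .data$log2)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "log2(norm+pc)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6),
                   axis.text.y = ggplot2::element_text(size = 6))
}
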