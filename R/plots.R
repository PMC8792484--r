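#' Triangle plot of hybrid index versus interspecific heterozygosity
#'
#' The classic hybrid-zone diagnostic: hybrid index on x, interspecific
#' heterozygosity on y. Pure parentals sit at (0, 0) and (1, 0), F1s at
#' the (0.5, 1) apex, F2s near (0.5, 0.5), and successive backcrosses slide
#' down the triangle's edges toward the recurrent parent. Reference points
#' for F1, F2 and first-generation backcrosses are drawn by default.
#'
#' @param report A `hybrid_report` tibble (see [hybrid_report()]).
#' @param reference Draw the F1/F2/Bx expectation points (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_triangle <- function(report, reference = TRUE) {
  p <- ggplot2::ggplot(report, ggplot2::aes(x = .data$hi, y = .data$het)) +
    ggplot2::geom_segment(
      data = tibble::tibble(x = c(0, 1), xend = c(0.5, 0.5),
                            y = c(0, 0), yend = c(1, 1)),
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend),
      linetype = "dashed", colour = "grey60", inherit.aes = FALSE) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$generation_class),
                        size = 2.5, alpha = 0.85) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Hybrid index", y = "Interspecific heterozygosity",
                  colour = "Class") +
    ggplot2::theme_minimal()
  if (reference) {
    ref <- tibble::tibble(
      hi = c(0.5, 0.5, 0.25, 0.75), het = c(1, 0.5, 0.5, 0.5),
      label = c("F1", "F2", "Bx1", "Bx1"))
    p <- p +
      ggplot2::geom_point(data = ref, shape = 4, size = 3,
                          colour = "black",
                          ggplot2::aes(x = .data$hi, y = .data$het)) +
      ggplot2::geom_text(data = ref, vjust = -0.8, size = 3,
                         ggplot2::aes(x = .data$hi, y = .data$het,
                                      label = .data$label))
  }
  p
}

#' @rdname plot_triangle
#' @param object A `hybrid_report`.
#' @param ... Unused.
#' @importFrom ggplot2 autoplot
#' @method autoplot hybrid_report
#' @export
autoplot.hybrid_report <- function(object, ...) plot_triangle(object, ...)

#' Structure-style stacked ancestry bars
#'
#' One bar per individual, split into the ancestry proportion toward each
#' parental gene pool, ordered by Q.
#'
#' @param q_table An `ancestry_table` (see [supervised_q()]).
#' @return A ggplot object.
#' @export
plot_ancestry_bars <- function(q_table) {
  long <- tidyr::pivot_longer(
    dplyr::mutate(q_table, species1 = 1 - .data$q, species2 = .data$q,
                  id = stats::reorder(.data$id, .data$q)),
    c("species1", "species2"), names_to = "pool", values_to = "proportion")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$id, y = .data$proportion,
                                     fill = .data$pool)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = NULL, y = "Ancestry proportion", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, size = 6))
}

#' @method autoplot ancestry_table
#' @export
autoplot.ancestry_table <- function(object, ...) plot_ancestry_bars(object)

#' BIC curve for cluster-number selection
#'
#' @param model A `cluster_model` from [choose_k_bic()].
#' @return A ggplot object.
#' @export
plot_bic <- function(model) {
  ggplot2::ggplot(model$bic, ggplot2::aes(x = .data$k, y = .data$bic)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = model$k, linetype = "dotted") +
    ggplot2::labs(x = "K", y = "BIC") +
    ggplot2::theme_minimal()
}

#' Folded site-frequency-spectrum bar plot
#'
#' @param sfs An `sfs_vector` from [folded_sfs()].
#' @return A ggplot object.
#' @export
plot_sfs <- function(sfs) {
  ggplot2::ggplot(tibble::as_tibble(sfs),
                  ggplot2::aes(x = .data$bin, y = .data$count)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "Minor-allele count", y = "Number of SNPs") +
    ggplot2::theme_minimal()
}

#' @method autoplot sfs_vector
#' @export
autoplot.sfs_vector <- function(object, ...) plot_sfs(object)
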