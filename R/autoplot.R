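# ggplot2 views of fitted objects.

#' Rank-size plot of OTUs from a clustering
#'
#' Bars give OTU sizes in rank order — the quickest visual check that a
#' run produced a sensible OTU size distribution rather than shattering
#' into singletons or collapsing into one blob.
#'
#' @param object An `otu_clustering` from [opticlust()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.otu_clustering <- function(object, ...) {
  sizes <- dplyr::count(object$partition, .data$otu, name = "size")
  sizes <- dplyr::arrange(sizes, dplyr::desc(.data$size))
  sizes$rank <- seq_len(nrow(sizes))
  ggplot2::ggplot(sizes, ggplot2::aes(x = .data$rank, y = .data$size)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "OTU rank", y = "sequences",
      title = sprintf("%d OTUs, MCC %.4f",
                      nrow(sizes), object$mcc)) +
    ggplot2::theme_minimal()
}

#' OTU composition plot for a reference fit
#'
#' OTU sizes in rank order, split by how many reference and query
#' sequences each OTU holds; discarded queries (closed mode) appear as an
#' "unmapped" bar.
#'
#' @param object An `otu_fit` from [optifit()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.otu_fit <- function(object, ...) {
  d <- tidy(object)
  d$otu[is.na(d$otu)] <- "(unmapped)"
  comp <- dplyr::count(d, .data$otu, .data$role, name = "n")
  sizes <- dplyr::count(d, .data$otu, name = "size")
  sizes <- dplyr::arrange(sizes, .data$otu == "(unmapped)",
                          dplyr::desc(.data$size))
  comp$otu <- factor(comp$otu, levels = sizes$otu)
  ggplot2::ggplot(comp, ggplot2::aes(x = as.integer(.data$otu),
                                     y = .data$n, fill = .data$role)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = "OTU rank", y = "sequences", fill = NULL,
      title = sprintf("%s-reference fit: MCC %.4f, %.1f%% of queries mapped",
                      object$mode, object$mcc,
                      100 * object$fraction_mapped)) +
    ggplot2::theme_minimal()
}
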