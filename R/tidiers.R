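# broom-style accessors for fitted objects.

#' Tidy OTU assignments of a clustering
#'
#' @param x An `otu_clustering` from [opticlust()].
#' @param ... Unused.
#' @return A tibble with one row per sequence: `id`, `otu`.
#' @export
tidy.otu_clustering <- function(x, ...) {
  as_tibble(x$partition)
}

#' One-row summary of a clustering
#'
#' @param x An `otu_clustering` from [opticlust()].
#' @param ... Unused.
#' @return A one-row tibble: confusion counts, `mcc`, `sensitivity`,
#'   `specificity`, `n_seqs`, `n_otus`, `iterations`, `converged`,
#'   `seed`.
#' @export
glance.otu_clustering <- function(x, ...) {
  dplyr::bind_cols(
    confusion_stats(x$counts),
    tibble(n_seqs = nrow(x$partition),
           n_otus = length(unique(x$partition$otu)),
           iterations = x$iterations, converged = x$converged,
           seed = if (is.null(x$seed)) NA_integer_ else x$seed))
}

#' Tidy OTU assignments of a reference fit
#'
#' @param x An `otu_fit` from [optifit()].
#' @param ... Unused.
#' @return A tibble `id`, `otu`, `role` (`"reference"`/`"query"`); in
#'   closed mode discarded queries appear with `otu = NA`.
#' @export
tidy.otu_fit <- function(x, ...) {
  out <- as_tibble(x$partition)
  qids <- x$query_ids %||% character()
  out$role <- ifelse(out$id %in% qids, "query", "reference")
  if (length(x$unmapped_ids) > 0) {
    out <- dplyr::bind_rows(
      out, tibble(id = x$unmapped_ids, otu = NA_character_, role = "query"))
  }
  out
}

#' One-row summary of a reference fit
#'
#' @param x An `otu_fit` from [optifit()].
#' @param ... Unused.
#' @return A one-row tibble: confusion counts and MCC plus
#'   `fraction_mapped`, `n_unmapped`, `mode`, `iterations`, `converged`,
#'   `seed`.
#' @export
glance.otu_fit <- function(x, ...) {
  dplyr::bind_cols(
    confusion_stats(x$counts),
    tibble(fraction_mapped = x$fraction_mapped,
           n_unmapped = length(x$unmapped_ids),
           mode = x$mode,
           n_otus = length(unique(x$partition$otu)),
           iterations = x$iterations, converged = x$converged,
           seed = if (is.null(x$seed)) NA_integer_ else x$seed))
}

#' @export
tidy.split_assignment <- function(x, ...) {
  tibble(id = x$id, role = x$role)
}

#' @export
glance.split_assignment <- function(x, ...) {
  tibble(strategy = attr(x, "strategy"),
         fraction = attr(x, "fraction"),
         n_reference = sum(x$role == "reference"),
         n_query = sum(x$role == "query"),
         seed = attr(x, "seed") %||% NA_integer_)
}
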