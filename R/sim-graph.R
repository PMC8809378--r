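#' Build a sparse similarity graph from pairwise distances
#'
#' Two sequences are connected iff their recorded pairwise distance is
#' less than or equal to `threshold` (the boundary distance counts as
#' "within"; this matches the cutoff semantics of the mothur ecosystem
#' and is exercised explicitly in the tests).  Pairs absent from `dist`
#' are treated as above-threshold, so the full sequence universe must be
#' supplied (or carried by `dist` via its `ids` attribute, as
#' [read_dist_matrix()] does) — edgeless sequences never appear in a
#' sparse distance file.
#'
#' Duplicate or reciprocal listings of the same pair collapse to one
#' edge.  Conflicting duplicates that straddle the threshold (one listing
#' within, another beyond) are ambiguous input and raise an error.
#' Self-pairs are ignored, with a warning when their distance is within
#' the threshold.
#'
#' @param dist A data frame with columns `id1`, `id2`, `distance`
#'   (e.g. from [read_dist_columns()] or [read_dist_matrix()]).
#' @param ids Character vector: the sequence universe, in a fixed order.
#'   Defaults to `attr(dist, "ids")` when present.
#' @param threshold Maximum distance (fraction in `[0, 1]`) for a pair to
#'   count as similar; 0.03 is the conventional OTU definition.
#' @return An object of class `sim_graph`: the universe (`ids`), the
#'   `threshold`, an edge matrix, and an adjacency list.
#' @export
#' @examples
#' d <- tibble::tibble(id1 = c("a", "a"), id2 = c("b", "c"),
#'                     distance = c(0.02, 0.05))
#' g <- sim_graph(d, ids = c("a", "b", "c", "d"), threshold = 0.03)
#' g
sim_graph <- function(dist, ids = attr(dist, "ids"), threshold = 0.03) {
  stopifnot(is.data.frame(dist),
            all(c("id1", "id2", "distance") %in% names(dist)))
  if (is.null(ids)) {
    abort(paste("`ids` (the sequence universe) is required: sparse column",
                "input cannot name sequences that have no close neighbor"))
  }
  assert_ids(ids)
  if (length(threshold) != 1 || is.na(threshold) ||
      threshold < 0 || threshold > 1) {
    abort("`threshold` must be a single distance fraction in [0, 1]")
  }
  i1 <- match(dist$id1, ids)
  i2 <- match(dist$id2, ids)
  if (anyNA(i1) || anyNA(i2)) {
    missing_id <- unique(c(dist$id1[is.na(i1)], dist$id2[is.na(i2)]))
    abort(sprintf("distance file names sequences not in the universe: %s",
                  paste(head(missing_id, 5), collapse = ", ")))
  }
  d <- dist$distance
  self <- i1 == i2
  if (any(self)) {
    if (any(d[self] <= threshold)) {
      warn(sprintf("ignoring %d self-pair(s) in distance input",
                   sum(self & d <= threshold)))
    }
    i1 <- i1[!self]; i2 <- i2[!self]; d <- d[!self]
  }
  # canonical unordered pair key
  lo <- pmin(i1, i2)
  hi <- pmax(i1, i2)
  key <- (lo - 1) * length(ids) + hi
  within <- d <= threshold
  if (anyDuplicated(key)) {
    conflict <- tapply(within, key, function(w) any(w) && !all(w))
    if (any(conflict)) {
      k <- as.numeric(names(conflict)[conflict][1])
      a <- ids[(k - 1) %/% length(ids) + 1]
      b <- ids[(k - 1) %% length(ids) + 1]
      abort(sprintf(
        "pair %s-%s listed with distances on both sides of threshold %g",
        a, b, threshold))
    }
    first <- !duplicated(key)
    lo <- lo[first]; hi <- hi[first]; within <- within[first]
  }
  edges <- cbind(lo[within], hi[within])
  new_sim_graph(ids, edges, threshold)
}

# edges: 2-column integer matrix of universe indices, i < j, unique;
# stored sorted so equal graphs are bit-identical however they were read
new_sim_graph <- function(ids, edges, threshold) {
  n <- length(ids)
  edges <- matrix(as.integer(edges), ncol = 2)
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  adj <- vector("list", n)
  nb <- split(c(edges[, 2], edges[, 1]), c(edges[, 1], edges[, 2]))
  adj[as.integer(names(nb))] <- lapply(nb, function(x) sort(as.integer(x)))
  empty <- vapply(adj, is.null, logical(1))
  adj[empty] <- list(integer())
  structure(
    list(ids = ids, threshold = threshold, edges = edges, adj = adj),
    class = "sim_graph")
}

#' @export
print.sim_graph <- function(x, ...) {
  n <- length(x$ids)
  cat(sprintf(
    "<sim_graph> %d sequences, %d edges (of %s pairs) at threshold %g\n",
    n, nrow(x$edges), format(total_pairs(n), big.mark = ","), x$threshold))
  invisible(x)
}

#' Edges and degrees of a similarity graph
#'
#' @param graph A [sim_graph()].
#' @return `graph_edges()`: a tibble with columns `id1`, `id2`, one row
#'   per within-threshold pair.  `graph_degree()`: a tibble with columns
#'   `id`, `degree`.
#' @export
graph_edges <- function(graph) {
  stopifnot(inherits(graph, "sim_graph"))
  tibble(id1 = graph$ids[graph$edges[, 1]],
         id2 = graph$ids[graph$edges[, 2]])
}

#' @rdname graph_edges
#' @export
graph_degree <- function(graph) {
  stopifnot(inherits(graph, "sim_graph"))
  tibble(id = graph$ids, degree = lengths(graph$adj))
}

#' Induced subgraph over a subset of the universe
#'
#' Keeps the given sequences (in their original universe order) and every
#' edge with both endpoints among them — e.g. the reference-only graph
#' that the de novo step of a split-fit pipeline clusters.
#'
#' @param graph A [sim_graph()].
#' @param ids Sequence ids to keep.
#' @return A [sim_graph()] over `ids`.
#' @export
subgraph <- function(graph, ids) {
  stopifnot(inherits(graph, "sim_graph"))
  idx <- match(ids, graph$ids)
  if (anyNA(idx)) {
    abort(sprintf("ids not in the graph universe: %s",
                  paste(head(ids[is.na(idx)], 5), collapse = ", ")))
  }
  subgraph_by_index(graph, idx)
}

# induced subgraph on a subset of ids (indices into graph$ids)
subgraph_by_index <- function(graph, idx) {
  idx <- sort(idx)
  keep <- graph$edges[, 1] %in% idx & graph$edges[, 2] %in% idx
  e <- graph$edges[keep, , drop = FALSE]
  remap <- integer(length(graph$ids))
  remap[idx] <- seq_along(idx)
  new_sim_graph(graph$ids[idx], cbind(remap[e[, 1]], remap[e[, 2]]),
                graph$threshold)
}
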