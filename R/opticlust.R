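#' De novo OTU clustering by iterative MCC maximization
#'
#' Implements the OptiClust strategy: every sequence starts as its own
#' singleton OTU; each sweep visits the sequences in a freshly shuffled
#' order and moves each one to whichever option — stay, join an OTU
#' containing at least one of its within-threshold neighbors, or split
#' off as a new singleton — gives the best Matthews correlation
#' coefficient over all sequence pairs.  Ties (MCC within 1e-12) are
#' broken uniformly at random.  Sweeps continue until the MCC improves by
#' no more than `tolerance` (default 0.0001) or `max_iterations`
#' (default 100) sweeps have run.
#'
#' @param graph A [sim_graph()].
#' @param seed Integer seed driving sequence visit order and tie breaks;
#'   the same seed and input always reproduce the same partition.  `NULL`
#'   uses (and advances) the current RNG state.
#' @param tolerance Minimum sweep-over-sweep MCC gain to keep iterating.
#' @param max_iterations Sweep cap.
#' @return An object of class `otu_clustering` with elements `partition`
#'   (tibble `id`, `otu`), `counts` (tp/fp/fn/tn), `mcc`, `iterations`,
#'   `converged` and `seed`.  Use [tidy()] / [glance()] / [autoplot()].
#' @export
#' @examples
#' d <- tibble::tibble(id1 = c("a", "b", "d"), id2 = c("b", "c", "e"),
#'                     distance = 0.01)
#' g <- sim_graph(d, ids = c("a", "b", "c", "d", "e"), threshold = 0.03)
#' res <- opticlust(g, seed = 8)
#' glance(res)
opticlust <- function(graph, seed = 1, tolerance = 1e-4,
                      max_iterations = 100) {
  stopifnot(inherits(graph, "sim_graph"))
  check_config(tolerance, max_iterations)
  run <- with_optional_seed(seed, opticlust_core(graph, tolerance,
                                                 max_iterations))
  partition <- memb_to_partition(graph$ids, run$memb)
  counts <- confusion_matrix(graph, partition)
  # cross-check the incremental bookkeeping against a full recount
  if (any(unlist(counts) != run$conf)) {
    abort("internal error: incremental confusion counts drifted")
  }
  structure(
    list(partition = partition, counts = counts, mcc = mcc(counts),
         iterations = run$iterations, converged = run$converged,
         mcc_trace = run$mcc_trace, seed = seed,
         threshold = graph$threshold),
    class = "otu_clustering")
}

# core without seeding: starts all-singletons, consumes the current RNG
opticlust_core <- function(graph, tolerance, max_iterations) {
  n <- length(graph$ids)
  memb <- seq_len(n)
  sizes <- rep(1, n)
  conf <- c(0, 0, nrow(graph$edges), total_pairs(n) - nrow(graph$edges))
  run_sweeps(graph, memb, sizes, conf, movable = seq_len(n),
             tolerance = tolerance, max_iterations = max_iterations)
}

check_config <- function(tolerance, max_iterations) {
  if (length(tolerance) != 1 || is.na(tolerance) || tolerance < 0) {
    abort("`tolerance` must be a single non-negative number")
  }
  if (length(max_iterations) != 1 || is.na(max_iterations) ||
      max_iterations < 1) {
    abort("`max_iterations` must be at least 1")
  }
  invisible(TRUE)
}

with_optional_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(seed, code)
}

# label OTUs canonically: descending size, ties by lexicographically
# smallest member
memb_to_partition <- function(ids, memb, labels = NULL) {
  members <- split(ids, memb)
  if (is.null(labels)) {
    members <- lapply(members, sort)
    size <- lengths(members)
    first <- vapply(members, `[[`, character(1), 1)
    members <- members[order(-size, first)]
    labels <- paste0("otu_", seq_along(members))
  } else {
    labels <- labels[as.integer(names(members))]
  }
  out <- tibble(
    id = unlist(members, use.names = FALSE),
    otu = rep(labels, lengths(members)))
  out[match(ids, out$id), ]
}

#' Candidate OTUs for relocating one sequence
#'
#' The options the optimizer scores when it considers moving `seq_id`:
#' every OTU holding at least one of its within-threshold neighbors, its
#' current OTU ("stay"), and a brand-new singleton (represented as `NA`).
#' Moving to any other OTU can only add false positives, so it is never
#' scored.
#'
#' @inheritParams confusion_matrix
#' @param seq_id Sequence identifier.
#' @return Character vector of OTU labels (current OTU included) with one
#'   trailing `NA` for the new-singleton option.
#' @export
candidate_otus <- function(graph, partition, seq_id) {
  stopifnot(inherits(graph, "sim_graph"))
  validate_partition(partition, graph$ids)
  i <- match(seq_id, graph$ids)
  if (is.na(i)) abort(sprintf("unknown sequence id '%s'", seq_id))
  nb_ids <- graph$ids[graph$adj[[i]]]
  cur <- partition$otu[match(seq_id, partition$id)]
  c(union(cur, unique(partition$otu[match(nb_ids, partition$id)])),
    NA_character_)
}

#' @export
print.otu_clustering <- function(x, ...) {
  cat(sprintf(
    "<otu_clustering> %d sequences in %d OTUs | MCC %.4f | %d sweep(s)%s\n",
    nrow(x$partition), length(unique(x$partition$otu)), x$mcc,
    x$iterations, if (x$converged) "" else " (not converged)"))
  invisible(x)
}
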