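#' Fit query sequences to existing reference OTUs (OptiFit)
#'
#' Reference assignments are frozen; every query starts as its own
#' singleton and each sweep (shuffled order, seeded RNG) moves each query
#' to whichever reference OTU holding at least one of its
#' within-threshold neighbors — or back to its own singleton — maximizes
#' the MCC over *all* pairs in the combined universe (reference-reference
#' pairs included).  A query whose best option is to remain a singleton
#' stays unassigned.  Convergence follows [opticlust()] (`tolerance`,
#' `max_iterations`).
#'
#' Afterwards, `mode` decides the fate of unassigned queries:
#' * `"closed"` — they are discarded; the reported partition, confusion
#'   and MCC cover the retained universe (references plus mapped
#'   queries), and every surviving OTU label is a reference label.
#' * `"open"` — they are clustered de novo with the OptiClust strategy on
#'   their induced subgraph (same RNG stream) and added as new OTUs; the
#'   report covers the full combined universe.
#'
#' @param graph A [sim_graph()] whose universe is exactly the reference
#'   ids plus `query_ids`.
#' @param ref_partition Tibble `id`, `otu`: the existing OTU assignments
#'   of the reference sequences.
#' @param query_ids Character vector of query sequence ids (disjoint from
#'   the reference ids).
#' @param mode `"open"` or `"closed"`.
#' @inheritParams opticlust
#' @return An object of class `otu_fit`: `partition`, `counts`, `mcc`,
#'   `fraction_mapped` (mapped queries / all queries; 1 in open mode),
#'   `unmapped_ids`, `iterations` (fit-phase sweeps), `converged`,
#'   `mode`, `seed`, plus `fit_mcc` (MCC over the full combined universe
#'   at the end of the fit phase, before mode-specific finalization) and
#'   `mcc_trace` (MCC after every accepted fit-phase move, for
#'   monotonicity checks).  When there are no queries at all the reference
#'   partition is returned as-is with `fraction_mapped = 1` and
#'   `no_queries = TRUE`.
#' @export
optifit <- function(graph, ref_partition, query_ids,
                    mode = c("open", "closed"), seed = 1,
                    tolerance = 1e-4, max_iterations = 100) {
  stopifnot(inherits(graph, "sim_graph"))
  mode <- match.arg(mode)
  check_config(tolerance, max_iterations)
  validate_partition(ref_partition)
  ref_ids <- ref_partition$id
  if (length(query_ids) > 0) assert_ids(query_ids, "query id")
  overlap <- intersect(ref_ids, query_ids)
  if (length(overlap) > 0) {
    abort(sprintf("ids are both reference and query: %s",
                  paste(head(overlap, 5), collapse = ", ")))
  }
  missing_q <- setdiff(query_ids, graph$ids)
  if (length(missing_q) > 0) {
    abort(sprintf("query ids missing from the graph universe: %s",
                  paste(head(missing_q, 5), collapse = ", ")))
  }
  if (!setequal(graph$ids, c(ref_ids, query_ids))) {
    abort("graph universe must be exactly reference ids + query ids")
  }

  n <- length(graph$ids)
  ref_labels <- unique(ref_partition$otu)
  n_ref_otus <- length(ref_labels)
  memb <- integer(n)
  memb[match(ref_ids, graph$ids)] <- match(ref_partition$otu, ref_labels)
  q_idx <- match(query_ids, graph$ids)
  memb[q_idx] <- n_ref_otus + seq_along(q_idx)
  sizes <- tabulate(memb)
  conf0 <- conf_from_memb(graph, memb)

  if (length(query_ids) == 0) {
    counts <- confusion_counts(conf0[["tp"]], conf0[["fp"]],
                               conf0[["fn"]], conf0[["tn"]])
    return(structure(
      list(partition = as_tibble(ref_partition[, c("id", "otu")]),
           counts = counts, mcc = mcc(counts), fraction_mapped = 1,
           unmapped_ids = character(), iterations = 0L, converged = TRUE,
           mode = mode, seed = seed, no_queries = TRUE,
           threshold = graph$threshold),
      class = "otu_fit"))
  }

  result <- with_optional_seed(seed, {
    run <- run_sweeps(graph, memb, sizes,
                      conf = unname(conf0), movable = q_idx,
                      ref_otu_max = n_ref_otus, tolerance = tolerance,
                      max_iterations = max_iterations)
    mapped <- q_idx[run$memb[q_idx] <= n_ref_otus]
    unmapped <- setdiff(q_idx, mapped)
    if (mode == "closed") {
      keep <- sort(c(match(ref_ids, graph$ids), mapped))
      sub <- subgraph_by_index(graph, keep)
      partition <- memb_to_partition(graph$ids[keep], run$memb[keep],
                                     labels = c(ref_labels))
      counts <- confusion_matrix(sub, partition)
      list(partition = partition, counts = counts,
           unmapped_ids = graph$ids[unmapped],
           fraction_mapped = length(mapped) / length(q_idx),
           fit_mcc = run$mcc, mcc_trace = run$mcc_trace,
           iterations = run$iterations, converged = run$converged)
    } else {
      memb2 <- run$memb
      next_id <- max(memb2) + 1L
      denovo_iter <- 0L
      if (length(unmapped) > 0) {
        sub <- subgraph_by_index(graph, unmapped)
        dn <- opticlust_core(sub, tolerance, max_iterations)
        memb2[sort(unmapped)] <- next_id + dn$memb - 1L
        denovo_iter <- dn$iterations
      }
      labels <- make_labels(memb2, ref_labels, n_ref_otus)
      partition <- memb_to_partition(graph$ids, memb2, labels = labels)
      counts <- confusion_matrix(graph, partition)
      list(partition = partition, counts = counts,
           unmapped_ids = character(),
           fraction_mapped = 1,
           n_mapped = length(mapped),
           denovo_iterations = denovo_iter,
           fit_mcc = run$mcc, mcc_trace = run$mcc_trace,
           iterations = run$iterations, converged = run$converged)
    }
  })

  structure(
    c(result,
      list(mcc = mcc(result$counts), mode = mode, seed = seed,
           no_queries = FALSE, threshold = graph$threshold,
           query_ids = query_ids)),
    class = "otu_fit")
}

# labels for OTU ids: 1..n_ref_otus keep their reference labels; higher
# ids get fresh "otu_<k>" labels that never collide with reference labels
make_labels <- function(memb, ref_labels, n_ref_otus) {
  top <- max(memb, n_ref_otus)
  labels <- character(top)
  labels[seq_len(n_ref_otus)] <- ref_labels
  extra <- setdiff(unique(memb), seq_len(n_ref_otus))
  k <- 0L
  for (o in sort(extra)) {
    repeat {
      k <- k + 1L
      cand <- paste0("otu_", k)
      if (!cand %in% ref_labels) break
    }
    labels[o] <- cand
  }
  labels
}

#' Drop queries that did not join a reference OTU (closed mode)
#'
#' @param partition Tibble `id`, `otu` over the combined universe, e.g.
#'   the state after the fit phase.
#' @param reference_labels Labels of the reference OTUs.
#' @param query_ids The query sequence ids.
#' @return A list with `partition` (references plus mapped queries; every
#'   label a reference label) and `unmapped_ids`.
#' @export
close_partition <- function(partition, reference_labels, query_ids) {
  validate_partition(partition)
  is_query <- partition$id %in% query_ids
  in_ref_otu <- partition$otu %in% reference_labels
  if (any(!is_query & !in_ref_otu)) {
    abort("reference sequences found outside reference OTUs")
  }
  unmapped <- partition$id[is_query & !in_ref_otu]
  list(partition = partition[!(is_query & !in_ref_otu), ],
       unmapped_ids = unmapped)
}

#' Cluster unassigned queries de novo and append them as new OTUs
#'
#' The open-reference finishing step: the induced subgraph over the
#' still-unassigned queries is clustered with the OptiClust strategy and
#' the resulting OTUs are appended under fresh labels; every other
#' assignment is untouched.
#'
#' @inheritParams optifit
#' @param partition Tibble `id`, `otu`; the unassigned ids must currently
#'   be singletons in it.
#' @param unassigned_ids Queries still in their own singletons.
#' @return The extended partition tibble.
#' @export
open_extend <- function(graph, partition, unassigned_ids, seed = 1,
                        tolerance = 1e-4, max_iterations = 100) {
  stopifnot(inherits(graph, "sim_graph"))
  validate_partition(partition, graph$ids)
  if (length(unassigned_ids) == 0) return(partition)
  sizes <- table(partition$otu)
  u_otus <- partition$otu[match(unassigned_ids, partition$id)]
  if (any(sizes[u_otus] != 1)) {
    abort("unassigned ids must be singletons in `partition`")
  }
  idx <- match(unassigned_ids, graph$ids)
  sub <- subgraph_by_index(graph, idx)
  res <- with_optional_seed(seed,
    opticlust_core(sub, tolerance, max_iterations))
  new_part <- memb_to_partition(sub$ids, res$memb)
  used <- unique(partition$otu[!partition$id %in% unassigned_ids])
  fresh <- fresh_labels(length(unique(new_part$otu)), used)
  new_part$otu <- fresh[match(new_part$otu, unique(new_part$otu))]
  dplyr::bind_rows(partition[!partition$id %in% unassigned_ids, ], new_part)
}

fresh_labels <- function(k, used) {
  out <- character(0)
  i <- 0L
  while (length(out) < k) {
    i <- i + 1L
    cand <- paste0("otu_", i)
    if (!cand %in% used) out <- c(out, cand)
  }
  out
}

#' @export
print.otu_fit <- function(x, ...) {
  cat(sprintf(
    "<otu_fit> %s mode | %d sequences in %d OTUs | MCC %.4f | mapped %.3f\n",
    x$mode, nrow(x$partition), length(unique(x$partition$otu)), x$mcc,
    x$fraction_mapped))
  invisible(x)
}
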