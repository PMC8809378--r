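# Exhaustive brute-force optima for small instances.  These are
# independent oracles for the iterative optimizers: they enumerate every
# admissible clustering and score each one from scratch.

#' Globally optimal partition by exhaustive enumeration
#'
#' Enumerates every set partition of the universe (via restricted growth
#' strings) and returns one with maximum MCC against the graph.  Feasible
#' only for tiny universes (Bell numbers explode); the cap is 12
#' sequences.  Ties keep the first optimum in enumeration order, but the
#' returned MCC is unique.
#'
#' @param graph A [sim_graph()] with at most 12 sequences.
#' @return A list with `partition` (tibble `id`, `otu`) and `mcc`.
#' @export
#' @examples
#' d <- tibble::tibble(id1 = "a", id2 = "b", distance = 0.01)
#' g <- sim_graph(d, ids = c("a", "b", "c"), threshold = 0.03)
#' brute_force_best_partition(g)$mcc
brute_force_best_partition <- function(graph) {
  stopifnot(inherits(graph, "sim_graph"))
  n <- length(graph$ids)
  if (n > 12) abort("exhaustive enumeration is capped at 12 sequences")
  if (n == 0) abort("empty universe")
  e <- graph$edges
  pos <- nrow(e)
  tot <- total_pairs(n)
  best_mcc <- -Inf
  best <- NULL
  # restricted growth strings: a[1] = 1; a[j] <= 1 + max(a[1..j-1])
  a <- rep(1L, n)
  repeat {
    tp <- if (pos) sum(a[e[, 1]] == a[e[, 2]]) else 0
    sizes <- tabulate(a)
    within <- sum(sizes * (sizes - 1) / 2)
    m <- mcc_num(tp, within - tp, pos - tp, tot - within - (pos - tp))
    if (m > best_mcc + MCC_TIE_TOL) {
      best_mcc <- m
      best <- a
    }
    # advance to the next RGS
    j <- n
    while (j > 1) {
      cap <- 1L + max(a[seq_len(j - 1)])
      if (a[j] < cap) break
      j <- j - 1L
    }
    if (j == 1) break
    a[j] <- a[j] + 1L
    if (j < n) a[(j + 1):n] <- 1L
  }
  list(partition = memb_to_partition(graph$ids, best), mcc = best_mcc)
}

#' Globally optimal fit by exhaustive enumeration
#'
#' Enumerates every assignment of each query to (each reference OTU or
#' its own singleton) with reference assignments frozen, scoring the MCC
#' over all pairs in the combined universe — the same objective and move
#' space as the fit phase of [optifit()].  Capped at 6 queries and 8
#' reference OTUs.
#'
#' @inheritParams optifit
#' @return A list with `assignment` (tibble `id`, `otu`; `otu` is `NA`
#'   for queries kept as singletons), `partition` (full combined
#'   partition, singleton queries under fresh labels) and `mcc`.
#' @export
brute_force_best_fit <- function(graph, ref_partition, query_ids) {
  stopifnot(inherits(graph, "sim_graph"))
  validate_partition(ref_partition)
  ref_labels <- unique(ref_partition$otu)
  R <- length(ref_labels)
  Q <- length(query_ids)
  if (Q > 6 || R > 8) {
    abort("exhaustive fit search is capped at 6 queries and 8 reference OTUs")
  }
  if (Q == 0) abort("no query sequences to fit")
  if (!setequal(graph$ids, c(ref_partition$id, query_ids))) {
    abort("graph universe must be exactly reference ids + query ids")
  }
  n <- length(graph$ids)
  memb <- integer(n)
  memb[match(ref_partition$id, graph$ids)] <-
    match(ref_partition$otu, ref_labels)
  q_idx <- match(query_ids, graph$ids)
  e <- graph$edges
  pos <- nrow(e)
  tot <- total_pairs(n)
  grid <- unname(as.matrix(expand.grid(rep(list(0:R), Q))))
  best_mcc <- -Inf
  best <- NULL
  for (r in seq_len(nrow(grid))) {
    opt <- unname(grid[r, ])
    memb[q_idx] <- ifelse(opt > 0, opt, R + seq_len(Q))
    tp <- if (pos) sum(memb[e[, 1]] == memb[e[, 2]]) else 0
    sizes <- tabulate(match(memb, unique(memb)))
    within <- sum(sizes * (sizes - 1) / 2)
    m <- mcc_num(tp, within - tp, pos - tp, tot - within - (pos - tp))
    if (m > best_mcc + MCC_TIE_TOL) {
      best_mcc <- m
      best <- opt
    }
  }
  memb[q_idx] <- ifelse(best > 0, best, R + seq_len(Q))
  labels <- make_labels(memb, ref_labels, R)
  list(
    assignment = tibble(
      id = query_ids,
      otu = ifelse(best > 0, ref_labels[ifelse(best > 0, best, 1)],
                   NA_character_)),
    partition = memb_to_partition(graph$ids, memb, labels = labels),
    mcc = best_mcc)
}
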