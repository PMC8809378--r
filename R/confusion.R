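# Confusion-matrix accounting over unordered sequence pairs.
#
# A pair within the distance threshold (a graph edge) is a true positive
# when co-clustered and a false negative when split; a pair beyond the
# threshold is a false positive when co-clustered and a true negative
# when split.  Counts are kept as exact doubles (integer-valued; they can
# reach ~n^2/2, past .Machine$integer.max for large n).

#' Assemble confusion counts
#'
#' @param tp,fp,fn,tn Non-negative pair counts.
#' @return A one-row tibble with columns `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_counts <- function(tp, fp, fn, tn) {
  v <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (anyNA(v) || any(v < 0) || any(v != trunc(v))) {
    abort("confusion counts must be non-negative integers")
  }
  tibble(tp = as.numeric(tp), fp = as.numeric(fp),
         fn = as.numeric(fn), tn = as.numeric(tn))
}

# vectorized numeric core; the denominator is a product of four square
# roots so marginal products cannot overflow double precision
mcc_num <- function(tp, fp, fn, tn) {
  denom <- sqrt(tp + fp) * sqrt(tp + fn) * sqrt(tn + fp) * sqrt(tn + fn)
  ifelse(denom == 0, 0, (tp * tn - fp * fn) / denom)
}

#' Matthews correlation coefficient of a confusion matrix
#'
#' Ranges from -1 (all pairs misclassified) through 0 (no better than
#' random) to 1 (all pairs correct).  When any marginal sum is zero the
#' standard formula is 0/0; this implementation returns 0 by convention
#' (documented as a dialect choice — an edgeless universe clustered as
#' all-singletons scores 0, not 1).
#'
#' @param counts A data frame (or named list/vector) with entries `tp`,
#'   `fp`, `fn`, `tn`, e.g. from [confusion_matrix()].
#' @return A numeric vector of MCC values in `[-1, 1]`, one per row.
#' @export
#' @examples
#' mcc(confusion_counts(tp = 14, fp = 0, fn = 9, tn = 1408)) # ~0.78
mcc <- function(counts) {
  counts <- as.list(counts)
  stopifnot(all(c("tp", "fp", "fn", "tn") %in% names(counts)))
  mcc_num(counts$tp, counts$fp, counts$fn, counts$tn)
}

# memb: integer OTU membership aligned with graph$ids (arbitrary ids)
conf_from_memb <- function(graph, memb) {
  e <- graph$edges
  tp <- sum(memb[e[, 1]] == memb[e[, 2]])
  sizes <- tabulate(match(memb, unique(memb)))
  within <- sum(sizes * (sizes - 1) / 2)
  pos <- nrow(e)
  tot <- total_pairs(length(memb))
  c(tp = tp, fp = within - tp, fn = pos - tp, tn = tot - within - (pos - tp))
}

#' Confusion matrix of a partition against a similarity graph
#'
#' @param graph A [sim_graph()].
#' @param partition A tibble with columns `id`, `otu`, covering exactly
#'   the graph's sequence universe.
#' @return A one-row tibble `tp`, `fp`, `fn`, `tn`.
#' @export
confusion_matrix <- function(graph, partition) {
  stopifnot(inherits(graph, "sim_graph"))
  validate_partition(partition, graph$ids)
  memb <- integer(length(graph$ids))
  memb[match(partition$id, graph$ids)] <-
    match(partition$otu, unique(partition$otu))
  cc <- conf_from_memb(graph, memb)
  confusion_counts(cc[["tp"]], cc[["fp"]], cc[["fn"]], cc[["tn"]])
}

#' Confusion counts after a hypothetical single-sequence move
#'
#' Returns the counts as if `seq_id` were moved to `target_otu` (or to a
#' brand-new singleton OTU when `target_otu` is `NA`).  The update is
#' exact and local: leaving an OTU where the sequence has `k` neighbors
#' and `m` non-neighbors changes the counts by `(tp-k, fn+k, fp-m, tn+m)`,
#' and joining is the mirror image — no full recount over all pairs.
#'
#' @inheritParams confusion_matrix
#' @param seq_id The sequence to move.
#' @param target_otu Label of an existing OTU, or `NA` for a new
#'   singleton.
#' @param counts Optional current confusion counts (one-row data frame);
#'   recomputed from scratch when omitted.
#' @return A one-row tibble `tp`, `fp`, `fn`, `tn` for the moved
#'   partition.
#' @export
move_delta <- function(graph, partition, seq_id, target_otu = NA,
                       counts = NULL) {
  stopifnot(inherits(graph, "sim_graph"))
  validate_partition(partition, graph$ids)
  i <- match(seq_id, graph$ids)
  if (is.na(i)) abort(sprintf("unknown sequence id '%s'", seq_id))
  if (!is.na(target_otu) && !target_otu %in% partition$otu) {
    abort(sprintf("unknown target OTU '%s'", target_otu))
  }
  if (is.null(counts)) counts <- confusion_matrix(graph, partition)
  cur <- partition$otu[match(seq_id, partition$id)]
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn

  nb_ids <- graph$ids[graph$adj[[i]]]
  otu_of <- function(ids) partition$otu[match(ids, partition$id)]
  # leave current OTU
  k_cur <- sum(otu_of(nb_ids) == cur)
  m_cur <- sum(partition$otu == cur) - 1 - k_cur
  tp <- tp - k_cur; fn <- fn + k_cur; fp <- fp - m_cur; tn <- tn + m_cur
  # join target (no-op when target is the new-singleton option)
  if (!is.na(target_otu) && target_otu != cur) {
    k_t <- sum(otu_of(nb_ids) == target_otu)
    m_t <- sum(partition$otu == target_otu) - k_t
    tp <- tp + k_t; fn <- fn - k_t; fp <- fp + m_t; tn <- tn - m_t
  } else if (!is.na(target_otu) && target_otu == cur) {
    # moving to its own OTU: undo the leave
    tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  }
  confusion_counts(tp, fp, fn, tn)
}

#' Clustering quality report
#'
#' Expands confusion counts into the standard diagnostic columns:
#' MCC, sensitivity `tp / (tp + fn)` and specificity `tn / (tn + fp)`.
#'
#' @param counts A data frame with columns `tp`, `fp`, `fn`, `tn`.
#' @return A tibble with the four counts plus `mcc`, `sensitivity`,
#'   `specificity` (the latter two are `NA` when undefined).
#' @export
confusion_stats <- function(counts) {
  counts <- as_tibble(as.list(counts)[c("tp", "fp", "fn", "tn")])
  dplyr::mutate(
    counts,
    mcc = mcc_num(.data$tp, .data$fp, .data$fn, .data$tn),
    sensitivity = ifelse(.data$tp + .data$fn == 0, NA_real_,
                         .data$tp / (.data$tp + .data$fn)),
    specificity = ifelse(.data$tn + .data$fp == 0, NA_real_,
                         .data$tn / (.data$tn + .data$fp)))
}
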