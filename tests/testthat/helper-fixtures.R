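# Fixture builders and independent oracles shared across test files.

# Build a sim_graph directly from character edge pairs.
graph_from_edges <- function(ids, edges, threshold = 0.03) {
  if (length(edges) == 0) {
    d <- tibble::tibble(id1 = character(), id2 = character(),
                        distance = double())
  } else {
    m <- do.call(rbind, edges)
    d <- tibble::tibble(id1 = m[, 1], id2 = m[, 2], distance = 0.01)
  }
  sim_graph(d, ids = ids, threshold = threshold)
}

# Erdos-Renyi style random graph over n sequences.
random_graph <- function(n, p, seed) {
  withr::with_seed(seed, {
    ids <- paste0("s", seq_len(n))
    pairs <- t(utils::combn(n, 2))
    keep <- stats::runif(nrow(pairs)) <= p
    edges <- lapply(which(keep), function(r) ids[pairs[r, ]])
    graph_from_edges(ids, edges)
  })
}

random_partition <- function(ids, max_otus = length(ids), seed) {
  withr::with_seed(seed, {
    k <- sample(max_otus, 1)
    otu <- paste0("p", sample(k, length(ids), replace = TRUE))
    tibble::tibble(id = ids, otu = otu)
  })
}

# Independent confusion oracle: classify every unordered pair directly
# from the edge list and the co-membership relation, one pair at a time.
brute_conf <- function(graph, partition) {
  ids <- graph$ids
  ed <- graph_edges(graph)
  ekey <- paste(pmin(ed$id1, ed$id2), pmax(ed$id1, ed$id2))
  otu_of <- stats::setNames(partition$otu, partition$id)
  tp <- fp <- fn <- tn <- 0
  n <- length(ids)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      a <- min(ids[i], ids[j]); b <- max(ids[i], ids[j])
      is_edge <- paste(a, b) %in% ekey
      same <- otu_of[[ids[i]]] == otu_of[[ids[j]]]
      if (is_edge && same) tp <- tp + 1
      else if (is_edge) fn <- fn + 1
      else if (same) fp <- fp + 1
      else tn <- tn + 1
    }
  }
  c(tp = tp, fp = fp, fn = fn, tn = tn)
}

# Canonical form of a partition for label-free comparison.
partition_signature <- function(partition) {
  groups <- lapply(split(partition$id, partition$otu), sort)
  unname(sort(vapply(groups, paste, character(1), collapse = ",")))
}

# Random small fit instance: references clustered de novo, then a few
# extra sequences appointed as queries.
random_fit_instance <- function(seed, n_ref = 6, n_query = 3, p = 0.4) {
  withr::with_seed(seed, {
    n <- n_ref + n_query
    ids <- c(paste0("r", seq_len(n_ref)), paste0("q", seq_len(n_query)))
    pairs <- t(utils::combn(n, 2))
    keep <- stats::runif(nrow(pairs)) <= p
    edges <- lapply(which(keep), function(r) ids[pairs[r, ]])
    graph <- graph_from_edges(ids, edges)
    ref_ids <- ids[seq_len(n_ref)]
    ref_graph <- subgraph_ids(graph, ref_ids)
    ref <- opticlust(ref_graph, seed = sample.int(1e6, 1))$partition
    list(graph = graph, ref = ref, query_ids = ids[-seq_len(n_ref)])
  })
}

# Small fit instance with planted OTU structure: references and queries
# drawn from the same planted community, references clustered de novo.
planted_fit_instance <- function(seed) {
  withr::with_seed(seed, {
    repeat {
      fx <- generate_planted_graph(n_otus = 3, otu_size_range = c(2, 4),
                                   p_within = 0.9, p_between = 0.05,
                                   seed = sample.int(1e6, 1))
      nq <- sample(2:4, 1)
      query_ids <- sample(fx$graph$ids, nq)
      ref_ids <- setdiff(fx$graph$ids, query_ids)
      ref_graph <- subgraph_ids(fx$graph, ref_ids)
      ref <- opticlust(ref_graph, seed = sample.int(1e6, 1))$partition
      # the exhaustive-fit comparison is framed for <= 6 reference OTUs
      if (length(unique(ref$otu)) <= 6) break
    }
    list(graph = fx$graph, ref = ref, query_ids = query_ids)
  })
}

# Label-free edge signature for comparing graphs read from different
# dialects.
edge_signature <- function(g) {
  ed <- graph_edges(g)
  sort(paste(pmin(ed$id1, ed$id2), pmax(ed$id1, ed$id2)))
}

# Induced subgraph by ids (test-side helper built on exported surface).
subgraph_ids <- function(graph, keep_ids) {
  ed <- graph_edges(graph)
  ed <- ed[ed$id1 %in% keep_ids & ed$id2 %in% keep_ids, ]
  ed$distance <- rep(0.01, nrow(ed))
  sim_graph(ed, ids = keep_ids, threshold = graph$threshold)
}
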