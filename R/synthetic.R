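# Synthetic fixtures with planted OTU structure.  These emulate the
# one property the optimizer actually consumes — a sparse graph of
# within-threshold pairs with block structure — not real amplicon data
# (no chimeras, no length variation, no abundance skew).

#' Generate a planted-partition similarity graph
#'
#' Sequences are grouped into `n_otus` planted OTUs; each within-OTU pair
#' becomes an edge with probability `p_within` and each between-OTU pair
#' with probability `p_between`.  With `p_within = 1, p_between = 0` the
#' result is a disjoint union of cliques and the planted partition scores
#' MCC 1.  Defaults give ~300 sequences in 30 OTUs whose sizes span
#' singletons up to ~20 members — amplicon communities are dominated by
#' rare taxa, and the rare tail is what makes closed-reference behavior
#' (unmappable queries) non-trivial — with strong within-OTU similarity
#' and sparse between-OTU noise.  This is the scale used throughout the
#' package's own evaluation.
#'
#' @param n_otus Number of planted OTUs.
#' @param otu_size_range Two integers: each OTU's size is drawn uniformly
#'   from this range (a single integer fixes the size).
#' @param p_within,p_between Edge probabilities inside / across planted
#'   OTUs; `p_between <= p_within` required.
#' @param seed Integer seed; every value yields one fixed fixture.
#' @param threshold Threshold recorded on the graph (cosmetic; edges are
#'   planted directly).
#' @return A list with `graph` (a [sim_graph()]) and `truth` (tibble
#'   `id`, `otu`: the planted partition).
#' @export
#' @examples
#' fx <- generate_planted_graph(3, c(4, 6), 1, 0, seed = 1)
#' confusion_matrix(fx$graph, fx$truth) # fp = fn = 0
generate_planted_graph <- function(n_otus = 30, otu_size_range = c(1, 19),
                                   p_within = 0.9, p_between = 0.005,
                                   seed = 1, threshold = 0.03) {
  stopifnot(n_otus >= 1, all(otu_size_range >= 1),
            p_between >= 0, p_within <= 1)
  if (p_between > p_within) abort("`p_between` must not exceed `p_within`")
  if (length(otu_size_range) == 1) otu_size_range <- rep(otu_size_range, 2)
  with_optional_seed(seed, {
    sizes <- sample(otu_size_range[1]:otu_size_range[2], n_otus,
                    replace = TRUE)
    block <- rep(seq_len(n_otus), sizes)
    ids <- paste0("otu", block, "_seq",
                  unlist(lapply(sizes, seq_len), use.names = FALSE))
    n <- length(ids)
    pair <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    same <- block[pair[, 1]] == block[pair[, 2]]
    p <- ifelse(same, p_within, p_between)
    keep <- runif(nrow(pair)) <= p
    edges <- cbind(pmin(pair[keep, 1], pair[keep, 2]),
                   pmax(pair[keep, 1], pair[keep, 2]))
    list(graph = new_sim_graph(ids, edges, threshold),
         truth = tibble(id = ids, otu = paste0("otu_", block)))
  })
}

#' Generate a mutated sequence family with its sparse distance file
#'
#' Each planted OTU gets a random centroid sequence; members are the
#' centroid with exactly `within_mutations` substitutions at random
#' positions.  Pairwise distance is the Hamming mismatch fraction on
#' these equal-length, ungapped sequences (a deliberate fixture
#' simplification — no alignment).  Intra-OTU distances are therefore at
#' most `2 * within_mutations / seq_length`, which must stay within 0.03,
#' and centroids are re-drawn until all inter-OTU member pairs exceed
#' 0.03.  The emitted distance table lists only pairs with distance
#' <= `max_emit`, mimicking a sparse column file with headroom above the
#' clustering threshold.
#'
#' @param n_otus Number of families.
#' @param members_per_otu Sequences per family.
#' @param seq_length Sequence length in bases.
#' @param within_mutations Substitutions applied to each member.
#' @param seed Integer seed.
#' @param max_emit Largest distance written to the sparse table.
#' @return A list with `sequences` (tibble `id`, `sequence`),
#'   `distances` (tibble `id1`, `id2`, `distance`; pairs <= `max_emit`)
#'   and `truth` (tibble `id`, `otu`).
#' @export
generate_sequence_family <- function(n_otus = 3, members_per_otu = 5,
                                     seq_length = 250, within_mutations = 2,
                                     seed = 1, max_emit = 0.10) {
  stopifnot(n_otus >= 1, members_per_otu >= 1, seq_length >= 20)
  if (2 * within_mutations / seq_length > 0.03) {
    abort("`within_mutations` too large: intra-OTU distances would exceed 0.03")
  }
  bases <- c("A", "C", "G", "T")
  with_optional_seed(seed, {
    sep_needed <- 0.03 + 2 * within_mutations / seq_length
    for (try in 1:50) {
      cent <- replicate(n_otus, sample(bases, seq_length, replace = TRUE),
                        simplify = FALSE)
      ok <- TRUE
      if (n_otus > 1) {
        for (a in seq_len(n_otus - 1)) for (b in (a + 1):n_otus) {
          if (mean(cent[[a]] != cent[[b]]) <= sep_needed) ok <- FALSE
        }
      }
      if (ok) break
    }
    if (!ok) abort("could not draw sufficiently separated centroids")
    seqs <- list(); ids <- character(); block <- integer()
    for (o in seq_len(n_otus)) {
      for (m in seq_len(members_per_otu)) {
        s <- cent[[o]]
        if (within_mutations > 0) {
          pos <- sample(seq_length, within_mutations)
          s[pos] <- vapply(s[pos], function(b)
            sample(setdiff(bases, b), 1), character(1))
        }
        seqs[[length(seqs) + 1]] <- s
        ids <- c(ids, sprintf("otu%d_seq%d", o, m))
        block <- c(block, o)
      }
    }
    n <- length(seqs)
    mat <- do.call(rbind, seqs)
    pair <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    pair <- pair[order(pair[, 1], pair[, 2]), , drop = FALSE]
    d <- vapply(seq_len(nrow(pair)), function(r)
      mean(mat[pair[r, 1], ] != mat[pair[r, 2], ]), numeric(1))
    keep <- d <= max_emit
    list(
      sequences = tibble(id = ids,
                         sequence = apply(mat, 1, paste, collapse = "")),
      distances = tibble(id1 = ids[pair[keep, 1]],
                         id2 = ids[pair[keep, 2]],
                         distance = d[keep]),
      truth = tibble(id = ids, otu = paste0("otu_", block)))
  })
}

#' Write sequences to a FASTA file
#'
#' @param sequences Tibble with columns `id`, `sequence`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  stopifnot(is.data.frame(sequences),
            all(c("id", "sequence") %in% names(sequences)))
  assert_ids(sequences$id)
  set <- Biostrings::BStringSet(stats::setNames(sequences$sequence,
                                                sequences$id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write distances as a sparse column file
#'
#' @param distances Tibble with columns `id1`, `id2`, `distance`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dist_columns <- function(distances, path) {
  stopifnot(is.data.frame(distances),
            all(c("id1", "id2", "distance") %in% names(distances)))
  writeLines(sprintf("%s\t%s\t%s", distances$id1, distances$id2,
                     format(distances$distance, digits = 6,
                            scientific = FALSE, trim = TRUE)),
             path)
  invisible(path)
}
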