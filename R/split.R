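# Reference/query splitting for split-dataset fitting experiments.

new_split <- function(ids, ref_ids, strategy, fraction, seed) {
  out <- tibble(
    id = ids,
    role = ifelse(ids %in% ref_ids, "reference", "query"))
  structure(out, class = c("split_assignment", class(out)),
            strategy = strategy, fraction = fraction, seed = seed)
}

split_size <- function(n, fraction) {
  if (length(fraction) != 1 || is.na(fraction) ||
      fraction <= 0 || fraction >= 1) {
    abort("`fraction` must be strictly between 0 and 1")
  }
  k <- round_half_up(fraction * n)
  if (k < 1 || k > n - 1) {
    abort(sprintf(
      "fraction %g of %d sequences leaves an empty reference or query set",
      fraction, n))
  }
  k
}

#' Split a sequence universe into reference and query sets
#'
#' Three sampling strategies choose which sequences seed the reference
#' fraction (the rest become queries):
#' * `split_simple()` — a simple random sample.
#' * `split_abundance()` — sampling weight proportional to each
#'   sequence's abundance count.
#' * `split_similarity()` — weight proportional to `1 + degree` in the
#'   similarity graph (the `+1` keeps sequences with no close neighbor
#'   selectable).
#'
#' Weighted draws are sequential without replacement with renormalization
#' after each draw (base R's `sample(prob = )` scheme).  The reference
#' size is `fraction * n` rounded half away from zero; a fraction that
#' would empty either side is an error.
#'
#' @param ids Character vector: the sequence universe.
#' @param fraction Reference fraction, strictly between 0 and 1.
#' @param seed Integer seed; `NULL` uses the current RNG state.
#' @return A `split_assignment`: a tibble with columns `id`, `role`
#'   (`"reference"`/`"query"`) carrying the strategy, fraction and seed
#'   as attributes.  Use [split_ids()] to extract either side.
#' @export
#' @examples
#' s <- split_simple(paste0("seq", 1:10), fraction = 0.5, seed = 3)
#' split_ids(s, "reference")
split_simple <- function(ids, fraction, seed = 1) {
  assert_ids(ids)
  k <- split_size(length(ids), fraction)
  ref <- with_optional_seed(seed, sample(ids, k))
  new_split(ids, ref, "simple", fraction, seed)
}

#' @param counts Abundance counts: a data frame with columns `id`,
#'   `count` (e.g. from [read_count_table()]) or a named numeric vector.
#'   Every id needs a positive count.
#' @rdname split_simple
#' @export
split_abundance <- function(ids, counts, fraction, seed = 1) {
  assert_ids(ids)
  w <- resolve_weights(ids, counts)
  k <- split_size(length(ids), fraction)
  ref <- with_optional_seed(seed, sample(ids, k, prob = w))
  new_split(ids, ref, "abundance", fraction, seed)
}

#' @param graph A [sim_graph()]; its universe is split.
#' @rdname split_simple
#' @export
split_similarity <- function(graph, fraction, seed = 1) {
  stopifnot(inherits(graph, "sim_graph"))
  ids <- graph$ids
  w <- 1 + lengths(graph$adj)
  k <- split_size(length(ids), fraction)
  ref <- with_optional_seed(seed, sample(ids, k, prob = w))
  new_split(ids, ref, "similarity", fraction, seed)
}

resolve_weights <- function(ids, counts) {
  if (is.data.frame(counts)) {
    stopifnot(all(c("id", "count") %in% names(counts)))
    counts <- stats::setNames(counts$count, counts$id)
  }
  w <- counts[ids]
  if (anyNA(w)) {
    abort(sprintf("no abundance count for: %s",
                  paste(head(ids[is.na(w)], 5), collapse = ", ")))
  }
  if (any(w <= 0) || any(w != trunc(w))) {
    abort("abundance counts must be positive integers")
  }
  as.numeric(w)
}

#' @param x A `split_assignment`.
#' @param role `"reference"` or `"query"`.
#' @rdname split_simple
#' @export
split_ids <- function(x, role = c("reference", "query")) {
  role <- match.arg(role)
  stopifnot(inherits(x, "split_assignment"))
  x$id[x$role == role]
}

#' Read a two-column abundance count table
#'
#' Tab-separated `id<TAB>count`; one header line is permitted (detected
#' by a non-numeric second field on line one).
#'
#' @param path File path.
#' @return A tibble with columns `id`, `count`.
#' @export
read_count_table <- function(path) {
  lines <- read_lines_checked(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("'%s' is empty", path))
  toks <- strsplit(lines, "[[:space:]]+")
  if (any(lengths(toks) != 2)) {
    abort(sprintf("'%s': every line must be 'id<TAB>count'", path))
  }
  first_count <- suppressWarnings(as.numeric(toks[[1]][2]))
  if (is.na(first_count)) toks <- toks[-1]  # header
  if (length(toks) == 0) abort(sprintf("'%s' has a header but no data", path))
  cnt <- suppressWarnings(as.numeric(vapply(toks, `[[`, character(1), 2)))
  if (anyNA(cnt)) abort(sprintf("'%s': non-numeric count", path))
  out <- tibble(id = vapply(toks, `[[`, character(1), 1), count = cnt)
  assert_ids(out$id)
  out
}
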