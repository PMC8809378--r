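#' Read sequence identifiers (and sequences) from a FASTA file
#'
#' Record identifiers are the first whitespace-delimited token after `>`;
#' any description text is dropped.  File order is preserved, so the same
#' file always yields the same sequence universe.
#'
#' @param path Path to a FASTA file.
#' @return A tibble with columns `id` and `sequence`, one row per record,
#'   in file order.  `dplyr::pull(x, id)` gives the sequence universe.
#' @export
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">seqA some description", "ACGT", ">seqB", "ACGA"), fa)
#' read_fasta(fa)
read_fasta <- function(path) {
  recs <- Biostrings::readBStringSet(path)
  if (length(recs) == 0) {
    abort(sprintf("FASTA file '%s' contains no records", path))
  }
  ids <- sub("\\s.*$", "", names(recs))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate FASTA id: %s", paste(dup, collapse = ", ")))
  }
  assert_ids(ids)
  tibble(id = ids, sequence = as.character(unname(recs)))
}

#' Read or write a plain-text name list (one sequence id per line)
#'
#' @param path File path.
#' @return `read_name_list()` returns a character vector of ids in file
#'   order; `write_name_list()` returns `path` invisibly.
#' @export
read_name_list <- function(path) {
  ids <- read_lines_checked(path)
  ids <- trimws(ids)
  ids <- ids[nzchar(ids)]
  assert_ids(ids)
  ids
}

#' @param ids Character vector of sequence ids.
#' @rdname read_name_list
#' @export
write_name_list <- function(ids, path) {
  assert_ids(ids)
  writeLines(ids, path)
  invisible(path)
}

#' Number of unordered sequence pairs
#'
#' Every pair of distinct sequences is classified (true/false
#' positive/negative) when scoring a clustering, so the universe of `n`
#' sequences always contributes `n * (n - 1) / 2` pairs.
#'
#' @param n Number of sequences, or a similarity graph / character vector
#'   of ids whose length is used.
#' @return The pair count as a double (exact for any realistic `n`).
#' @export
#' @examples
#' total_pairs(54) # 1431
total_pairs <- function(n) {
  if (inherits(n, "sim_graph")) n <- length(n$ids)
  if (is.character(n)) n <- length(n)
  if (length(n) != 1 || is.na(n) || n < 0 || n != trunc(n)) {
    abort("`n` must be a single non-negative integer")
  }
  n * (n - 1) / 2
}
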