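#' Read pairwise distances in sparse column format
#'
#' The column format has one pair per line: `id1 id2 distance`, whitespace
#' separated.  Pairs absent from the file are taken to be farther apart
#' than any threshold of interest, which is why building a graph from
#' column data additionally requires the full sequence universe (a FASTA
#' or name list): sequences with no close neighbor never appear in the
#' distance file at all.
#'
#' @param path Path to a column-format distance file.
#' @return A tibble with columns `id1`, `id2` and `distance`, one row per
#'   input line, in file order.
#' @seealso [sim_graph()] to threshold the distances into a graph.
#' @export
read_dist_columns <- function(path) {
  lines <- read_lines_checked(path)
  keep <- nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) {
    return(tibble(id1 = character(), id2 = character(), distance = double()))
  }
  toks <- strsplit(trimws(lines), "[[:space:]]+")
  nf <- lengths(toks)
  if (any(nf != 3)) {
    bad <- which(nf != 3)[1]
    abort(sprintf("line %d of '%s': expected 3 fields, found %d",
                  lineno[bad], path, nf[bad]))
  }
  m <- matrix(unlist(toks), ncol = 3, byrow = TRUE)
  d <- suppressWarnings(as.numeric(m[, 3]))
  if (anyNA(d)) {
    bad <- which(is.na(d))[1]
    abort(sprintf("line %d of '%s': distance '%s' is not a number",
                  lineno[bad], path, m[bad, 3]))
  }
  tibble(id1 = m[, 1], id2 = m[, 2], distance = d)
}

#' Read a PHYLIP-style distance matrix (lower-triangle or square)
#'
#' The first line gives the sequence count `n`; each following row starts
#' with a sequence id.  Lower-triangle rows carry `i - 1` distances,
#' square rows carry `n`.  Square matrices must be symmetric to within
#' 1e-9.  The sequence universe is taken from the row labels, so no
#' separate name list is needed with this format.
#'
#' @param path Path to the matrix file.
#' @return A tibble with columns `id1`, `id2`, `distance` listing every
#'   pair once, with the row labels attached as attribute `ids`.
#' @export
read_dist_matrix <- function(path) {
  lines <- read_lines_checked(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("'%s' is empty", path))
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || n < 0) {
    abort(sprintf("'%s': first line must be the sequence count", path))
  }
  rows <- lines[-1]
  if (length(rows) != n) {
    abort(sprintf("'%s': declared %d sequences but found %d rows",
                  path, n, length(rows)))
  }
  if (n == 0) {
    out <- tibble(id1 = character(), id2 = character(), distance = double())
    attr(out, "ids") <- character()
    return(out)
  }
  toks <- strsplit(trimws(rows), "[[:space:]]+")
  ids <- vapply(toks, `[[`, character(1), 1)
  assert_ids(ids)
  nval <- lengths(toks) - 1L
  square <- nval[1] == n
  expected <- if (square) rep(n, n) else seq_len(n) - 1L
  if (any(nval != expected)) {
    bad <- which(nval != expected)[1]
    abort(sprintf(
      "'%s': row %d ('%s') has %d distances, expected %d (%s format)",
      path, bad, ids[bad], nval[bad], expected[bad],
      if (square) "square" else "lower-triangle"))
  }
  vals <- lapply(toks, function(tk) {
    v <- suppressWarnings(as.numeric(tk[-1]))
    if (anyNA(v)) abort(sprintf("'%s': non-numeric distance in matrix", path))
    v
  })
  if (square) {
    mat <- do.call(rbind, vals)
    if (max(abs(mat - t(mat))) > 1e-9) {
      abort(sprintf("'%s': square matrix is not symmetric (tolerance 1e-9)",
                    path))
    }
    idx <- which(upper.tri(mat), arr.ind = TRUE)
    out <- tibble(id1 = ids[idx[, 1]], id2 = ids[idx[, 2]],
                  distance = mat[idx])
  } else {
    i <- rep(seq_len(n), times = nval)   # row index
    j <- sequence(nval)                  # column index, always < i
    out <- tibble(id1 = ids[j], id2 = ids[i],
                  distance = unlist(vals, use.names = FALSE))
  }
  attr(out, "ids") <- ids
  out
}
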