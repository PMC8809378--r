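# Partitions are tibbles with columns `id` (sequence) and `otu` (label).

validate_partition <- function(partition, ids = NULL) {
  stopifnot(is.data.frame(partition),
            all(c("id", "otu") %in% names(partition)))
  assert_ids(partition$id, "sequence id")
  if (anyNA(partition$otu)) abort("OTU labels must be non-missing")
  if (!is.null(ids)) {
    extra <- setdiff(partition$id, ids)
    if (length(extra) > 0) {
      abort(sprintf("partition contains ids outside the universe: %s",
                    paste(head(extra, 5), collapse = ", ")))
    }
    missing_id <- setdiff(ids, partition$id)
    if (length(missing_id) > 0) {
      abort(sprintf("partition is missing ids from the universe: %s",
                    paste(head(missing_id, 5), collapse = ", ")))
    }
  }
  invisible(partition)
}

# canonical OTU display order: descending size, ties by lexicographically
# smallest member; members sorted within each OTU
otu_order <- function(partition) {
  members <- split(partition$id, partition$otu)
  members <- lapply(members, sort)
  size <- lengths(members)
  first <- vapply(members, `[[`, character(1), 1)
  members[order(-size, first)]
}

#' Write a partition as a mothur-style list file
#'
#' A list file is one line: a label (conventionally the distance
#' threshold, e.g. `"0.03"`), the OTU count, then one tab-separated field
#' per OTU with comma-joined member ids.  OTUs are written in descending
#' size order (ties by lexicographically smallest member) and members are
#' sorted, so output is deterministic and diffable.
#'
#' @param partition A tibble with columns `id`, `otu`.
#' @param path Output file path.
#' @param label Label string for the first column.
#' @return `path`, invisibly.
#' @export
write_otu_list <- function(partition, path, label = "0.03") {
  validate_partition(partition)
  members <- otu_order(partition)
  fields <- vapply(members, paste, character(1), collapse = ",")
  writeLines(paste(c(label, length(fields), fields), collapse = "\t"), path)
  invisible(path)
}

#' Read a mothur-style list file into a partition
#'
#' @param path Path to a single-line list file as written by
#'   [write_otu_list()].
#' @param ids Optional sequence universe; when given, every member id
#'   must belong to it.
#' @return A tibble with columns `id` and `otu`; OTUs are labelled
#'   `otu_1 ... otu_k` in file order.  The original label line is
#'   attached as attribute `label`.
#' @export
read_otu_list <- function(path, ids = NULL) {
  lines <- read_lines_checked(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 1) {
    abort(sprintf("'%s': expected a single-label list file (one data line)",
                  path))
  }
  fields <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (length(fields) < 2) abort(sprintf("'%s': malformed list line", path))
  label <- fields[1]
  n_otu <- suppressWarnings(as.integer(fields[2]))
  otus <- fields[-(1:2)]
  if (is.na(n_otu) || length(otus) != n_otu) {
    abort(sprintf("'%s': declared %s OTUs but found %d",
                  path, fields[2], length(otus)))
  }
  members <- strsplit(otus, ",", fixed = TRUE)
  if (any(lengths(members) == 0)) abort(sprintf("'%s': empty OTU field", path))
  out <- tibble(
    id = unlist(members, use.names = FALSE),
    otu = rep(paste0("otu_", seq_len(n_otu)), lengths(members)))
  dup <- unique(out$id[duplicated(out$id)])
  if (length(dup) > 0) {
    abort(sprintf("'%s': sequence(s) in more than one OTU: %s",
                  path, paste(head(dup, 5), collapse = ", ")))
  }
  if (!is.null(ids)) {
    extra <- setdiff(out$id, ids)
    if (length(extra) > 0) {
      abort(sprintf("'%s': ids not in the supplied universe: %s",
                    path, paste(head(extra, 5), collapse = ", ")))
    }
  }
  attr(out, "label") <- label
  out
}
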