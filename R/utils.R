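# Shared internal helpers.

# round-half-away-from-zero; base round() is banker's rounding
round_half_up <- function(x) {
  trunc(x + sign(x) * 0.5)
}

# MCC comparisons treat values within this of each other as tied
MCC_TIE_TOL <- 1e-12

assert_ids <- function(ids, what = "id") {
  if (length(ids) == 0) {
    abort(sprintf("need at least one %s", what))
  }
  if (anyNA(ids) || !is.character(ids)) {
    abort(sprintf("%ss must be character and non-missing", what))
  }
  if (any(grepl("[[:space:],]", ids))) {
    bad <- ids[grepl("[[:space:],]", ids)][1]
    abort(sprintf("%s '%s' contains whitespace or a comma", what, bad))
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0) {
    abort(sprintf("duplicate %s: %s", what, paste(head(dup, 5), collapse = ", ")))
  }
  invisible(ids)
}

read_lines_checked <- function(path) {
  if (!is.character(path) || length(path) != 1 || !file.exists(path)) {
    abort(sprintf("cannot read '%s': no such file", as.character(path)[1]))
  }
  readLines(path)
}

usage_error <- function(msg) {
  abort(msg, class = "otufit_usage_error")
}

log_msg <- function(level, ...) {
  message(sprintf("[%s] %s", level, sprintf(...)))
}
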