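# Minimal CoNLL-U reader/writer. Only the columns this package consumes are
# interpreted (ID, FORM, UPOS, HEAD); sentence-level comments carry the
# doc_id and sentence index used to align parses with candidate examples.

#' Read a CoNLL-U file of dependency parses
#'
#' Sentences are separated by blank lines; the comments `# doc_id = ...` and
#' `# sent_index = ...` identify which document sentence each parse belongs
#' to. Multi-word-token ranges and empty nodes (ids containing `-` or `.`)
#' are skipped.
#'
#' @param path Path to a 10-column CoNLL-U file.
#' @return List of parses, each a list with `doc_id`, `sent_index`, and a
#'   data frame `tokens(id, form, upos, head)`.
#' @export
read_conllu <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  sentences <- list()
  meta <- list()
  rows <- list()
  flush <- function() {
    if (length(rows) == 0L) return()
    tok <- do.call(rbind, rows)
    tok <- data.frame(id = as.integer(tok[, 1]), form = tok[, 2],
                      upos = tok[, 3], head = as.integer(tok[, 4]),
                      stringsAsFactors = FALSE)
    if (anyNA(tok$head)) {
      stopf("%s: token without head in sentence %s/%s", path,
            meta$doc_id %||% "?", meta$sent_index %||% "?")
    }
    sentences[[length(sentences) + 1L]] <<- list(
      doc_id = meta$doc_id, sent_index = as.integer(meta$sent_index),
      tokens = tok)
    meta <<- list()
    rows <<- list()
  }
  for (k in seq_along(lines)) {
    line <- lines[k]
    if (!nzchar(line)) {
      flush()
    } else if (startsWith(line, "#")) {
      m <- regmatches(line, regexec("^#\\s*([A-Za-z_]+)\\s*=\\s*(.*)$", line))[[1]]
      if (length(m) == 3L) meta[[m[2]]] <- trimws(m[3])
    } else {
      f <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (length(f) != 10L) {
        stopf("%s: malformed line %d (expected 10 fields, got %d)", path, k,
              length(f))
      }
      if (grepl("[-.]", f[1])) next  # multiword ranges / empty nodes
      rows[[length(rows) + 1L]] <- c(f[1], f[2], f[4], f[7])
    }
  }
  flush()
  sentences
}

#' Write dependency parses in CoNLL-U format
#'
#' @param parses List of parses as returned by [read_conllu()] (fields other
#'   than `form`, `upos`, `head` are written as `_`).
#' @param path Output path.
#' @export
write_conllu <- function(parses, path) {
  out <- character(0)
  for (s in parses) {
    tok <- s$tokens
    out <- c(out,
             paste0("# doc_id = ", s$doc_id),
             paste0("# sent_index = ", s$sent_index),
             paste(seq_len(nrow(tok)), tok$form, "_", tok$upos, "_", "_",
                   tok$head, "_", "_", "_", sep = "\t"),
             "")
  }
  writeLines(out, path, useBytes = TRUE)
  invisible(path)
}
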