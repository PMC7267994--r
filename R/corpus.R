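# ChemProt-style corpus reader/writer. A corpus is three tab-separated files:
#   abstracts: doc_id <TAB> title <TAB> abstract
#   entities:  doc_id <TAB> Tn <TAB> {CHEMICAL,GENE-Y,GENE-N} <TAB> start <TAB> end <TAB> surface
#   relations: doc_id <TAB> CPR:k [<TAB> eval flag [<TAB> type name]] <TAB> Arg1:Tn <TAB> Arg2:Tn
# Character offsets are 0-based, end-exclusive, over title + sep + abstract
# (sep defaults to a single tab, the ChemProt distribution convention).

read_tsv_lines <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines[nzchar(lines)]
}

split_fields <- function(lines, path, n_fields) {
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != n_fields)
  if (length(bad) > 0L) {
    stopf("%s: malformed line %d (expected %d tab-separated fields, got %d)",
          path, bad[1], n_fields, length(parts[[bad[1]]]))
  }
  parts
}

strip_arg <- function(x, path, line) {
  out <- sub("^Arg[12]:", "", x)
  if (any(out == x)) {
    stopf("%s: malformed line %d (argument field '%s' lacks Arg1:/Arg2: prefix)",
          path, line[out == x][1], x[out == x][1])
  }
  out
}

#' Full document text used for character offsets
#'
#' @param corpus A `chemprot_corpus`.
#' @param doc_id Document identifier(s); default all documents.
#' @return Named character vector `title <sep> abstract` per document.
#' @export
doc_text <- function(corpus, doc_id = NULL) {
  docs <- corpus$documents
  if (!is.null(doc_id)) docs <- docs[match(doc_id, docs$doc_id), , drop = FALSE]
  stats::setNames(paste(docs$title, docs$abstract, sep = corpus$sep), docs$doc_id)
}

#' Read a ChemProt-style corpus
#'
#' Reads the abstracts, entities and relations files, resolves all
#' cross-references, and enforces the format invariants: unique document ids,
#' mention offsets matching the document text, relation arguments resolving to
#' mentions of the same document. Mentions and relations that reference an
#' unknown document or entity are dropped with a warning; an offset/surface
#' mismatch is an error. Both the gold-standard relation dialects (5 or 6
#' columns with an evaluation flag) and the minimal 4-column dialect are
#' accepted, auto-detected by column count. Duplicate relation lines are
#' de-duplicated with a warning.
#'
#' @param abstracts_path,entities_path,relations_path File paths.
#' @param sep Separator inserted between title and abstract when computing
#'   character offsets (default `"\t"`).
#' @return An object of class `chemprot_corpus`: list of data frames
#'   `documents(doc_id, title, abstract)`,
#'   `entities(doc_id, entity_id, etype, start, end, surface)`,
#'   `relations(doc_id, cpr_group, evaluated, arg1_id, arg2_id)`.
#' @export
read_corpus <- function(abstracts_path, entities_path, relations_path,
                        sep = "\t") {
  ## documents
  parts <- split_fields(read_tsv_lines(abstracts_path), abstracts_path, 3L)
  documents <- data.frame(
    doc_id = vapply(parts, `[[`, "", 1L),
    title = vapply(parts, `[[`, "", 2L),
    abstract = vapply(parts, `[[`, "", 3L),
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(documents$doc_id))) stopf("%s: empty doc_id", abstracts_path)
  if (anyDuplicated(documents$doc_id)) {
    stopf("%s: duplicate doc_id '%s'", abstracts_path,
          documents$doc_id[duplicated(documents$doc_id)][1])
  }
  text <- stats::setNames(paste(documents$title, documents$abstract, sep = sep),
                          documents$doc_id)

  ## entities
  parts <- split_fields(read_tsv_lines(entities_path), entities_path, 6L)
  entities <- data.frame(
    doc_id = vapply(parts, `[[`, "", 1L),
    entity_id = vapply(parts, `[[`, "", 2L),
    etype = vapply(parts, `[[`, "", 3L),
    start = as.integer(vapply(parts, `[[`, "", 4L)),
    end = as.integer(vapply(parts, `[[`, "", 5L)),
    surface = vapply(parts, `[[`, "", 6L),
    stringsAsFactors = FALSE
  )
  bad_type <- which(!entities$etype %in% ENTITY_TYPES)
  if (length(bad_type) > 0L) {
    stopf("%s: malformed line %d (unknown entity type '%s')", entities_path,
          bad_type[1], entities$etype[bad_type[1]])
  }
  if (anyNA(entities$start) || anyNA(entities$end) ||
      any(entities$start < 0L) || any(entities$start >= entities$end)) {
    stopf("%s: invalid character offsets (need 0 <= start < end)", entities_path)
  }
  unknown <- !entities$doc_id %in% documents$doc_id
  if (any(unknown)) {
    warnf("%s: dropping %d mention(s) referencing unknown documents (e.g. %s/%s)",
          entities_path, sum(unknown), entities$doc_id[unknown][1],
          entities$entity_id[unknown][1])
    entities <- entities[!unknown, , drop = FALSE]
  }
  if (nrow(entities) > 0L) {
    key <- paste(entities$doc_id, entities$entity_id)
    if (anyDuplicated(key)) {
      stopf("%s: duplicate entity id within document (%s)", entities_path,
            key[duplicated(key)][1])
    }
    slice <- substr(text[entities$doc_id], entities$start + 1L, entities$end)
    mism <- which(slice != entities$surface)
    if (length(mism) > 0L) {
      i <- mism[1]
      stopf(paste0("%s: offset/surface mismatch for mention %s/%s: ",
                   "document slice [%d,%d) is '%s' but surface is '%s'",
                   " (%d mismatching mention(s) in total)"),
            entities_path, entities$doc_id[i], entities$entity_id[i],
            entities$start[i], entities$end[i], slice[i], entities$surface[i],
            length(mism))
    }
  }

  ## relations
  lines <- read_tsv_lines(relations_path)
  if (length(lines) == 0L) {
    relations <- data.frame(doc_id = character(), cpr_group = character(),
                            evaluated = logical(), arg1_id = character(),
                            arg2_id = character(), stringsAsFactors = FALSE)
  } else {
    parts <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(parts)
    bad <- which(!nf %in% c(4L, 5L, 6L))
    if (length(bad) > 0L) {
      stopf("%s: malformed line %d (expected 4, 5 or 6 fields, got %d)",
            relations_path, bad[1], nf[bad[1]])
    }
    a1 <- mapply(function(p, k) p[[k - 1L]], parts, nf)
    a2 <- mapply(function(p, k) p[[k]], parts, nf)
    ln <- seq_along(parts)
    relations <- data.frame(
      doc_id = vapply(parts, `[[`, "", 1L),
      cpr_group = vapply(parts, `[[`, "", 2L),
      arg1_id = strip_arg(a1, relations_path, ln),
      arg2_id = strip_arg(a2, relations_path, ln),
      stringsAsFactors = FALSE
    )
    bad_grp <- which(!relations$cpr_group %in% CPR_GROUPS)
    if (length(bad_grp) > 0L) {
      stopf("%s: malformed line %d (unknown relation group '%s')",
            relations_path, bad_grp[1], relations$cpr_group[bad_grp[1]])
    }
    relations$evaluated <- relations$cpr_group %in% EVALUATED_GROUPS
    relations <- relations[, c("doc_id", "cpr_group", "evaluated",
                               "arg1_id", "arg2_id")]
    ekey <- paste(entities$doc_id, entities$entity_id)
    ok_doc <- relations$doc_id %in% documents$doc_id
    ok_a1 <- paste(relations$doc_id, relations$arg1_id) %in% ekey
    ok_a2 <- paste(relations$doc_id, relations$arg2_id) %in% ekey
    drop <- !(ok_doc & ok_a1 & ok_a2)
    if (any(drop)) {
      warnf("%s: dropping %d relation(s) with unresolvable references (e.g. line %d)",
            relations_path, sum(drop), which(drop)[1])
      relations <- relations[!drop, , drop = FALSE]
    }
    dup <- duplicated(relations)
    if (any(dup)) {
      warnf("%s: de-duplicated %d repeated relation line(s)", relations_path,
            sum(dup))
      relations <- relations[!dup, , drop = FALSE]
    }
    rownames(relations) <- NULL
  }

  structure(list(documents = documents, entities = entities,
                 relations = relations, sep = sep),
            class = "chemprot_corpus")
}

#' @export
print.chemprot_corpus <- function(x, ...) {
  cat("<chemprot_corpus> ", nrow(x$documents), " documents, ",
      nrow(x$entities), " entity mentions, ",
      nrow(x$relations), " relations (",
      sum(x$relations$evaluated), " evaluated)\n", sep = "")
  invisible(x)
}

#' Write a corpus back to the three TSV files
#'
#' Inverse of [read_corpus()]; relations are written in the 5-column dialect
#' (doc, group, Y/N evaluation flag, Arg1:, Arg2:).
#'
#' @param corpus A `chemprot_corpus`.
#' @param abstracts_path,entities_path,relations_path Output paths.
#' @export
write_corpus <- function(corpus, abstracts_path, entities_path,
                         relations_path) {
  d <- corpus$documents
  writeLines(paste(d$doc_id, d$title, d$abstract, sep = "\t"),
             abstracts_path, useBytes = TRUE)
  e <- corpus$entities
  writeLines(paste(e$doc_id, e$entity_id, e$etype, e$start, e$end, e$surface,
                   sep = "\t"),
             entities_path, useBytes = TRUE)
  r <- corpus$relations
  writeLines(paste(r$doc_id, r$cpr_group, ifelse(r$evaluated, "Y", "N"),
                   paste0("Arg1:", r$arg1_id), paste0("Arg2:", r$arg2_id),
                   sep = "\t"),
             relations_path, useBytes = TRUE)
  invisible(corpus)
}

#' Write predicted relations
#'
#' Writes one relation per line in the 4-column dialect
#' `doc_id<TAB>CPR:k<TAB>Arg1:Tn<TAB>Arg2:Tn`, loadable by the relation
#' reader of [read_corpus()]. Predictions outside the five evaluated classes
#' are rejected.
#'
#' @param predictions Data frame with columns `doc_id`, `cpr_group`,
#'   `arg1_id`, `arg2_id` (zero rows produce an empty file).
#' @param path Output path.
#' @export
write_predictions <- function(predictions, path) {
  req <- c("doc_id", "cpr_group", "arg1_id", "arg2_id")
  if (!all(req %in% names(predictions))) {
    stopf("predictions must have columns %s", paste(req, collapse = ", "))
  }
  bad <- which(!predictions$cpr_group %in% EVALUATED_GROUPS)
  if (length(bad) > 0L) {
    stopf("prediction %d has non-evaluated class '%s'", bad[1],
          predictions$cpr_group[bad[1]])
  }
  lines <- if (nrow(predictions) == 0L) character(0) else {
    paste(predictions$doc_id, predictions$cpr_group,
          paste0("Arg1:", predictions$arg1_id),
          paste0("Arg2:", predictions$arg2_id), sep = "\t")
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read a predictions file
#'
#' @param path A 4-column predictions TSV as written by [write_predictions()].
#' @return Data frame with `doc_id`, `cpr_group`, `arg1_id`, `arg2_id`.
#' @export
read_predictions <- function(path) {
  lines <- read_tsv_lines(path)
  if (length(lines) == 0L) {
    return(data.frame(doc_id = character(), cpr_group = character(),
                      arg1_id = character(), arg2_id = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- split_fields(lines, path, 4L)
  ln <- seq_along(parts)
  data.frame(
    doc_id = vapply(parts, `[[`, "", 1L),
    cpr_group = vapply(parts, `[[`, "", 2L),
    arg1_id = strip_arg(vapply(parts, `[[`, "", 3L), path, ln),
    arg2_id = strip_arg(vapply(parts, `[[`, "", 4L), path, ln),
    stringsAsFactors = FALSE
  )
}
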