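# From corpus to classified sentence-level candidates: sentence splitting,
# candidate chemical-gene pair enumeration, digit normalization, entity-type
# tag sequences, CoNLL-U parse attachment, and the 9:1 document re-split.

#' Split a document into sentences
#'
#' The title is always its own sentence; the abstract is split after
#' sentence-final punctuation followed by whitespace. When entity mentions
#' are supplied, any boundary that would cut a mention in two is repaired by
#' merging the adjacent sentences, so every mention lies within one sentence.
#'
#' @param document A list or one-row data frame with `title` and `abstract`.
#' @param sep Separator between title and abstract in the offset scheme.
#' @param entities Optional data frame with `start`/`end` character offsets
#'   used for boundary repair.
#' @return Data frame `start`, `end` (0-based, end-exclusive offsets into
#'   `title <sep> abstract`) and `text`, one row per sentence, disjoint and
#'   ordered.
#' @export
split_sentences <- function(document, sep = "\t", entities = NULL) {
  title <- document$title
  abstract <- document$abstract
  full <- paste(title, abstract, sep = sep)
  ranges <- data.frame(start = 0L, end = nchar(title))
  if (nzchar(abstract)) {
    base <- nchar(title) + nchar(sep)
    m <- gregexpr("(?<=[.!?])\\s+", abstract, perl = TRUE)[[1]]
    if (m[1] == -1L) {
      seg_start <- 1L
      seg_end <- nchar(abstract)
    } else {
      ml <- attr(m, "match.length")
      seg_start <- c(1L, m + ml)
      seg_end <- c(m - 1L, nchar(abstract))
    }
    keep <- seg_end >= seg_start
    ranges <- rbind(ranges, data.frame(start = base + seg_start[keep] - 1L,
                                       end = base + seg_end[keep]))
  }
  # boundary repair: merge sentences until every mention fits in one range
  if (!is.null(entities) && nrow(entities) > 0L) {
    repeat {
      merged <- FALSE
      for (k in seq_len(nrow(entities))) {
        hit <- which(ranges$start < entities$end[k] &
                       ranges$end > entities$start[k])
        if (length(hit) > 1L) {
          lo <- min(hit)
          hi <- max(hit)
          ranges <- rbind(
            if (lo > 1L) ranges[seq_len(lo - 1L), ] else NULL,
            data.frame(start = ranges$start[lo], end = ranges$end[hi]),
            if (hi < nrow(ranges)) ranges[(hi + 1L):nrow(ranges), ] else NULL)
          merged <- TRUE
          break
        }
      }
      if (!merged) break
    }
  }
  rownames(ranges) <- NULL
  ranges$text <- substr(rep(full, nrow(ranges)), ranges$start + 1L, ranges$end)
  ranges
}

# whitespace tokenization with absolute 0-based character offsets
tokenize_range <- function(full_text, start, end) {
  text <- substr(full_text, start + 1L, end)
  m <- gregexpr("\\S+", text)[[1]]
  if (m[1] == -1L) {
    return(data.frame(form = character(), start = integer(), end = integer()))
  }
  ml <- attr(m, "match.length")
  data.frame(form = regmatches(text, list(m))[[1]],
             start = start + m - 1L, end = start + m - 1L + ml,
             stringsAsFactors = FALSE)
}

token_span <- function(tok, m_start, m_end) {
  which(tok$start < m_end & tok$end > m_start)
}

new_examples <- function(x, ...) {
  structure(x, class = "cpi_examples", ...)
}

#' @export
print.cpi_examples <- function(x, ...) {
  tab <- table(factor(vapply(x, `[[`, "", "label"), levels = LABEL_SET))
  cat("<cpi_examples> ", length(x), " candidate pairs (",
      paste(names(tab), tab, sep = "=", collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Enumerate sentence-level candidate chemical-gene pairs
#'
#' One example is produced per (chemical mention, gene mention) pair
#' co-occurring in a sentence. The label is the gold CPR group when an
#' evaluated annotation links the pair, and `"NEG"` otherwise (including
#' pairs annotated only with non-evaluated groups). Gold evaluated relations
#' whose arguments sit in different sentences are dropped and counted in the
#' `n_cross_sentence` attribute. Pairs whose mentions occupy exactly the same
#' character span are dropped with a warning. Tokenization is provisional
#' (whitespace); [attach_parses()] replaces it with the parse tokenization.
#'
#' @param corpus A `chemprot_corpus`.
#' @param sentences Optional named list (by `doc_id`) of sentence-boundary
#'   data frames with `start`/`end`, e.g. gold boundaries from the synthetic
#'   generator manifest; computed with [split_sentences()] when absent.
#' @return A `cpi_examples` list of `sentence_example` records, with
#'   attributes `n_cross_sentence` and `n_dropped_pairs`.
#' @export
generate_candidates <- function(corpus, sentences = NULL) {
  text <- doc_text(corpus)
  rel_key <- paste(corpus$relations$doc_id, corpus$relations$arg1_id,
                   corpus$relations$arg2_id)
  rel_group <- stats::setNames(corpus$relations$cpr_group, rel_key)
  examples <- list()
  n_cross <- 0L
  n_dropped <- 0L
  matched_rel <- character(0)

  for (di in seq_len(nrow(corpus$documents))) {
    doc <- corpus$documents[di, ]
    ents <- corpus$entities[corpus$entities$doc_id == doc$doc_id, , drop = FALSE]
    if (nrow(ents) == 0L) next
    ranges <- sentences[[doc$doc_id]] %||%
      split_sentences(doc, corpus$sep, ents)
    sent_of <- vapply(seq_len(nrow(ents)), function(k) {
      hit <- which(ranges$start <= ents$start[k] & ranges$end >= ents$end[k])
      if (length(hit) == 0L) NA_integer_ else hit[1]
    }, integer(1))
    if (anyNA(sent_of)) {
      warnf("document %s: %d mention(s) cross a sentence boundary; skipped",
            doc$doc_id, sum(is.na(sent_of)))
    }
    for (si in sort(unique(stats::na.omit(sent_of)))) {
      here <- which(sent_of == si)
      chems <- here[ents$etype[here] == "CHEMICAL"]
      genes <- here[is_protein_type(ents$etype[here])]
      if (length(chems) == 0L || length(genes) == 0L) next
      tok <- tokenize_range(text[[doc$doc_id]], ranges$start[si], ranges$end[si])
      for (ci in chems) {
        for (gi in genes) {
          if (ents$start[ci] == ents$start[gi] && ents$end[ci] == ents$end[gi]) {
            warnf("document %s: pair %s/%s overlaps completely; dropped",
                  doc$doc_id, ents$entity_id[ci], ents$entity_id[gi])
            n_dropped <- n_dropped + 1L
            next
          }
          key <- paste(doc$doc_id, ents$entity_id[ci], ents$entity_id[gi])
          grp <- if (key %in% names(rel_group)) rel_group[[key]] else NA_character_
          if (!is.na(grp)) matched_rel <- c(matched_rel, key)
          label <- if (!is.na(grp) && grp %in% EVALUATED_GROUPS) grp else NEG_LABEL
          examples[[length(examples) + 1L]] <- structure(list(
            doc_id = doc$doc_id, sent_index = si,
            sent_start = ranges$start[si], sent_end = ranges$end[si],
            sent_text = substr(text[[doc$doc_id]], ranges$start[si] + 1L,
                               ranges$end[si]),
            tokens = tok$form, token_start = tok$start, token_end = tok$end,
            pos_tags = rep(NA_character_, nrow(tok)),
            entity_tags = NULL, heads = NULL,
            chem_id = ents$entity_id[ci], prot_id = ents$entity_id[gi],
            chem_start = ents$start[ci], chem_end = ents$end[ci],
            prot_start = ents$start[gi], prot_end = ents$end[gi],
            chem_span = token_span(tok, ents$start[ci], ents$end[ci]),
            prot_span = token_span(tok, ents$start[gi], ents$end[gi]),
            label = label), class = "sentence_example")
        }
      }
    }
  }
  ev <- corpus$relations[corpus$relations$evaluated, , drop = FALSE]
  ev_key <- paste(ev$doc_id, ev$arg1_id, ev$arg2_id)
  n_cross <- sum(!ev_key %in% matched_rel)
  new_examples(examples, n_cross_sentence = n_cross,
               n_dropped_pairs = n_dropped)
}

apply_examples <- function(x, f, ...) {
  if (inherits(x, "cpi_examples")) {
    out <- lapply(unclass(x), f, ...)
    attributes(out) <- attributes(x)
    return(out)
  }
  f(x, ...)
}

#' Replace digit strings outside the entity mentions with "num"
#'
#' Every maximal digit run in a token not belonging to either argument
#' mention becomes the literal tag `num`; tokens inside the chemical or
#' protein span are left untouched, so digit-bearing entity names survive.
#' The operation is idempotent.
#'
#' @param x A `sentence_example` or a `cpi_examples` collection.
#' @param whole_token If `TRUE`, only tokens consisting entirely of digits
#'   are replaced (the coarser granularity); default replaces digit runs
#'   inside tokens too (`"p53"` becomes `"pnum"`).
#' @export
normalize_digits <- function(x, whole_token = FALSE) {
  apply_examples(x, function(ex) {
    protected <- c(ex$chem_span, ex$prot_span)
    idx <- setdiff(seq_along(ex$tokens), protected)
    if (whole_token) {
      hit <- idx[grepl("^[0-9]+$", ex$tokens[idx])]
      ex$tokens[hit] <- "num"
    } else {
      ex$tokens[idx] <- gsub("[0-9]+", "num", ex$tokens[idx])
    }
    ex
  })
}

#' Assign per-token entity-type tags
#'
#' Tokens of the chemical mention are tagged `chemical`, tokens of the
#' gene/protein mention `gen`, all others `O`. When the two spans overlap
#' (nested mentions), the shorter mention wins on the shared tokens; on equal
#' length the chemical tag wins.
#'
#' @param x A `sentence_example` or a `cpi_examples` collection.
#' @export
tag_entity_types <- function(x) {
  apply_examples(x, function(ex) {
    tags <- rep("O", length(ex$tokens))
    if (length(ex$chem_span) <= length(ex$prot_span)) {
      tags[ex$prot_span] <- "gen"
      tags[ex$chem_span] <- "chemical"
    } else {
      tags[ex$chem_span] <- "chemical"
      tags[ex$prot_span] <- "gen"
    }
    ex$entity_tags <- tags
    ex
  })
}

#' Attach dependency parses to candidate examples
#'
#' Parses are matched to examples by the `doc_id` / `sent_index` comments in
#' the CoNLL-U file. The parse tokenization replaces the provisional one: the
#' token forms are aligned left-to-right against the sentence text (an
#' alignment failure names the sentence), entity character spans are
#' re-projected onto the new tokens, and `heads` / `pos_tags` are filled in.
#'
#' @param examples A `cpi_examples` collection.
#' @param conllu_path Path to the CoNLL-U file.
#' @return The collection with `tokens`, `pos_tags`, `heads`, `chem_span`,
#'   `prot_span` updated.
#' @export
attach_parses <- function(examples, conllu_path) {
  parses <- read_conllu(conllu_path)
  key <- vapply(parses, function(s) paste(s$doc_id, s$sent_index), "")
  if (anyDuplicated(key)) {
    stopf("%s: duplicate parse for sentence %s", conllu_path,
          key[duplicated(key)][1])
  }
  idx <- stats::setNames(seq_along(parses), key)
  apply_examples(examples, function(ex) {
    k <- paste(ex$doc_id, ex$sent_index)
    if (is.na(idx[k])) {
      stopf("no parse for sentence %s (doc %s, sentence %d)", k, ex$doc_id,
            ex$sent_index)
    }
    tokens <- parses[[idx[k]]]$tokens
    # align parse tokens against the sentence text
    text <- ex$sent_text
    cursor <- 1L
    start <- integer(nrow(tokens))
    for (t in seq_len(nrow(tokens))) {
      while (cursor <= nchar(text) && substr(text, cursor, cursor) == " ") {
        cursor <- cursor + 1L
      }
      w <- tokens$form[t]
      if (substr(text, cursor, cursor + nchar(w) - 1L) != w) {
        stopf("parse/text alignment failure in doc %s sentence %d at token %d ('%s')",
              ex$doc_id, ex$sent_index, t, w)
      }
      start[t] <- ex$sent_start + cursor - 1L
      cursor <- cursor + nchar(w)
    }
    tok <- data.frame(form = tokens$form, start = start,
                      end = start + nchar(tokens$form), stringsAsFactors = FALSE)
    heads <- dep_tree(tokens$head)$heads
    ex$tokens <- tok$form
    ex$token_start <- tok$start
    ex$token_end <- tok$end
    ex$pos_tags <- tokens$upos
    ex$heads <- heads
    ex$chem_span <- token_span(tok, ex$chem_start, ex$chem_end)
    ex$prot_span <- token_span(tok, ex$prot_start, ex$prot_end)
    if (length(ex$chem_span) == 0L || length(ex$prot_span) == 0L) {
      stopf("entity span projects onto no parse token in doc %s sentence %d",
            ex$doc_id, ex$sent_index)
    }
    ex$entity_tags <- NULL  # stale after re-tokenization
    ex
  })
}

#' Sentence-example pipeline
#'
#' Convenience wrapper: candidate generation, parse attachment, digit
#' normalization and entity-type tagging in the canonical order.
#'
#' @param corpus A `chemprot_corpus`.
#' @param conllu_path Optional CoNLL-U parse file.
#' @param sentences Optional gold sentence boundaries (see
#'   [generate_candidates()]).
#' @param whole_token Digit-normalization granularity, see
#'   [normalize_digits()].
#' @return A `cpi_examples` collection ready for encoding.
#' @export
prepare_examples <- function(corpus, conllu_path = NULL, sentences = NULL,
                             whole_token = FALSE) {
  ex <- generate_candidates(corpus, sentences)
  if (!is.null(conllu_path)) ex <- attach_parses(ex, conllu_path)
  ex <- normalize_digits(ex, whole_token = whole_token)
  tag_entity_types(ex)
}

#' Specification of the train/development re-split
#'
#' @param seed Integer seed making the split deterministic.
#' @param train_fraction Proportion of documents assigned to training
#'   (default 0.9, the 9:1 re-split).
#' @export
split_spec <- function(seed = 1L, train_fraction = 0.9) {
  if (!(train_fraction > 0 && train_fraction < 1)) {
    stopf("train_fraction must lie strictly between 0 and 1")
  }
  structure(list(seed = as.integer(seed), train_fraction = train_fraction),
            class = "split_spec")
}

#' Document-level train/development re-split
#'
#' Pools the documents present in `examples` and re-splits them 9:1 (or per
#' `spec`) at document level: no document contributes examples to both
#' halves, and the split is deterministic given the seed.
#'
#' @param examples A `cpi_examples` collection.
#' @param spec A [split_spec()].
#' @return List with `train` and `dev` collections.
#' @export
resplit <- function(examples, spec = split_spec()) {
  docs <- sort(unique(vapply(examples, `[[`, "", "doc_id")))
  n <- length(docs)
  if (n < 2L) stopf("need at least two documents to split")
  n_train <- max(1L, min(n - 1L, round(spec$train_fraction * n)))
  train_docs <- with_seed(spec$seed, sample(docs, n_train))
  in_train <- vapply(examples, function(e) e$doc_id %in% train_docs, logical(1))
  list(train = new_examples(unclass(examples)[in_train]),
       dev = new_examples(unclass(examples)[!in_train]))
}

#' Gold relation tuples of a set of examples
#'
#' @param examples A `cpi_examples` collection.
#' @return Unique data frame `doc_id`, `cpr_group`, `arg1_id`, `arg2_id` of
#'   the non-negative examples, the reference side of [micro_f()].
#' @export
gold_relations <- function(examples) {
  pos <- Filter(function(e) e$label != NEG_LABEL, examples)
  out <- data.frame(
    doc_id = vapply(pos, `[[`, "", "doc_id"),
    cpr_group = vapply(pos, `[[`, "", "label"),
    arg1_id = vapply(pos, `[[`, "", "chem_id"),
    arg2_id = vapply(pos, `[[`, "", "prot_id"),
    stringsAsFactors = FALSE
  )
  unique(out)
}

#' Serialize examples as JSON-lines
#'
#' @param examples A `cpi_examples` collection.
#' @param path Output path; one JSON object per line.
#' @export
write_examples_jsonl <- function(examples, path) {
  lines <- vapply(examples, function(e) {
    as.character(jsonlite::toJSON(unclass(e), auto_unbox = TRUE, null = "null"))
  }, "")
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read examples from JSON-lines
#'
#' @param path File written by [write_examples_jsonl()].
#' @return A `cpi_examples` collection.
#' @export
read_examples_jsonl <- function(path) {
  lines <- read_tsv_lines(path)
  new_examples(lapply(lines, function(l) {
    e <- jsonlite::fromJSON(l, simplifyVector = TRUE)
    for (f in c("chem_span", "prot_span", "heads", "token_start", "token_end",
                "sent_index", "sent_start", "sent_end")) {
      if (!is.null(e[[f]])) e[[f]] <- as.integer(e[[f]])
    }
    structure(e, class = "sentence_example")
  }))
}
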