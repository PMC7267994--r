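# Synthetic ChemProt-format corpus generator. Sentences are built from
# templates that carry hand-written dependency structure, so no external
# parser is ever needed: the class of each positive pair is determined by a
# trigger token, distractor clauses hang off the dependency path (exercising
# pruning), digit-bearing entity names exercise the digit-normalization
# exemption, and a fraction of sentences nests a chemical mention inside a
# gene mention (the PART_OF-style tagging case).

TRIGGER_LEXICON <- list(
  "CPR:3" = c("activator", "upregulator"),
  "CPR:4" = c("inhibitor", "downregulator"),
  "CPR:5" = c("agonist"),
  "CPR:6" = c("antagonist"),
  "CPR:9" = c("substrate", "product")
)
NEG_FILLERS <- c("component", "marker", "feature", "aspect")

# Placeholders: {CHEM} chemical surface, {GENE} gene surface, {TRIG} trigger
# or neutral filler, {NUM} a digit token, {CHEM2} second chemical (nested
# template: the gene mention is "{CHEM} receptor" and {CHEM} itself is also
# annotated as a chemical). Heads are 1-indexed, 0 = root.
TEMPLATES <- list(
  copular = list(
    tokens = c("{CHEM}", "is", "a", "{TRIG}", "of", "{GENE}", "."),
    pos = c("NOUN", "AUX", "DET", "NOUN", "ADP", "NOUN", "PUNCT"),
    heads = c(4L, 4L, 4L, 0L, 6L, 4L, 4L),
    distractor = integer(0)
  ),
  copular_distractor = list(
    tokens = c("{CHEM}", "is", "a", "{TRIG}", "of", "{GENE}", "in", "{NUM}",
               "patients", "with", "chronic", "renal", "disease", "."),
    pos = c("NOUN", "AUX", "DET", "NOUN", "ADP", "NOUN", "ADP", "NUM", "NOUN",
            "ADP", "ADJ", "ADJ", "NOUN", "PUNCT"),
    heads = c(4L, 4L, 4L, 0L, 6L, 4L, 9L, 9L, 4L, 13L, 13L, 13L, 9L, 4L),
    distractor = 7:13
  ),
  appositive = list(
    tokens = c("{CHEM}", ",", "a", "potent", "{TRIG}", ",", "targets",
               "{GENE}", "."),
    pos = c("NOUN", "PUNCT", "DET", "ADJ", "NOUN", "PUNCT", "VERB", "NOUN",
            "PUNCT"),
    heads = c(7L, 1L, 5L, 5L, 1L, 1L, 0L, 7L, 7L),
    distractor = integer(0)
  ),
  appositive_distractor = list(
    tokens = c("{CHEM}", ",", "a", "potent", "{TRIG}", ",", "targets",
               "{GENE}", "in", "{NUM}", "trials", "with", "unclear", "dosing",
               "."),
    pos = c("NOUN", "PUNCT", "DET", "ADJ", "NOUN", "PUNCT", "VERB", "NOUN",
            "ADP", "NUM", "NOUN", "ADP", "ADJ", "NOUN", "PUNCT"),
    heads = c(7L, 1L, 5L, 5L, 1L, 1L, 0L, 7L, 11L, 11L, 7L, 14L, 14L, 11L,
              7L),
    distractor = 9:14
  ),
  nested = list(
    tokens = c("{CHEM2}", "is", "a", "{TRIG}", "of", "the", "{CHEM}",
               "receptor", "."),
    pos = c("NOUN", "AUX", "DET", "NOUN", "ADP", "DET", "NOUN", "NOUN",
            "PUNCT"),
    heads = c(4L, 4L, 4L, 0L, 8L, 8L, 8L, 4L, 4L),
    distractor = integer(0)
  )
)

TITLE_TOKENS <- c("Synthetic", "chemical", "protein", "interaction",
                  "abstract", ".")
TITLE_HEADS <- c(0L, 1L, 1L, 1L, 1L, 1L)
TITLE_POS <- c("ADJ", "NOUN", "NOUN", "NOUN", "NOUN", "PUNCT")

#' Simulation specification
#'
#' States the world the generator emulates: number of multi-sentence
#' abstracts, sentences per abstract, the class prevalences over the five
#' evaluated CPR groups plus NEG, the probability that a sentence carries an
#' off-path distractor clause, the probability of a nested
#' chemical-inside-gene mention, and the sentence template pool. The defaults
#' yield roughly 2,000 sentences (400 documents x 4-6 sentences) with a 30%
#' negative rate.
#'
#' @param n_documents Number of abstracts.
#' @param sent_range Integer range (inclusive) of sentences per abstract.
#' @param prevalence Named probabilities over
#'   `c("CPR:3","CPR:4","CPR:5","CPR:6","CPR:9","NEG")`; must sum to 1.
#' @param distractor_prob Probability a sentence uses the distractor variant
#'   of its template.
#' @param nested_prob Probability a sentence uses the nested-mention
#'   template.
#' @param template_pool Base templates to draw from (`"copular"` has the
#'   trigger on the dependency path, `"appositive"` off it).
#' @param seed Integer seed; identical specs give byte-identical output.
#' @export
sim_spec <- function(n_documents = 400L, sent_range = c(4L, 6L),
                     prevalence = c("CPR:3" = 0.14, "CPR:4" = 0.14,
                                    "CPR:5" = 0.14, "CPR:6" = 0.14,
                                    "CPR:9" = 0.14, "NEG" = 0.30),
                     distractor_prob = 0.3, nested_prob = 0.1,
                     template_pool = c("copular", "appositive"),
                     seed = 1L) {
  if (!setequal(names(prevalence), LABEL_SET)) {
    stopf("prevalence must be named over %s", paste(LABEL_SET, collapse = ", "))
  }
  prevalence <- prevalence[LABEL_SET]
  if (any(prevalence < 0) || abs(sum(prevalence) - 1) > 1e-8) {
    stopf("impossible prevalence vector: must be non-negative and sum to 1")
  }
  if (anyDuplicated(unlist(TRIGGER_LEXICON))) {
    stopf("trigger lexicons must be disjoint")  # guards future edits
  }
  if (!all(template_pool %in% c("copular", "appositive"))) {
    stopf("template_pool entries must be 'copular' or 'appositive'")
  }
  structure(list(n_documents = as.integer(n_documents),
                 sent_range = as.integer(sent_range),
                 prevalence = prevalence,
                 distractor_prob = distractor_prob,
                 nested_prob = nested_prob,
                 template_pool = template_pool,
                 seed = as.integer(seed)),
            class = "sim_spec")
}

#' Fixed toy dependency trees used in examples and tests
#'
#' `"svo"` is the 5-token tree with heads `[3,3,0,5,3]`; the remaining ids
#' are the sentence templates of the generator, returned with their entity
#' token spans, trigger token and distractor token set.
#'
#' @param template_id One of `"svo"` or `names(cpigcn:::TEMPLATES)`.
#' @return List with `tree` (a [dep_tree()]), `chem_span`, `prot_span`, and
#'   for generator templates also `trig`, `distractor`.
#' @export
generate_unit_tree <- function(template_id) {
  if (identical(template_id, "svo")) {
    return(list(tree = dep_tree(c(3L, 3L, 0L, 5L, 3L)),
                chem_span = 1L, prot_span = c(4L, 5L)))
  }
  tpl <- TEMPLATES[[template_id]]
  if (is.null(tpl)) stopf("unknown template id '%s'", template_id)
  chem_tok <- which(tpl$tokens == if (is.na(match("{CHEM2}", tpl$tokens)))
    "{CHEM}" else "{CHEM2}")
  gene_tok <- if ("{GENE}" %in% tpl$tokens) {
    which(tpl$tokens == "{GENE}")
  } else {
    which(tpl$tokens == "{CHEM}") + 0:1  # "{CHEM} receptor"
  }
  list(tree = dep_tree(tpl$heads), chem_span = chem_tok,
       prot_span = gene_tok, trig = which(tpl$tokens == "{TRIG}"),
       distractor = tpl$distractor)
}

rand_int <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

#' Generate a synthetic ChemProt-format corpus
#'
#' Writes the abstracts/entities/relations TSV files, a CoNLL-U parse file
#' (templates carry their own parses) and a JSON-lines ground-truth manifest
#' into `dir`, and returns the corresponding in-memory objects. Character
#' offsets satisfy every reader invariant; each positive pair's class is
#' recoverable from its trigger token alone, which is what makes
#' parameter-recovery testing meaningful.
#'
#' @param spec A [sim_spec()].
#' @param dir Output directory (created if needed).
#' @return List with `corpus` (a `chemprot_corpus`), `sentences` (named list
#'   of gold boundary data frames, title included), `manifest` (list of
#'   per-sentence ground-truth records) and `paths`.
#' @export
generate_corpus <- function(spec = sim_spec(), dir = tempfile("simcorpus")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  with_seed(spec$seed, {
    docs <- list()
    ents <- list()
    rels <- list()
    parses <- list()
    sentences <- list()
    manifest <- list()
    title <- paste(TITLE_TOKENS, collapse = " ")
    for (di in seq_len(spec$n_documents)) {
      doc_id <- sprintf("D%04d", di)
      n_sent <- rand_int(spec$sent_range[1], spec$sent_range[2])
      t_counter <- 0L
      sent_texts <- character(n_sent)
      bounds <- data.frame(start = 0L, end = nchar(title))
      parses[[length(parses) + 1L]] <- list(
        doc_id = doc_id, sent_index = 1L,
        tokens = data.frame(id = seq_along(TITLE_TOKENS), form = TITLE_TOKENS,
                            upos = TITLE_POS, head = TITLE_HEADS,
                            stringsAsFactors = FALSE))
      offset <- nchar(title) + 1L  # title + tab separator
      for (si in seq_len(n_sent)) {
        label <- sample(LABEL_SET, 1L, prob = spec$prevalence)
        nested <- stats::runif(1) < spec$nested_prob
        base <- sample(spec$template_pool, 1L)
        tpl_id <- if (nested) {
          "nested"
        } else if (stats::runif(1) < spec$distractor_prob) {
          paste0(base, "_distractor")
        } else {
          base
        }
        tpl <- TEMPLATES[[tpl_id]]
        trig_word <- if (label == NEG_LABEL) {
          sample(NEG_FILLERS, 1L)
        } else {
          lex <- TRIGGER_LEXICON[[label]]
          lex[sample.int(length(lex), 1L)]
        }
        chem_surface <- sprintf("CHM-%d", rand_int(100L, 999L))
        gene_surface <- sprintf("GPR-%d", rand_int(100L, 999L))
        chem2_surface <- sprintf("CHM-%d", rand_int(100L, 999L))
        toks <- tpl$tokens
        toks[toks == "{TRIG}"] <- trig_word
        toks[toks == "{NUM}"] <- as.character(rand_int(10L, 99L))
        toks[toks == "{GENE}"] <- gene_surface
        toks[toks == "{CHEM}"] <- chem_surface
        toks[toks == "{CHEM2}"] <- chem2_surface
        text <- paste(toks, collapse = " ")
        tok_start <- offset + c(0L, cumsum(nchar(toks) + 1L)[-length(toks)])
        tok_end <- tok_start + nchar(toks)

        mk_ent <- function(span, etype) {
          t_counter <<- t_counter + 1L
          s <- min(tok_start[span])
          e <- max(tok_end[span])
          ents[[length(ents) + 1L]] <<- data.frame(
            doc_id = doc_id, entity_id = paste0("T", t_counter),
            etype = etype, start = s, end = e,
            surface = paste(toks[span], collapse = " "),
            stringsAsFactors = FALSE)
          paste0("T", t_counter)
        }
        if (tpl_id == "nested") {
          chem_id <- mk_ent(which(tpl$tokens == "{CHEM2}"), "CHEMICAL")
          gene_span <- which(tpl$tokens == "{CHEM}") + 0:1
          gene_id <- mk_ent(gene_span, "GENE-Y")
          mk_ent(which(tpl$tokens == "{CHEM}"), "CHEMICAL")  # nested mention
        } else {
          chem_id <- mk_ent(which(tpl$tokens == "{CHEM}"), "CHEMICAL")
          gene_id <- mk_ent(which(tpl$tokens == "{GENE}"),
                            sample(c("GENE-Y", "GENE-N"), 1L))
        }
        if (label != NEG_LABEL) {
          rels[[length(rels) + 1L]] <- data.frame(
            doc_id = doc_id, cpr_group = label, evaluated = TRUE,
            arg1_id = chem_id, arg2_id = gene_id, stringsAsFactors = FALSE)
        }
        sent_texts[si] <- text
        bounds <- rbind(bounds, data.frame(start = offset,
                                           end = offset + nchar(text)))
        parses[[length(parses) + 1L]] <- list(
          doc_id = doc_id, sent_index = si + 1L,
          tokens = data.frame(id = seq_along(toks), form = toks,
                              upos = tpl$pos, head = tpl$heads,
                              stringsAsFactors = FALSE))
        manifest[[length(manifest) + 1L]] <- list(
          doc_id = doc_id, sent_index = si + 1L, start = offset,
          end = offset + nchar(text), template = tpl_id, label = label,
          trigger = trig_word, n_tokens = length(toks),
          distractor_tokens = tpl$distractor,
          chem_id = chem_id, gene_id = gene_id)
        offset <- offset + nchar(text) + 1L  # joining space
      }
      docs[[di]] <- data.frame(doc_id = doc_id, title = title,
                               abstract = paste(sent_texts, collapse = " "),
                               stringsAsFactors = FALSE)
      sentences[[doc_id]] <- bounds
    }
    corpus <- structure(list(
      documents = do.call(rbind, docs),
      entities = do.call(rbind, ents),
      relations = if (length(rels) > 0) do.call(rbind, rels) else
        data.frame(doc_id = character(), cpr_group = character(),
                   evaluated = logical(), arg1_id = character(),
                   arg2_id = character(), stringsAsFactors = FALSE),
      sep = "\t"), class = "chemprot_corpus")
    paths <- list(abstracts = file.path(dir, "abstracts.tsv"),
                  entities = file.path(dir, "entities.tsv"),
                  relations = file.path(dir, "relations.tsv"),
                  conllu = file.path(dir, "parses.conllu"),
                  manifest = file.path(dir, "manifest.jsonl"))
    write_corpus(corpus, paths$abstracts, paths$entities, paths$relations)
    write_conllu(parses, paths$conllu)
    writeLines(vapply(manifest, function(m) {
      as.character(jsonlite::toJSON(m, auto_unbox = TRUE))
    }, ""), paths$manifest, useBytes = TRUE)
    list(corpus = corpus, sentences = sentences, manifest = manifest,
         paths = paths)
  })
}
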