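test_that("sentence splitting produces ordered disjoint ranges", {
  doc <- list(title = "T .", abstract = "A is B. C is D.")
  s <- split_sentences(doc)
  expect_equal(nrow(s), 3L)  # title + two sentences
  expect_equal(s$text, c("T .", "A is B.", "C is D."))
  expect_true(all(diff(s$start) > 0))
  expect_true(all(s$end[-nrow(s)] <= s$start[-1]))

  # empty abstract: title-only list
  expect_equal(nrow(split_sentences(list(title = "T .", abstract = ""))), 1L)
})

test_that("a mention spanning a split point repairs the boundary", {
  doc <- list(title = "T .", abstract = "Binds IL. 6 receptor strongly. Done.")
  ents <- data.frame(start = 10L, end = 24L)  # "IL. 6 receptor"
  s <- split_sentences(doc, entities = ents)
  hit <- which(s$start <= ents$start & s$end >= ents$end)
  expect_length(hit, 1L)
  # without the entity the same text splits one sentence earlier
  expect_gt(nrow(split_sentences(doc)), nrow(s))
})

test_that("generator boundaries match the default splitter", {
  sim <- generate_corpus(sim_spec(n_documents = 3, seed = 5),
                         dir = withr::local_tempdir())
  for (di in seq_len(3)) {
    doc <- sim$corpus$documents[di, ]
    got <- split_sentences(doc)
    want <- sim$sentences[[doc$doc_id]]
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
  }
})

test_that("candidate generation enumerates pairs and labels them", {
  fx <- write_fixture_corpus()
  cp <- read_corpus(fx$abstracts, fx$entities, fx$relations)
  ex <- generate_candidates(cp)
  expect_length(ex, 2L)
  labels <- vapply(ex, `[[`, "", "label")
  expect_setequal(labels, c("CPR:6", "NEG"))
  expect_equal(attr(ex, "n_cross_sentence"), 0L)

  # sentence with 2 chemicals and 1 gene, no relations -> 2 NEG examples
  dir <- withr::local_tempdir()
  writeLines("D1\tT .\tCHM-1 and CHM-2 bind GPX .", file.path(dir, "a.tsv"))
  writeLines(c("D1\tT1\tCHEMICAL\t4\t9\tCHM-1",
               "D1\tT2\tCHEMICAL\t14\t19\tCHM-2",
               "D1\tT3\tGENE-Y\t25\t28\tGPX"),
             file.path(dir, "e.tsv"))
  writeLines(character(0), file.path(dir, "r.tsv"))
  cp2 <- read_corpus(file.path(dir, "a.tsv"), file.path(dir, "e.tsv"),
                     file.path(dir, "r.tsv"))
  ex2 <- generate_candidates(cp2)
  expect_length(ex2, 2L)
  expect_true(all(vapply(ex2, `[[`, "", "label") == "NEG"))
})

test_that("completely overlapping mention pairs are dropped with a warning", {
  dir <- withr::local_tempdir()
  writeLines("D1\tT .\tABC1 works alone .", file.path(dir, "a.tsv"))
  writeLines(c("D1\tT1\tCHEMICAL\t4\t8\tABC1",
               "D1\tT2\tGENE-Y\t4\t8\tABC1"),
             file.path(dir, "e.tsv"))
  writeLines(character(0), file.path(dir, "r.tsv"))
  cp <- read_corpus(file.path(dir, "a.tsv"), file.path(dir, "e.tsv"),
                    file.path(dir, "r.tsv"))
  expect_warning(ex <- generate_candidates(cp), "overlaps completely")
  expect_length(ex, 0L)
  expect_equal(attr(ex, "n_dropped_pairs"), 1L)
})

test_that("cross-sentence gold relations yield no example and are counted", {
  dir <- withr::local_tempdir()
  writeLines("D1\tT .\tCHM-1 binds . GPX waits .", file.path(dir, "a.tsv"))
  writeLines(c("D1\tT1\tCHEMICAL\t4\t9\tCHM-1",
               "D1\tT2\tGENE-Y\t18\t21\tGPX"),
             file.path(dir, "e.tsv"))
  writeLines("D1\tCPR:4\tY\tArg1:T1\tArg2:T2", file.path(dir, "r.tsv"))
  cp <- read_corpus(file.path(dir, "a.tsv"), file.path(dir, "e.tsv"),
                    file.path(dir, "r.tsv"))
  ex <- generate_candidates(cp)
  expect_length(ex, 0L)
  expect_equal(attr(ex, "n_cross_sentence"), 1L)
})

test_that("candidate count equals sum over sentences of #chem x #gene", {
  sim <- generate_corpus(sim_spec(n_documents = 10, seed = 11,
                                  nested_prob = 0.5),
                         dir = withr::local_tempdir())
  ex <- generate_candidates(sim$corpus, sentences = sim$sentences)
  # per manifest sentence: 1 chem x 1 gene, nested adds a second chem
  want <- sum(vapply(sim$manifest, function(m) {
    if (m$template == "nested") 2L else 1L
  }, integer(1)))
  expect_length(ex, want - attr(ex, "n_dropped_pairs"))
  expect_equal(attr(ex, "n_dropped_pairs"), 0L)
})

test_that("digit normalization replaces runs outside entities, idempotently", {
  ex <- structure(list(tokens = c("CHM-354", "binds", "50", "p53", "GPX-1"),
                       chem_span = 1L, prot_span = 5L),
                  class = "sentence_example")
  out <- normalize_digits(ex)
  expect_equal(out$tokens, c("CHM-354", "binds", "num", "pnum", "GPX-1"))
  expect_equal(normalize_digits(out)$tokens, out$tokens)  # idempotent

  whole <- normalize_digits(ex, whole_token = TRUE)
  expect_equal(whole$tokens, c("CHM-354", "binds", "num", "p53", "GPX-1"))
})

test_that("entity-type tagging marks spans, shorter mention winning overlap", {
  ex <- structure(list(tokens = letters[1:5], chem_span = 1L,
                       prot_span = 4:5), class = "sentence_example")
  expect_equal(tag_entity_types(ex)$entity_tags,
               c("chemical", "O", "O", "gen", "gen"))

  # nested chemical inside the gene mention: inner token tagged chemical
  nested <- structure(list(tokens = letters[1:4], chem_span = 2L,
                           prot_span = 2:3), class = "sentence_example")
  expect_equal(tag_entity_types(nested)$entity_tags,
               c("O", "chemical", "gen", "O"))
})

test_that("attach_parses replaces tokenization and projects spans", {
  sim <- generate_corpus(sim_spec(n_documents = 2, seed = 3),
                         dir = withr::local_tempdir())
  ex <- generate_candidates(sim$corpus, sentences = sim$sentences)
  ex2 <- attach_parses(ex, sim$paths$conllu)
  man <- sim$manifest
  for (k in seq_along(ex2)) {
    e <- ex2[[k]]
    m <- Filter(function(m) m$doc_id == e$doc_id &&
                  m$sent_index == e$sent_index, man)[[1]]
    expect_length(e$heads, m$n_tokens)
    expect_length(e$tokens, m$n_tokens)
    expect_equal(sum(e$heads == 0L), 1L)
    expect_gt(length(e$chem_span), 0L)
    expect_gt(length(e$prot_span), 0L)
  }
  # an entity char span covering 2 tokens projects to a token span of size 2
  nested_sim <- generate_corpus(sim_spec(n_documents = 4, seed = 9,
                                         nested_prob = 1),
                                dir = withr::local_tempdir())
  nex <- attach_parses(generate_candidates(nested_sim$corpus,
                                           nested_sim$sentences),
                       nested_sim$paths$conllu)
  spans <- lapply(nex, `[[`, "prot_span")
  expect_true(any(lengths(spans) == 2L))

  # wrong metadata -> alignment failure naming the sentence
  bad <- read_conllu(sim$paths$conllu)
  idx <- vapply(bad, function(s) s$sent_index, integer(1))
  swap <- which(idx > 1L)[1:2]
  tmp <- bad[[swap[1]]]$sent_index
  bad[[swap[1]]]$sent_index <- bad[[swap[2]]]$sent_index
  bad[[swap[2]]]$sent_index <- tmp
  badpath <- withr::local_tempfile(fileext = ".conllu")
  write_conllu(bad, badpath)
  expect_error(attach_parses(ex, badpath), "alignment failure")
})

test_that("resplit is by document, 9:1, and deterministic", {
  sim <- generate_corpus(sim_spec(n_documents = 10, seed = 2),
                         dir = withr::local_tempdir())
  ex <- prepare_examples(sim$corpus, sim$paths$conllu,
                         sentences = sim$sentences)
  halves <- resplit(ex, split_spec(seed = 4))
  train_docs <- unique(vapply(halves$train, `[[`, "", "doc_id"))
  dev_docs <- unique(vapply(halves$dev, `[[`, "", "doc_id"))
  expect_length(train_docs, 9L)
  expect_length(dev_docs, 1L)
  expect_length(intersect(train_docs, dev_docs), 0L)

  halves2 <- resplit(ex, split_spec(seed = 4))
  expect_identical(vapply(halves2$train, `[[`, "", "doc_id"),
                   vapply(halves$train, `[[`, "", "doc_id"))

  # no doc in both halves across many random splits
  for (s in 1:100) {
    h <- resplit(ex, split_spec(seed = s))
    expect_length(intersect(unique(vapply(h$train, `[[`, "", "doc_id")),
                            unique(vapply(h$dev, `[[`, "", "doc_id"))), 0L)
  }
})

test_that("examples survive a JSON-lines round trip", {
  ex <- fixture_examples(n_documents = 2L, seed = 13L)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_examples_jsonl(ex, path)
  back <- read_examples_jsonl(path)
  expect_length(back, length(ex))
  for (f in c("tokens", "heads", "chem_span", "prot_span", "label")) {
    expect_equal(back[[3]][[f]], ex[[3]][[f]])
  }
})
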