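test_that("micro_f matches hand-worked cases", {
  gold <- data.frame(doc_id = c("D1", "D1", "D2", "D2", "D3"),
                     cpr_group = c("CPR:3", "CPR:4", "CPR:4", "CPR:9", "CPR:6"),
                     arg1_id = "T1", arg2_id = "T2")
  # perfect predictions
  ev <- micro_f(gold, gold)
  expect_equal(c(ev$precision, ev$recall, ev$f), c(100, 100, 100))

  # TP=2, FP=1, FN=3 -> P=66.67, R=40.00, F=50.00
  pred <- rbind(gold[1:2, ],
                data.frame(doc_id = "D9", cpr_group = "CPR:5",
                           arg1_id = "T1", arg2_id = "T2"))
  ev <- micro_f(gold, pred)
  expect_equal(c(ev$tp, ev$fp, ev$fn), c(2, 1, 3))
  expect_equal(ev$precision, 200 / 3, tolerance = 1e-10)
  expect_equal(ev$recall, 40)
  expect_equal(ev$f, 50)

  # zero-denominator rule
  ev0 <- micro_f(gold, random_tuples(0L))
  expect_equal(c(ev0$precision, ev0$recall, ev0$f), c(0, 0, 0))

  # duplicates count once; non-evaluated predictions are an error
  ev_dup <- micro_f(gold, rbind(gold[1, ], gold[1, ]))
  expect_equal(ev_dup$tp, 1)
  bad <- data.frame(doc_id = "D1", cpr_group = "CPR:1", arg1_id = "T1",
                    arg2_id = "T2")
  expect_error(micro_f(gold, bad), "non-evaluated")

  # per-class counts pool to the micro counts
  ev <- micro_f(gold, pred)
  expect_equal(sum(ev$per_class$tp), ev$tp)
  expect_equal(sum(ev$per_class$fn), ev$fn)
})

test_that("adding a correct prediction never decreases F", {
  set.seed(12)
  for (rep in 1:50) {
    gold <- unique(random_tuples(sample(2:10, 1)))
    pred <- unique(random_tuples(sample(0:10, 1)))
    missing <- gold[!do.call(paste, gold) %in% do.call(paste, pred), ,
                    drop = FALSE]
    if (nrow(missing) == 0L) next
    f0 <- micro_f(gold, pred)$f
    f1 <- micro_f(gold, rbind(pred, missing[1, ]))$f
    expect_gte(f1, f0)
  }
})

test_that("training loss decreases on separable data and is reproducible", {
  sim <- generate_corpus(sim_spec(n_documents = 40, seed = 21),
                         dir = withr::local_tempdir())
  ex <- prepare_examples(sim$corpus, sim$paths$conllu,
                         sentences = sim$sentences)
  expect_gte(length(ex), 200L)
  halves <- resplit(ex, split_spec(seed = 21))
  cfg <- model_config(word_dim = 16, pos_dim = 4, etype_dim = 4,
                      lstm_hidden = 16, gcn_hidden = 16, ffnn_hidden = 16,
                      dropout = 0)
  m <- train_cpi(halves$train, halves$dev, cfg,
                 train_spec(max_epochs = 3L, seed = 21L))
  expect_true(all(diff(m$history$loss) < 0))

  # same seed twice -> identical history
  m2 <- train_cpi(halves$train, halves$dev, cfg,
                  train_spec(max_epochs = 3L, seed = 21L))
  expect_identical(m2$history, m$history)
})

test_that("negative downsampling trains and stays deterministic", {
  ex <- fixture_examples(n_documents = 4L)
  halves <- resplit(ex, split_spec(seed = 9))
  sp <- train_spec(max_epochs = 2L, neg_keep = 0.5, seed = 9L)
  m1 <- train_cpi(halves$train, halves$dev, tiny_config(), sp)
  m2 <- train_cpi(halves$train, halves$dev, tiny_config(), sp)
  expect_identical(m1$history, m2$history)
  expect_error(train_spec(neg_keep = 0), "neg_keep")
})

test_that("early stopping honours patience", {
  ex <- fixture_examples(n_documents = 4L)
  halves <- resplit(ex, split_spec(seed = 3))
  # learning rate ~0: dev F can never improve after the first evaluation
  m <- train_cpi(halves$train, halves$dev, tiny_config(),
                 train_spec(learning_rate = 1e-9, max_epochs = 10L,
                            patience = 1L, seed = 3L))
  expect_equal(nrow(m$history), 2L)
})

test_that("predict emits only evaluated classes and respects NEG", {
  ex <- fixture_examples(n_documents = 4L)
  halves <- resplit(ex, split_spec(seed = 2))
  model <- train_cpi(halves$train, halves$dev, tiny_config(),
                     train_spec(max_epochs = 2L, seed = 2L))
  preds <- predict(model, halves$dev)
  expect_lte(nrow(preds), length(halves$dev))
  expect_true(all(preds$cpr_group %in% evaluated_groups()))
  expect_equal(anyDuplicated(do.call(paste, preds)), 0L)

  # a model whose output layer always prefers NEG predicts nothing
  neg_model <- model
  neg_model$params$out$W[] <- 0
  neg_model$params$out$b <- c(0, 0, 0, 0, 0, 100)
  expect_equal(nrow(predict(neg_model, halves$dev)), 0L)
})

test_that("sweep produces one deterministic row per variant", {
  ex <- fixture_examples(n_documents = 6L)
  halves <- resplit(ex, split_spec(seed = 5))
  sp <- train_spec(max_epochs = 2L, seed = 5L)

  grid_n <- list("N=0" = tiny_config(prune_dist = 0),
                 "N=2" = tiny_config(prune_dist = 2))
  tab <- sweep_cpi(grid_n, halves$train, halves$dev, sp)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$variant, c("N=0", "N=2"))

  tab2 <- sweep_cpi(grid_n, halves$train, halves$dev, sp)
  expect_identical(tab2, tab)

  # the embedding-feature ablation axis
  grid_feat <- list(
    word = tiny_config(use_pos = FALSE, use_etype = FALSE),
    word_pos = tiny_config(use_etype = FALSE),
    word_etype = tiny_config(use_pos = FALSE),
    word_pos_etype = tiny_config()
  )
  tab3 <- sweep_cpi(grid_feat, halves$train, halves$dev, sp)
  expect_equal(nrow(tab3), 4L)
  expect_true(all(is.finite(tab3$f)))
})
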