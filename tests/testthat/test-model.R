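test_that("embedding concatenation has the configured width", {
  ex <- fixture_examples(n_documents = 2L)
  cfg <- model_config()  # full-scale dims: 200 + 20 + 60
  vocab <- build_vocab(ex)
  params <- init_params(cfg, vocab, seed = 5)
  enc <- encode_examples(ex, vocab, cfg)
  X <- embed(enc[[1]], params, cfg)
  expect_equal(dim(X), c(enc[[1]]$n, 280L))

  cfg2 <- model_config(use_pos = FALSE, use_etype = FALSE)
  p2 <- init_params(cfg2, vocab, seed = 5)
  expect_equal(ncol(embed(encode_examples(ex, vocab, cfg2)[[1]], p2, cfg2)),
               200L)

  # unseen token maps to the unknown row
  enc1 <- enc[[1]]
  enc1$word[1] <- 2L  # what lookup_ids assigns to OOV
  expect_equal(embed(enc1, params, cfg)[1, 1:200],
               params$emb$word[2L, ])
})

test_that("word vectors load and seed the embedding table", {
  path <- withr::local_tempfile(fileext = ".vec")
  writeLines(c("2 4", "inhibitor 0.1 0.2 0.3 0.4", "agonist 1 2 3 4"), path)
  M <- load_word_vectors(path)
  expect_equal(dim(M), c(2L, 4L))
  expect_equal(M["agonist", ], c(1, 2, 3, 4))

  vocab <- list(words = c("<pad>", "<unk>", "agonist", "zzz"),
                pos = c("<pad>", "<unk>", "NOUN"),
                etype = c("<pad>", "<unk>", "chemical", "gen", "O"))
  cfg <- model_config(word_dim = 4, pos_dim = 2, etype_dim = 2,
                      lstm_hidden = 3, gcn_hidden = 3, ffnn_hidden = 3)
  params <- init_params(cfg, vocab, word_vectors = M, seed = 1)
  expect_equal(params$emb$word[3, ], c(1, 2, 3, 4))
  expect_true(all(abs(params$emb$word[4, ]) <= 0.25))  # random fallback
  expect_equal(params$emb$word[1, ], rep(0, 4))        # padding row
})

test_that("Bi-LSTM output is the two-direction concatenation, deterministic", {
  ex <- fixture_examples(n_documents = 2L)
  cfg <- model_config()
  vocab <- build_vocab(ex)
  params <- init_params(cfg, vocab, seed = 5)
  X <- embed(encode_examples(ex, vocab, cfg)[[1]], params, cfg)
  H <- encode_bilstm(X, params)
  expect_equal(ncol(H), 400L)  # 2 x 200 hidden units
  expect_identical(H, encode_bilstm(X, params))
  expect_true(all(is.finite(H)))
})

test_that("gcn_forward satisfies identity and symmetry contracts", {
  # isolated node, W = identity, b = 0: output equals (non-negative) input
  g1 <- build_adjacency(dep_tree(0L), 1L)
  H1 <- matrix(abs(rnorm(4)), 1, 4)
  p1 <- list(list(W = diag(4), b = rep(0, 4)))
  expect_equal(gcn_forward(H1, g1, p1), H1)

  # two connected nodes with equal inputs get equal outputs
  g2 <- build_adjacency(dep_tree(c(0L, 1L)), 1:2)
  H2 <- rbind(c(1, -2, 3), c(1, -2, 3))
  p2 <- list(list(W = matrix(rnorm(9), 3), b = rnorm(3)))
  out <- gcn_forward(H2, g2, p2)
  expect_equal(out[1, ], out[2, ])

  expect_error(gcn_forward(matrix(0, 3, 2), g2, p2), "3 rows")
  expect_error(gcn_forward(matrix(0, 2, 5), g2, p2), "input dim")
})

test_that("pool_and_classify is a proper softmax with max-pool routing", {
  set.seed(31)
  HL <- matrix(rnorm(24), 6, 4)
  params <- list(ffnn = list(W = matrix(rnorm(48), 12, 4), b = rnorm(4)),
                 out = list(W = matrix(rnorm(24), 4, 6), b = rnorm(6)))
  pr <- pool_and_classify(HL, 2:3, 5L, 1:6, params)
  expect_equal(sum(pr), 1)
  expect_true(all(pr >= 0))
  expect_named(pr, cpi_labels())

  # permutation invariance of the pooled sets
  perm <- sample(6)
  pr2 <- pool_and_classify(HL[perm, ], which(perm %in% 2:3),
                           which(perm == 5), 1:6, params)
  expect_equal(unname(pr2), unname(pr))

  # zeroed output layer -> uniform distribution
  params0 <- params
  params0$out <- list(W = matrix(0, 4, 6), b = rep(0, 6))
  expect_equal(unname(pool_and_classify(HL, 2:3, 5L, 1:6, params0)),
               rep(1 / 6, 6))

  expect_error(pool_and_classify(HL, 2:3, 5L, integer(0), params),
               "empty kept set")
})

test_that("ablation switches all run end-to-end with finite probabilities", {
  ex <- fixture_examples(n_documents = 3L)
  grid <- list(
    full = tiny_config(),
    bilstm_only = tiny_config(use_gcn = FALSE),
    gcn_only = tiny_config(use_bilstm = FALSE),
    word_only = tiny_config(use_pos = FALSE, use_etype = FALSE),
    whole_sentence_pool = tiny_config(pool_kept_only = FALSE),
    deep = tiny_config(gcn_layers = 3L, prune_dist = Inf)
  )
  for (nm in names(grid)) {
    cfg <- grid[[nm]]
    vocab <- build_vocab(ex)
    params <- init_params(cfg, vocab, seed = 2)
    enc <- encode_examples(ex, vocab, cfg)
    for (e in enc) {
      probs <- cpigcn:::cpi_forward(e, params, cfg)$probs
      expect_true(all(is.finite(probs)), info = nm)
      expect_equal(sum(probs), 1, info = nm)
    }
  }
})

test_that("analytic gradients match finite differences", {
  ex <- fixture_examples(n_documents = 2L)
  cfg <- tiny_config(dropout = 0)
  vocab <- build_vocab(ex)
  params <- init_params(cfg, vocab, seed = 11)
  enc <- encode_examples(ex, vocab, cfg)[[2]]
  loss <- function(p) {
    -log(cpigcn:::cpi_forward(enc, p, cfg)$probs[enc$label_id])
  }
  grads <- cpigcn:::cpi_backward(cpigcn:::cpi_forward(enc, params, cfg), params)
  eps <- 1e-6
  set.seed(4)
  leaves <- list(c("out", "W"), c("out", "b"), c("ffnn", "W"), c("ffnn", "b"),
                 c("lstm_fw", "Wx"), c("lstm_fw", "Wh"), c("lstm_fw", "b"),
                 c("lstm_bw", "Wx"), c("lstm_bw", "Wh"))
  for (leaf in leaves) {
    for (r in 1:3) {
      i <- sample(length(params[[leaf[1]]][[leaf[2]]]), 1)
      bump <- function(d) {
        p <- params
        p[[leaf[1]]][[leaf[2]]][i] <- p[[leaf[1]]][[leaf[2]]][i] + d
        p
      }
      num <- (loss(bump(eps)) - loss(bump(-eps))) / (2 * eps)
      expect_equal(grads[[leaf[1]]][[leaf[2]]][i], num, tolerance = 1e-4,
                   info = paste(leaf, collapse = "$"))
    }
  }
  for (l in seq_len(cfg$gcn_layers)) {
    i <- sample(length(params$gcn[[l]]$W), 1)
    bump <- function(d) {
      p <- params
      p$gcn[[l]]$W[i] <- p$gcn[[l]]$W[i] + d
      p
    }
    num <- (loss(bump(eps)) - loss(bump(-eps))) / (2 * eps)
    expect_equal(grads$gcn[[l]]$W[i], num, tolerance = 1e-4)
  }
  # sparse embedding gradient rows
  wid <- grads$emb$word$ids[2]
  bump <- function(d) {
    p <- params
    p$emb$word[wid, 3] <- p$emb$word[wid, 3] + d
    p
  }
  num <- (loss(bump(eps)) - loss(bump(-eps))) / (2 * eps)
  expect_equal(unname(grads$emb$word$G[2, 3]), num, tolerance = 1e-4)
})

test_that("checkpoints embed the config and restore predictions", {
  ex <- fixture_examples(n_documents = 4L)
  halves <- resplit(ex, split_spec(seed = 1))
  model <- train_cpi(halves$train, halves$dev, tiny_config(),
                     train_spec(max_epochs = 2L, seed = 1L))
  path <- withr::local_tempfile(fileext = ".rds")
  save_cpi_model(model, path)
  back <- load_cpi_model(path)
  expect_equal(back$config, model$config)
  expect_equal(predict(back, halves$dev), predict(model, halves$dev))
})
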