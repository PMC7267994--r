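# The neural scoring function: embedding concatenation, Bi-LSTM contextual
# encoder, L-layer degree-normalized GCN with self-loops, entity-aware
# max-pooling, FFNN and softmax classifier. Everything is plain base-R linear
# algebra; matrices are row-per-token. Gradients live in backprop.R.

#' Model configuration
#'
#' Collects every architecture hyperparameter: embedding dimensions (word
#' 200, POS 20, entity type 60), LSTM and GCN hidden sizes (200 each), the
#' learning-relevant dropout rate (0.5), the number of GCN layers `L`, the
#' path-centric pruning distance `N`, and the feature/ablation switches. The
#' defaults are the tuned full-scale values; tests and desk-scale runs shrink
#' the dimensions.
#'
#' @param word_dim,pos_dim,etype_dim Embedding dimensions.
#' @param lstm_hidden Hidden units per LSTM direction (output is doubled).
#' @param gcn_hidden GCN hidden units per layer.
#' @param gcn_layers Number of GCN layers `L` (>= 1).
#' @param prune_dist Pruning distance `N` (non-negative integer or `Inf`).
#' @param dropout Dropout rate applied to embeddings and between GCN layers
#'   during training.
#' @param n_classes Output classes; fixed at 6 (five CPR groups + NEG).
#' @param use_pos,use_etype Feature switches for the POS and entity-type
#'   embeddings (the embedding-ablation axis).
#' @param use_bilstm,use_gcn Module switches: disabling one yields the
#'   single-model ablations (GCN over raw embeddings, or Bi-LSTM alone).
#' @param ffnn_hidden Width of the FFNN hidden layer; defaults to
#'   `gcn_hidden`.
#' @param pool_kept_only If `TRUE` (default) the sentence representation
#'   max-pools over the kept (pruned-tree) tokens only; `FALSE` pools over
#'   the whole sentence.
#' @return A `model_config` list.
#' @export
model_config <- function(word_dim = 200L, pos_dim = 20L, etype_dim = 60L,
                         lstm_hidden = 200L, gcn_hidden = 200L,
                         gcn_layers = 2L, prune_dist = 2, dropout = 0.5,
                         n_classes = 6L, use_pos = TRUE, use_etype = TRUE,
                         use_bilstm = TRUE, use_gcn = TRUE,
                         ffnn_hidden = NULL, pool_kept_only = TRUE) {
  cfg <- list(word_dim = as.integer(word_dim), pos_dim = as.integer(pos_dim),
              etype_dim = as.integer(etype_dim),
              lstm_hidden = as.integer(lstm_hidden),
              gcn_hidden = as.integer(gcn_hidden),
              gcn_layers = as.integer(gcn_layers), prune_dist = prune_dist,
              dropout = dropout, n_classes = as.integer(n_classes),
              use_pos = use_pos, use_etype = use_etype,
              use_bilstm = use_bilstm, use_gcn = use_gcn,
              ffnn_hidden = as.integer(ffnn_hidden %||% gcn_hidden),
              pool_kept_only = pool_kept_only)
  dims <- unlist(cfg[c("word_dim", "pos_dim", "etype_dim", "lstm_hidden",
                       "gcn_hidden", "ffnn_hidden")])
  if (any(dims <= 0L)) stopf("all dimensions must be positive")
  if (cfg$gcn_layers < 1L) stopf("gcn_layers must be >= 1")
  if (cfg$n_classes != 6L) stopf("n_classes is fixed at 6 (five CPR + NEG)")
  if (!(cfg$dropout >= 0 && cfg$dropout < 1)) stopf("dropout must be in [0,1)")
  if (!is.infinite(cfg$prune_dist) && cfg$prune_dist < 0) {
    stopf("prune_dist must be >= 0 or Inf")
  }
  structure(cfg, class = "model_config")
}

input_dim <- function(cfg) {
  cfg$word_dim + (if (cfg$use_pos) cfg$pos_dim else 0L) +
    (if (cfg$use_etype) cfg$etype_dim else 0L)
}
enc_dim <- function(cfg) if (cfg$use_bilstm) 2L * cfg$lstm_hidden else input_dim(cfg)
pool_dim <- function(cfg) if (cfg$use_gcn) cfg$gcn_hidden else enc_dim(cfg)

PAD_ID <- 1L
UNK_ID <- 2L

#' Build vocabularies from training examples
#'
#' Index 1 is reserved for padding and index 2 for unknown tokens in each
#' table (word, POS, entity type); unseen symbols at prediction time map to
#' the unknown row.
#'
#' @param examples A `cpi_examples` collection (tagged, parsed).
#' @return List of character vectors `words`, `pos`, `etype`.
#' @export
build_vocab <- function(examples) {
  words <- sort(unique(unlist(lapply(examples, `[[`, "tokens"))))
  pos <- sort(unique(stats::na.omit(unlist(lapply(examples, `[[`, "pos_tags")))))
  list(words = c("<pad>", "<unk>", words),
       pos = c("<pad>", "<unk>", pos),
       etype = c("<pad>", "<unk>", "chemical", "gen", "O"))
}

#' Load pretrained word vectors in word2vec/FastText text format
#'
#' First line `vocab_size dim`, then one token and `dim` numbers per line.
#'
#' @param path Path to the text-format vectors.
#' @return Numeric matrix with tokens as row names.
#' @export
load_word_vectors <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  header <- as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(header) != 2L || anyNA(header)) {
    stopf("%s: expected 'vocab_size dim' header line", path)
  }
  body <- lines[-1][nzchar(lines[-1])]
  parts <- strsplit(body, "\\s+")
  bad <- which(lengths(parts) != header[2] + 1L)
  if (length(bad) > 0L) stopf("%s: malformed vector line %d", path, bad[1] + 1L)
  M <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(header[2])))
  rownames(M) <- vapply(parts, `[[`, "", 1L)
  M
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Initialize a parameter bundle
#'
#' Word embeddings are copied from `word_vectors` where the vocabulary
#' matches and otherwise drawn uniformly from \[-0.25, 0.25\]; POS and
#' entity-type embeddings are always random. Linear layers use
#' Glorot-uniform initialization and the LSTM forget-gate bias starts at 1.
#' The padding rows are zero and stay zero during training.
#'
#' @param config A [model_config()].
#' @param vocab A [build_vocab()] result.
#' @param word_vectors Optional matrix from [load_word_vectors()].
#' @param seed Integer seed for the random draws.
#' @return Nested list of parameter matrices (`emb`, `lstm_fw`, `lstm_bw`,
#'   `gcn`, `ffnn`, `out`).
#' @export
init_params <- function(config, vocab, word_vectors = NULL, seed = 1L) {
  with_seed(seed, {
    V <- length(vocab$words)
    emb <- list(word = matrix(stats::runif(V * config$word_dim, -0.25, 0.25),
                              V, config$word_dim))
    if (!is.null(word_vectors)) {
      if (ncol(word_vectors) != config$word_dim) {
        stopf("word vectors have dim %d but config$word_dim is %d",
              ncol(word_vectors), config$word_dim)
      }
      hit <- intersect(vocab$words, rownames(word_vectors))
      emb$word[match(hit, vocab$words), ] <- word_vectors[hit, , drop = FALSE]
    }
    emb$pos <- matrix(stats::runif(length(vocab$pos) * config$pos_dim, -0.25, 0.25),
                      length(vocab$pos), config$pos_dim)
    emb$etype <- matrix(stats::runif(length(vocab$etype) * config$etype_dim,
                                     -0.25, 0.25),
                        length(vocab$etype), config$etype_dim)
    emb$word[PAD_ID, ] <- 0
    emb$pos[PAD_ID, ] <- 0
    emb$etype[PAD_ID, ] <- 0

    D <- input_dim(config)
    H <- config$lstm_hidden
    mk_lstm <- function() {
      b <- numeric(4L * H)
      b[(H + 1L):(2L * H)] <- 1  # forget-gate bias
      list(Wx = glorot(D, 4L * H), Wh = glorot(H, 4L * H), b = b)
    }
    params <- list(emb = emb)
    if (config$use_bilstm) {
      params$lstm_fw <- mk_lstm()
      params$lstm_bw <- mk_lstm()
    }
    if (config$use_gcn) {
      g <- config$gcn_hidden
      ins <- c(enc_dim(config), rep(g, config$gcn_layers - 1L))
      params$gcn <- lapply(ins, function(nin) {
        list(W = glorot(nin, g), b = numeric(g))
      })
    }
    p3 <- 3L * pool_dim(config)
    params$ffnn <- list(W = glorot(p3, config$ffnn_hidden),
                        b = numeric(config$ffnn_hidden))
    params$out <- list(W = glorot(config$ffnn_hidden, config$n_classes),
                       b = numeric(config$n_classes))
    params
  })
}

# ---- example encoding -------------------------------------------------------

lookup_ids <- function(x, table) {
  id <- match(x, table)
  id[is.na(id)] <- UNK_ID
  id
}

#' Encode examples for the model
#'
#' Maps tokens/POS/entity tags to vocabulary ids, prunes the dependency tree
#' at the configured distance `N`, and precomputes the self-looped adjacency
#' and the pooling mask. Done once per (examples, config) pair; the training
#' loop reuses the encoding every epoch.
#'
#' @param examples A `cpi_examples` collection (parsed and tagged when the
#'   corresponding features are enabled).
#' @param vocab A [build_vocab()] result.
#' @param config A [model_config()].
#' @return List of encoded examples.
#' @export
encode_examples <- function(examples, vocab, config) {
  lapply(examples, function(ex) {
    n <- length(ex$tokens)
    if (config$use_etype && is.null(ex$entity_tags)) {
      stopf("entity tags missing (run tag_entity_types) for doc %s", ex$doc_id)
    }
    if (config$use_pos && all(is.na(ex$pos_tags))) {
      stopf("POS tags missing (attach parses) for doc %s", ex$doc_id)
    }
    enc <- list(
      n = n,
      word = lookup_ids(ex$tokens, vocab$words),
      pos = if (config$use_pos) lookup_ids(ex$pos_tags, vocab$pos),
      etype = if (config$use_etype) lookup_ids(ex$entity_tags, vocab$etype),
      chem_span = ex$chem_span, prot_span = ex$prot_span,
      label_id = match(ex$label, LABEL_SET),
      doc_id = ex$doc_id, chem_id = ex$chem_id, prot_id = ex$prot_id
    )
    need_tree <- config$use_gcn || config$pool_kept_only
    if (need_tree && is.null(ex$heads)) {
      stopf("dependency heads missing (attach parses) for doc %s", ex$doc_id)
    }
    if (!is.null(ex$heads)) {
      tree <- dep_tree(ex$heads)
      kept <- prune(tree, ex$chem_span, ex$prot_span, config$prune_dist)
      enc$kept <- kept
      enc$graph <- build_adjacency(tree, kept, n)
    } else {
      enc$kept <- seq_len(n)
      enc$graph <- NULL
    }
    enc$pool_mask <- if (config$use_gcn && config$pool_kept_only) {
      enc$kept
    } else {
      seq_len(n)
    }
    enc
  })
}

#' Embed an encoded example
#'
#' Concatenates the word, POS and entity-type embeddings per token
#' (200 + 20 + 60 = 280 columns at the full-scale defaults); switched-off
#' features are omitted from the concatenation. Out-of-vocabulary symbols
#' use the unknown row.
#'
#' @param enc One element of [encode_examples()].
#' @param params A parameter bundle from [init_params()].
#' @param config A [model_config()].
#' @return `n x input_dim` numeric matrix, one row per token.
#' @export
embed <- function(enc, params, config) {
  X <- params$emb$word[enc$word, , drop = FALSE]
  if (config$use_pos) X <- cbind(X, params$emb$pos[enc$pos, , drop = FALSE])
  if (config$use_etype) X <- cbind(X, params$emb$etype[enc$etype, , drop = FALSE])
  X
}

# ---- Bi-LSTM ----------------------------------------------------------------

sigmoid <- function(x) 1 / (1 + exp(-x))

# one LSTM direction; returns hidden states plus the caches BPTT needs
lstm_dir <- function(X, p) {
  n <- nrow(X)
  Hh <- nrow(p$Wh)  # hidden size; Wh is Hh x 4*Hh
  I <- Fg <- O <- G <- C <- TanhC <- Hmat <- matrix(0, n, Hh)
  h_prev <- numeric(Hh)
  c_prev <- numeric(Hh)
  pre <- X %*% p$Wx
  for (t in seq_len(n)) {
    a <- pre[t, ] + as.numeric(h_prev %*% p$Wh) + p$b
    i <- sigmoid(a[1:Hh])
    f <- sigmoid(a[(Hh + 1L):(2L * Hh)])
    o <- sigmoid(a[(2L * Hh + 1L):(3L * Hh)])
    g <- tanh(a[(3L * Hh + 1L):(4L * Hh)])
    c <- f * c_prev + i * g
    tc <- tanh(c)
    h <- o * tc
    I[t, ] <- i; Fg[t, ] <- f; O[t, ] <- o; G[t, ] <- g
    C[t, ] <- c; TanhC[t, ] <- tc; Hmat[t, ] <- h
    h_prev <- h
    c_prev <- c
  }
  list(X = X, I = I, Fg = Fg, O = O, G = G, C = C, TanhC = TanhC, H = Hmat)
}

#' Bi-LSTM contextual encoding
#'
#' Runs a forward and a backward LSTM over the embedded sentence and
#' concatenates the two hidden states per token, giving vectors of length
#' `2 * lstm_hidden` (400 at the full-scale defaults). Deterministic given
#' parameters and input.
#'
#' @param X `n x input_dim` embedding matrix.
#' @param params Parameter bundle with `lstm_fw` and `lstm_bw`.
#' @return `n x (2 * lstm_hidden)` matrix.
#' @export
encode_bilstm <- function(X, params) {
  bilstm_cache(X, params)$H
}

bilstm_cache <- function(X, params) {
  n <- nrow(X)
  fw <- lstm_dir(X, params$lstm_fw)
  bw <- lstm_dir(X[rev(seq_len(n)), , drop = FALSE], params$lstm_bw)
  list(fw = fw, bw = bw,
       H = cbind(fw$H, bw$H[rev(seq_len(n)), , drop = FALSE]))
}

# ---- GCN --------------------------------------------------------------------

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Graph convolution over the pruned dependency graph
#'
#' Per layer, each token representation is updated as
#' `h_i = sigma( sum_j A_tilde[i,j] W h_j / d_i + b )` with `sigma` the
#' rectifier, `A_tilde = A + I` the self-looped adjacency and `d_i` its row
#' degree. Tokens outside the kept set only see their self-loop.
#'
#' @param H `n x enc_dim` input representations (Bi-LSTM output, or raw
#'   embeddings in the GCN-only ablation).
#' @param graph A `pruned_graph` from [build_adjacency()].
#' @param gcn_params List of per-layer `list(W, b)` as in
#'   `init_params(...)$gcn`.
#' @param L Number of layers to apply (default: all).
#' @return `n x gcn_hidden` matrix after `L` layers.
#' @export
gcn_forward <- function(H, graph, gcn_params, L = length(gcn_params)) {
  if (nrow(H) != graph$n) {
    stopf("H has %d rows but graph has %d tokens", nrow(H), graph$n)
  }
  for (l in seq_len(L)) {
    p <- gcn_params[[l]]
    if (ncol(H) != nrow(p$W)) {
      stopf("layer %d: input dim %d does not match W (%d x %d)", l, ncol(H),
            nrow(p$W), ncol(p$W))
    }
    M <- (graph$A_tilde %*% H) / graph$d
    H <- relu(sweep(M %*% p$W, 2L, p$b, `+`))
  }
  H
}

# ---- pooling, FFNN, softmax -------------------------------------------------

# column-wise max over the given rows, remembering which row won per column
pool_max <- function(H, rows) {
  sub <- H[rows, , drop = FALSE]
  amax <- max.col(t(sub), ties.method = "first")
  list(value = sub[cbind(amax, seq_len(ncol(sub)))], rows = rows[amax])
}

softmax <- function(z) {
  e <- exp(z - max(z))
  e / sum(e)
}

classify_cache <- function(HL, chem_span, prot_span, kept, params) {
  if (length(kept) == 0L) stopf("empty kept set: cannot pool")
  if (!all(chem_span %in% seq_len(nrow(HL))) ||
      !all(prot_span %in% seq_len(nrow(HL)))) {
    stopf("entity span outside the representation matrix")
  }
  ps <- pool_max(HL, kept)
  pc <- pool_max(HL, chem_span)
  pp <- pool_max(HL, prot_span)
  z <- c(ps$value, pc$value, pp$value)
  af <- as.numeric(z %*% params$ffnn$W) + params$ffnn$b
  hf <- relu(af)
  logits <- as.numeric(hf %*% params$out$W) + params$out$b
  probs <- softmax(logits)
  list(probs = probs, z = z, af = af, hf = hf,
       pool = list(sent = ps, chem = pc, prot = pp))
}

#' Pool token representations and classify the pair
#'
#' `h_sent`, `h_c` and `h_p` are element-wise maxima over the kept tokens and
#' the two entity spans; their concatenation passes through a one-hidden-layer
#' FFNN (rectifier) and a linear + softmax output over the six classes.
#'
#' @param HL `n x pool_dim` token representations after the GCN (or encoder).
#' @param chem_span,prot_span Token index sets of the two mentions.
#' @param kept Token index set pooled for the sentence representation.
#' @param params Parameter bundle with `ffnn` and `out`.
#' @return Named probability vector over [cpi_labels()], summing to 1.
#' @export
pool_and_classify <- function(HL, chem_span, prot_span, kept, params) {
  out <- classify_cache(HL, chem_span, prot_span, kept, params)$probs
  stats::setNames(out, LABEL_SET)
}

# ---- full forward pass ------------------------------------------------------

# Forward pass for one encoded example. With train = TRUE, inverted-dropout
# masks are drawn from the current RNG stream and recorded in the cache.
cpi_forward <- function(enc, params, config, train = FALSE) {
  X0 <- embed(enc, params, config)
  cache <- list(enc = enc, config = config, X0 = X0)
  X <- X0
  if (train && config$dropout > 0) {
    mx <- (matrix(stats::runif(length(X0)), nrow(X0)) >= config$dropout) /
      (1 - config$dropout)
    X <- X0 * mx
    cache$mx <- mx
  }
  if (config$use_bilstm) {
    cache$bilstm <- bilstm_cache(X, params)
    H <- cache$bilstm$H
  } else {
    H <- X
  }
  if (config$use_gcn) {
    L <- config$gcn_layers
    layers <- vector("list", L)
    Hin <- H
    for (l in seq_len(L)) {
      p <- params$gcn[[l]]
      M <- (enc$graph$A_tilde %*% Hin) / enc$graph$d
      Z <- sweep(M %*% p$W, 2L, p$b, `+`)
      Hout <- relu(Z)
      lay <- list(Hin = Hin, M = M, Z = Z)
      if (train && config$dropout > 0 && l < L) {
        mg <- (matrix(stats::runif(length(Hout)), nrow(Hout)) >= config$dropout) /
          (1 - config$dropout)
        lay$mg <- mg
        Hout <- Hout * mg
      }
      layers[[l]] <- lay
      Hin <- Hout
    }
    cache$layers <- layers
    HL <- Hin
  } else {
    HL <- H
  }
  cache$HL <- HL
  cls <- classify_cache(HL, enc$chem_span, enc$prot_span, enc$pool_mask, params)
  cache$cls <- cls
  cache$probs <- cls$probs
  cache
}

#' Save / load a trained model
#'
#' The checkpoint embeds the full [model_config()], the vocabularies, the
#' parameter bundle and the training history.
#'
#' @param model A `cpi_model` as returned by [train_cpi()].
#' @param path Checkpoint path (RDS).
#' @export
save_cpi_model <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_cpi_model
#' @export
load_cpi_model <- function(path) {
  model <- readRDS(path)
  if (!inherits(model, "cpi_model")) stopf("%s is not a cpi_model checkpoint", path)
  model
}
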