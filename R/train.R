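# Training loop (plain SGD with gradient-norm clipping), prediction, the
# micro-averaged P/R/F scorer, and the pruning-distance / feature-ablation
# sweep driver.

#' Training specification
#'
#' The learning rate follows the tuned full-scale value (0.3); the optimizer
#' is plain stochastic gradient descent with the global gradient norm clipped
#' at `clip`. Batch size and epoch budget are desk-scale implementation
#' choices (see the methods vignette); early stopping monitors the
#' development micro-F with the given patience.
#'
#' @param learning_rate SGD step size (> 0).
#' @param max_epochs Maximum number of passes over the training data.
#' @param patience Epochs without development micro-F improvement before
#'   stopping (>= 1).
#' @param batch_size Examples per gradient update (mean gradient).
#' @param clip Global gradient-norm clipping threshold.
#' @param neg_keep Fraction of NEG training examples sampled per epoch
#'   (default 1: no reweighting of the class imbalance; lower values
#'   downsample negatives).
#' @param seed Integer seed controlling initialization, shuffling and
#'   dropout; identical seeds give identical training histories.
#' @export
train_spec <- function(learning_rate = 0.3, max_epochs = 20L, patience = 5L,
                       batch_size = 8L, clip = 5, neg_keep = 1,
                       seed = 1L) {
  if (learning_rate <= 0) stopf("learning_rate must be > 0")
  if (patience < 1L) stopf("patience must be >= 1")
  if (!(neg_keep > 0 && neg_keep <= 1)) stopf("neg_keep must be in (0, 1]")
  structure(list(learning_rate = learning_rate,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 batch_size = as.integer(batch_size),
                 clip = clip, neg_keep = neg_keep, seed = as.integer(seed)),
            class = "train_spec")
}

predict_encoded <- function(enc_list, params, config) {
  vapply(enc_list, function(enc) {
    which.max(cpi_forward(enc, params, config, train = FALSE)$probs)
  }, integer(1))
}

tuples_from_encoded <- function(enc_list, label_ids) {
  keep <- which(LABEL_SET[label_ids] != NEG_LABEL)
  out <- data.frame(
    doc_id = vapply(enc_list[keep], `[[`, "", "doc_id"),
    cpr_group = LABEL_SET[label_ids[keep]],
    arg1_id = vapply(enc_list[keep], `[[`, "", "chem_id"),
    arg2_id = vapply(enc_list[keep], `[[`, "", "prot_id"),
    stringsAsFactors = FALSE
  )
  unique(out)
}

#' Train the relation classifier
#'
#' Stochastic-gradient training of the full model: per batch, the mean
#' gradient of the softmax cross-entropy is clipped to `clip` and applied
#' with the given learning rate. After every epoch the development micro-F
#' is computed; the returned model carries the parameters achieving the best
#' development micro-F, and training stops early when it has not improved
#' for `patience` epochs. Fully reproducible given `spec$seed`.
#'
#' @param train_examples,dev_examples `cpi_examples` collections (parsed and
#'   tagged as the configuration requires).
#' @param config A [model_config()].
#' @param spec A [train_spec()].
#' @param word_vectors Optional pretrained vectors from
#'   [load_word_vectors()].
#' @param verbose Print one line per epoch.
#' @return A `cpi_model`: list with `params`, `vocab`, `config`, `spec` and
#'   a per-epoch `history` data frame (`epoch`, `loss`, `dev_p`, `dev_r`,
#'   `dev_f`).
#' @export
train_cpi <- function(train_examples, dev_examples, config = model_config(),
                      spec = train_spec(), word_vectors = NULL,
                      verbose = FALSE) {
  if (length(train_examples) == 0L) stopf("empty training set")
  vocab <- build_vocab(train_examples)
  enc_train <- encode_examples(train_examples, vocab, config)
  enc_dev <- encode_examples(dev_examples, vocab, config)
  dev_gold <- gold_relations(dev_examples)
  have_dev <- length(enc_dev) > 0L

  n <- length(enc_train)
  history <- data.frame(epoch = integer(), loss = numeric(),
                        dev_p = numeric(), dev_r = numeric(),
                        dev_f = numeric())
  with_seed(spec$seed, {
    params <- init_params(config, vocab, word_vectors, seed = NULL)
    best <- list(params = params, f = -Inf, epoch = 0L)
    stale <- 0L
    neg_idx <- which(vapply(enc_train, function(e) {
      LABEL_SET[e$label_id] == NEG_LABEL
    }, logical(1)))
    for (epoch in seq_len(spec$max_epochs)) {
      ord <- sample.int(n)
      if (spec$neg_keep < 1 && length(neg_idx) > 0L) {
        dropped <- sample(neg_idx,
                          round((1 - spec$neg_keep) * length(neg_idx)))
        ord <- ord[!ord %in% dropped]
      }
      total_loss <- 0
      batch_grads <- NULL
      batch_count <- 0L
      flush_batch <- function() {
        if (batch_count == 0L) return()
        g <- scale_grads_keep_ids(batch_grads, 1 / batch_count)
        g <- clip_grads(g, spec$clip)
        params <<- sgd_step(params, g, spec$learning_rate)
        batch_grads <<- NULL
        batch_count <<- 0L
      }
      for (k in ord) {
        cache <- cpi_forward(enc_train[[k]], params, config, train = TRUE)
        total_loss <- total_loss -
          log(max(cache$probs[enc_train[[k]]$label_id], 1e-12))
        batch_grads <- add_grads(batch_grads, cpi_backward(cache, params))
        batch_count <- batch_count + 1L
        if (batch_count >= spec$batch_size) flush_batch()
      }
      flush_batch()

      dev_p <- dev_r <- dev_f <- NA_real_
      if (have_dev) {
        pred_ids <- predict_encoded(enc_dev, params, config)
        ev <- micro_f(dev_gold, tuples_from_encoded(enc_dev, pred_ids))
        dev_p <- ev$precision
        dev_r <- ev$recall
        dev_f <- ev$f
      }
      history[epoch, ] <- list(epoch, total_loss / length(ord), dev_p, dev_r,
                               dev_f)
      if (verbose) {
        message(sprintf("epoch %d: loss %.4f dev F %.2f", epoch,
                        total_loss / n, dev_f))
      }
      if (have_dev) {
        if (dev_f > best$f) {
          best <- list(params = params, f = dev_f, epoch = epoch)
          stale <- 0L
        } else {
          stale <- stale + 1L
          if (stale >= spec$patience) break
        }
      } else {
        best <- list(params = params, f = NA_real_, epoch = epoch)
      }
    }
  })
  structure(list(params = best$params, vocab = vocab, config = config,
                 spec = spec, history = history, best_epoch = best$epoch,
                 best_dev_f = best$f),
            class = "cpi_model")
}

#' @export
print.cpi_model <- function(x, ...) {
  cat("<cpi_model> ", nrow(x$history), " epoch(s) trained; best dev F ",
      if (is.na(x$best_dev_f)) "NA" else sprintf("%.2f%%", x$best_dev_f),
      " at epoch ", x$best_epoch, "\n", sep = "")
  invisible(x)
}

#' Predict relations for candidate examples
#'
#' Each example receives the argmax class (ties broken by the lowest class
#' index); examples predicted `NEG` emit no relation record, so the output
#' contains only evaluated-class tuples, de-duplicated.
#'
#' @param object A trained `cpi_model`.
#' @param examples A `cpi_examples` collection.
#' @param ... Unused.
#' @return Data frame `doc_id`, `cpr_group`, `arg1_id`, `arg2_id`, writable
#'   with [write_predictions()].
#' @export
predict.cpi_model <- function(object, examples, ...) {
  enc <- encode_examples(examples, object$vocab, object$config)
  ids <- predict_encoded(enc, object$params, object$config)
  tuples_from_encoded(enc, ids)
}

tuple_key <- function(x) paste(x$doc_id, x$arg1_id, x$arg2_id, x$cpr_group)

#' Micro-averaged precision, recall and F-score
#'
#' Relations are matched as exact tuples (document, Arg1, Arg2, class) over
#' the five evaluated CPR groups: `TP = |gold n predicted|`,
#' `FP = |predicted \\ gold|`, `FN = |gold \\ predicted|`, pooled over all
#' classes, with `P = TP/(TP+FP)`, `R = TP/(TP+FN)`, `F = 2PR/(P+R)` reported
#' as percentages and defined as 0 when a denominator is 0. Duplicate tuples
#' count once. A prediction outside the evaluated classes is an error;
#' non-evaluated gold annotations are ignored.
#'
#' @param gold,predicted Data frames with columns `doc_id`, `cpr_group`,
#'   `arg1_id`, `arg2_id`.
#' @return An `eval_counts` object: pooled `tp`, `fp`, `fn`, `precision`,
#'   `recall`, `f`, plus a `per_class` data frame.
#' @export
micro_f <- function(gold, predicted) {
  bad <- which(!predicted$cpr_group %in% EVALUATED_GROUPS)
  if (length(bad) > 0L) {
    stopf("prediction %d has non-evaluated class '%s'", bad[1],
          predicted$cpr_group[bad[1]])
  }
  gold <- gold[gold$cpr_group %in% EVALUATED_GROUPS, , drop = FALSE]
  gk <- unique(tuple_key(gold))
  pk <- unique(tuple_key(predicted))
  prf <- function(tp, fp, fn) {
    p <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
    r <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
    f <- if (p + r > 0) 2 * p * r / (p + r) else 0
    c(p = p, r = r, f = f)
  }
  per_class <- do.call(rbind, lapply(EVALUATED_GROUPS, function(cl) {
    gc <- gk[endsWith(gk, cl)]
    pc <- pk[endsWith(pk, cl)]
    tp <- length(intersect(gc, pc))
    fp <- length(setdiff(pc, gc))
    fn <- length(setdiff(gc, pc))
    s <- prf(tp, fp, fn)
    data.frame(class = cl, tp = tp, fp = fp, fn = fn,
               precision = s["p"], recall = s["r"], f = s["f"],
               row.names = NULL)
  }))
  tp <- sum(per_class$tp)
  fp <- sum(per_class$fp)
  fn <- sum(per_class$fn)
  s <- prf(tp, fp, fn)
  structure(list(tp = tp, fp = fp, fn = fn,
                 precision = unname(s["p"]), recall = unname(s["r"]),
                 f = unname(s["f"]), per_class = per_class),
            class = "eval_counts")
}

#' @export
print.eval_counts <- function(x, ...) {
  cat(sprintf("micro P %.2f%%  R %.2f%%  F %.2f%%  (TP %d, FP %d, FN %d)\n",
              x$precision, x$recall, x$f, x$tp, x$fp, x$fn))
  invisible(x)
}

#' Train/evaluate sweep over configuration variants
#'
#' Runs one independently seeded train/evaluate cycle per configuration
#' (e.g. the pruning distances N in \{0, 1, 2, 3, Inf\} or the embedding
#' feature grid) and tabulates development precision/recall/F at the best
#' epoch. Identical variant and seed give identical rows.
#'
#' @param variants Named list of [model_config()] objects.
#' @param train_examples,dev_examples `cpi_examples` collections.
#' @param spec A [train_spec()]; variant `i` trains with `spec$seed + i - 1`.
#' @return Data frame `variant`, `precision`, `recall`, `f`, `best_epoch`.
#' @export
sweep_cpi <- function(variants, train_examples, dev_examples,
                      spec = train_spec()) {
  if (is.null(names(variants))) names(variants) <- seq_along(variants)
  rows <- lapply(seq_along(variants), function(i) {
    sp <- spec
    sp$seed <- spec$seed + i - 1L
    model <- train_cpi(train_examples, dev_examples, variants[[i]], sp)
    h <- model$history[model$best_epoch, ]
    data.frame(variant = names(variants)[i], precision = h$dev_p,
               recall = h$dev_r, f = h$dev_f, best_epoch = model$best_epoch,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
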