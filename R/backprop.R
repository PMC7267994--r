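# Hand-derived gradients for the full forward pass in model.R: softmax
# cross-entropy -> linear output -> FFNN -> max-pool routing -> GCN layers ->
# Bi-LSTM BPTT -> embedding rows. Embedding gradients are kept sparse
# (ids + row-gradient matrix) so updates touch only the rows actually used.
# Verified against finite differences in the test suite.

# Backward through one LSTM direction given the cache from lstm_dir().
# The sequential loop only propagates the recurrent dh/dc chain and collects
# the pre-activation gradients dA; all weight/input gradients are single
# matrix products afterwards.
lstm_backward <- function(cache, p, dH) {
  n <- nrow(dH)
  Hh <- ncol(cache$H)
  dA <- matrix(0, n, 4L * Hh)
  dh_rec <- numeric(Hh)
  dc <- numeric(Hh)
  for (t in rev(seq_len(n))) {
    i <- cache$I[t, ]; f <- cache$Fg[t, ]; o <- cache$O[t, ]; g <- cache$G[t, ]
    tc <- cache$TanhC[t, ]
    c_prev <- if (t > 1L) cache$C[t - 1L, ] else numeric(Hh)
    dh <- dH[t, ] + dh_rec
    do_ <- dh * tc
    dcl <- dc + dh * o * (1 - tc^2)
    di <- dcl * g
    dg <- dcl * i
    df <- dcl * c_prev
    dc <- dcl * f
    da <- c(di * i * (1 - i), df * f * (1 - f), do_ * o * (1 - o),
            dg * (1 - g^2))
    dA[t, ] <- da
    dh_rec <- as.numeric(p$Wh %*% da)
  }
  h_prev_rows <- rbind(numeric(Hh), cache$H[-n, , drop = FALSE])
  list(dX = tcrossprod(dA, p$Wx),
       Wx = crossprod(cache$X, dA),
       Wh = crossprod(h_prev_rows, dA),
       b = colSums(dA))
}

# scatter a pooled-dimension gradient back to the winning rows
unpool <- function(dHL, pool, dvec) {
  idx <- cbind(pool$rows, seq_along(dvec))
  dHL[idx] <- dHL[idx] + dvec
  dHL
}

# Backward pass for one example. Returns gradients shaped like the parameter
# bundle, except emb$* which are list(ids, G) sparse row gradients.
cpi_backward <- function(cache, params) {
  enc <- cache$enc
  config <- cache$config
  cls <- cache$cls
  y <- enc$label_id

  dlogits <- cls$probs
  dlogits[y] <- dlogits[y] - 1
  grads <- list(
    out = list(W = tcrossprod(cls$hf, dlogits), b = dlogits)
  )
  dhf <- as.numeric(dlogits %*% t(params$out$W))
  daf <- dhf * (cls$af > 0)
  grads$ffnn <- list(W = tcrossprod(cls$z, daf), b = daf)
  dz <- as.numeric(daf %*% t(params$ffnn$W))

  g <- length(cls$pool$sent$value)
  dHL <- matrix(0, nrow(cache$HL), ncol(cache$HL))
  dHL <- unpool(dHL, cls$pool$sent, dz[seq_len(g)])
  dHL <- unpool(dHL, cls$pool$chem, dz[g + seq_len(g)])
  dHL <- unpool(dHL, cls$pool$prot, dz[2L * g + seq_len(g)])

  if (config$use_gcn) {
    L <- config$gcn_layers
    grads$gcn <- vector("list", L)
    up <- dHL
    for (l in rev(seq_len(L))) {
      lay <- cache$layers[[l]]
      if (!is.null(lay$mg)) up <- up * lay$mg
      dZ <- up * (lay$Z > 0)
      grads$gcn[[l]] <- list(W = crossprod(lay$M, dZ), b = colSums(dZ))
      dM <- tcrossprod(dZ, params$gcn[[l]]$W)
      up <- enc$graph$A_tilde %*% (dM / enc$graph$d)
    }
    dH <- up
  } else {
    dH <- dHL
  }

  if (config$use_bilstm) {
    n <- enc$n
    Hh <- ncol(cache$bilstm$fw$H)
    bfw <- lstm_backward(cache$bilstm$fw, params$lstm_fw,
                         dH[, seq_len(Hh), drop = FALSE])
    dbw_in <- dH[rev(seq_len(n)), Hh + seq_len(Hh), drop = FALSE]
    bbw <- lstm_backward(cache$bilstm$bw, params$lstm_bw, dbw_in)
    grads$lstm_fw <- bfw[c("Wx", "Wh", "b")]
    grads$lstm_bw <- bbw[c("Wx", "Wh", "b")]
    dX <- bfw$dX + bbw$dX[rev(seq_len(n)), , drop = FALSE]
  } else {
    dX <- dH
  }
  if (!is.null(cache$mx)) dX <- dX * cache$mx

  # split the embedding gradient by feature block and aggregate by row id
  sparse_rows <- function(ids, G) {
    keep <- ids != PAD_ID  # padding row stays zero
    ids <- ids[keep]
    G <- G[keep, , drop = FALSE]
    agg <- rowsum(G, group = ids)
    list(ids = as.integer(rownames(agg)), G = agg)
  }
  off <- 0L
  grads$emb <- list()
  grads$emb$word <- sparse_rows(enc$word,
                                dX[, off + seq_len(config$word_dim), drop = FALSE])
  off <- off + config$word_dim
  if (config$use_pos) {
    grads$emb$pos <- sparse_rows(enc$pos,
                                 dX[, off + seq_len(config$pos_dim), drop = FALSE])
    off <- off + config$pos_dim
  }
  if (config$use_etype) {
    grads$emb$etype <- sparse_rows(enc$etype,
                                   dX[, off + seq_len(config$etype_dim),
                                      drop = FALSE])
  }
  grads
}

# ---- gradient bookkeeping ---------------------------------------------------

# sum two gradient structures (same shape); sparse embedding blocks are
# concatenated and re-aggregated
add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) {
    if (nm == "emb") {
      for (tb in names(b$emb)) {
        ids <- c(a$emb[[tb]]$ids, b$emb[[tb]]$ids)
        G <- rbind(a$emb[[tb]]$G, b$emb[[tb]]$G)
        agg <- rowsum(G, group = ids)
        a$emb[[tb]] <- list(ids = as.integer(rownames(agg)), G = agg)
      }
    } else if (nm == "gcn") {
      for (l in seq_along(b$gcn)) {
        a$gcn[[l]]$W <- a$gcn[[l]]$W + b$gcn[[l]]$W
        a$gcn[[l]]$b <- a$gcn[[l]]$b + b$gcn[[l]]$b
      }
    } else {
      for (f in names(b[[nm]])) a[[nm]][[f]] <- a[[nm]][[f]] + b[[nm]][[f]]
    }
  }
  a
}

grad_sq_norm <- function(g) {
  tot <- 0
  walk <- function(x) {  # "ids" vectors are indices, not gradient mass
    if (is.list(x)) {
      nms <- names(x)
      for (k in seq_along(x)) {
        if (!is.null(nms) && identical(nms[k], "ids")) next
        walk(x[[k]])
      }
    } else if (is.numeric(x)) {
      tot <<- tot + sum(x^2)
    }
  }
  walk(g)
  tot
}

# clip the global gradient norm at `max_norm`
clip_grads <- function(g, max_norm) {
  nrm <- sqrt(grad_sq_norm(g))
  if (is.finite(nrm) && nrm > max_norm) {
    g <- scale_grads_keep_ids(g, max_norm / nrm)
  }
  g
}

scale_grads_keep_ids <- function(x, s) {
  if (is.list(x)) {
    nms <- names(x)
    for (k in seq_along(x)) {
      if (!is.null(nms) && identical(nms[k], "ids")) next
      x[[k]] <- scale_grads_keep_ids(x[[k]], s)
    }
    x
  } else if (is.numeric(x)) {
    x * s
  } else {
    x
  }
}

# in-place (functional) SGD step: params <- params - lr * grads
sgd_step <- function(params, grads, lr) {
  for (nm in names(grads)) {
    if (nm == "emb") {
      for (tb in names(grads$emb)) {
        sp <- grads$emb[[tb]]
        params$emb[[tb]][sp$ids, ] <- params$emb[[tb]][sp$ids, , drop = FALSE] -
          lr * sp$G
      }
    } else if (nm == "gcn") {
      for (l in seq_along(grads$gcn)) {
        params$gcn[[l]]$W <- params$gcn[[l]]$W - lr * grads$gcn[[l]]$W
        params$gcn[[l]]$b <- params$gcn[[l]]$b - lr * grads$gcn[[l]]$b
      }
    } else {
      for (f in names(grads[[nm]])) {
        params[[nm]][[f]] <- params[[nm]][[f]] - lr * grads[[nm]][[f]]
      }
    }
  }
  params
}
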