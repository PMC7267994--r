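# Independent brute-force oracles used to validate the package's graph
# algorithms, GCN arithmetic and scorer. They deliberately use different
# machinery (ancestor-set enumeration, igraph BFS, per-node loops, naive set
# counting) from the implementations they check.

# random labelled tree as a head array: attach each node (in random order)
# to a previously placed node
random_tree_heads <- function(n) {
  ord <- sample.int(n)
  heads <- integer(n)
  heads[ord[1]] <- 0L
  for (k in seq_len(n)[-1]) {
    heads[ord[k]] <- ord[sample.int(k - 1L, 1L)]
  }
  heads
}

random_span <- function(n, max_size = 3L) {
  sort(sample.int(n, min(n, sample.int(max_size, 1L))))
}

tree_igraph <- function(heads) {
  n <- length(heads)
  i <- which(heads != 0L)
  igraph::graph_from_edgelist(cbind(i, heads[i]), directed = FALSE) |>
    (\(g) if (igraph::vcount(g) < n) igraph::add_vertices(g, n - igraph::vcount(g)) else g)()
}

oracle_depths <- function(heads) {
  vapply(seq_along(heads), function(i) {
    d <- 0L
    while (heads[i] != 0L) {
      i <- heads[i]
      d <- d + 1L
    }
    d
  }, integer(1))
}

oracle_ancestors <- function(heads, i) {
  out <- i
  while (heads[i] != 0L) {
    i <- heads[i]
    out <- c(out, i)
  }
  out
}

# LCA by ancestor-set intersection: common ancestors of all span tokens,
# deepest one wins
oracle_lca <- function(heads, span1, span2) {
  common <- Reduce(intersect,
                   lapply(c(span1, span2), function(i) oracle_ancestors(heads, i)))
  common[which.max(oracle_depths(heads)[common])]
}

# Path-centric pruning from the all-pairs igraph distance matrix. In a tree
# the unique path between two LCA-subtree nodes stays inside the subtree, so
# full-tree distances equal subtree-restricted distances; a node u lies on
# the shortest path between v and w iff d(v,u) + d(u,w) == d(v,w).
oracle_prune <- function(heads, span1, span2, N,
                         D = igraph::distances(tree_igraph(heads))) {
  a <- oracle_lca(heads, span1, span2)
  subtree <- which(vapply(seq_along(heads),
                          function(i) a %in% oracle_ancestors(heads, i),
                          logical(1)))
  if (is.infinite(N)) return(sort(subtree))
  depth <- oracle_depths(heads)
  top1 <- span1[which.min(depth[span1])]
  top2 <- span2[which.min(depth[span2])]
  on_path <- function(v, w) which(D[v, ] + D[, w] == D[v, w])
  path <- unique(c(on_path(top1, a), on_path(top2, a), span1, span2))
  kept <- subtree[apply(D[path, subtree, drop = FALSE], 2L, min) <= N]
  sort(kept)
}

# adjacency by independent graph-library construction
oracle_adjacency <- function(heads, kept, n, g = tree_igraph(heads)) {
  A <- matrix(0, n, n)
  if (length(kept) > 1L) {
    sub <- igraph::induced_subgraph(g, kept)
    As <- as.matrix(igraph::as_adjacency_matrix(sub))
    A[kept, kept] <- As
  }
  A
}

# dense per-node GCN reference: explicit loops over nodes and neighbours
oracle_gcn <- function(H, A_tilde, d, gcn_params, L) {
  n <- nrow(H)
  for (l in seq_len(L)) {
    W <- gcn_params[[l]]$W
    b <- gcn_params[[l]]$b
    out <- matrix(0, n, ncol(W))
    for (i in seq_len(n)) {
      agg <- numeric(ncol(H))
      for (j in seq_len(n)) {
        if (A_tilde[i, j] != 0) agg <- agg + A_tilde[i, j] * H[j, ]
      }
      z <- as.numeric(agg %*% W) / d[i] + b
      out[i, ] <- pmax(z, 0)
    }
    H <- out
  }
  H
}

# naive set-arithmetic micro P/R/F over tuple strings
oracle_micro <- function(gold_keys, pred_keys) {
  gold_keys <- unique(gold_keys)
  pred_keys <- unique(pred_keys)
  tp <- 0L; fp <- 0L; fn <- 0L
  for (k in pred_keys) {
    if (k %in% gold_keys) tp <- tp + 1L else fp <- fp + 1L
  }
  for (k in gold_keys) {
    if (!k %in% pred_keys) fn <- fn + 1L
  }
  p <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
  r <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(tp = tp, fp = fp, fn = fn, p = p, r = r, f = f)
}

random_tuples <- function(k) {
  if (k == 0L) {
    return(data.frame(doc_id = character(), cpr_group = character(),
                      arg1_id = character(), arg2_id = character()))
  }
  data.frame(
    doc_id = sample(paste0("D", 1:4), k, replace = TRUE),
    cpr_group = sample(evaluated_groups(), k, replace = TRUE),
    arg1_id = sample(paste0("T", 1:4), k, replace = TRUE),
    arg2_id = sample(paste0("T", 5:8), k, replace = TRUE),
    stringsAsFactors = FALSE
  )
}

# hand-built 2-document fixture corpus written to tempdir
write_fixture_corpus <- function(dir = withr::local_tempdir(.local_envir = parent.frame())) {
  title1 <- "Alprenolol study ."
  abs1 <- "Alprenolol is an antagonist of ADRB1 . It was measured twice ."
  title2 <- "Second doc ."
  abs2 <- "KIN-9 phosphorylates SUB-1 protein ."
  writeLines(c(paste("D01", title1, abs1, sep = "\t"),
               paste("D02", title2, abs2, sep = "\t")),
             file.path(dir, "abstracts.tsv"))
  full1 <- paste(title1, abs1, sep = "\t")
  off <- function(full, s) regexpr(s, full, fixed = TRUE)[1] - 1L
  ents <- c(
    paste("D01", "T1", "CHEMICAL", off(full1, "Alprenolol is") , off(full1, "Alprenolol is") + 10L, "Alprenolol", sep = "\t"),
    paste("D01", "T2", "GENE-Y", off(full1, "ADRB1"), off(full1, "ADRB1") + 5L, "ADRB1", sep = "\t"),
    paste("D02", "T1", "CHEMICAL", 13L, 18L, "KIN-9", sep = "\t"),
    paste("D02", "T2", "GENE-N", 34L, 39L, "SUB-1", sep = "\t")
  )
  writeLines(ents, file.path(dir, "entities.tsv"))
  writeLines(paste("D01", "CPR:6", "Y", "Arg1:T1", "Arg2:T2", sep = "\t"),
             file.path(dir, "relations.tsv"))
  list(dir = dir,
       abstracts = file.path(dir, "abstracts.tsv"),
       entities = file.path(dir, "entities.tsv"),
       relations = file.path(dir, "relations.tsv"))
}

# small prepared example set for model-level tests
fixture_examples <- function(n_documents = 4L, seed = 7L) {
  sim <- generate_corpus(sim_spec(n_documents = n_documents, seed = seed),
                         dir = withr::local_tempdir(.local_envir = parent.frame()))
  prepare_examples(sim$corpus, sim$paths$conllu, sentences = sim$sentences)
}

tiny_config <- function(...) {
  model_config(word_dim = 6, pos_dim = 3, etype_dim = 3, lstm_hidden = 4,
               gcn_hidden = 4, ffnn_hidden = 4, ...)
}
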