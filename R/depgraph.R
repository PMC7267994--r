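# Dependency-tree algorithms: LCA of two entity spans, the dependency path
# between them, path-centric pruning at distance N, and construction of the
# self-looped, degree-normalized adjacency used by the graph convolution.

#' Construct a dependency tree from a head array
#'
#' A sentence parse is stored as a head index per token (1-indexed, 0 marks
#' the root). The constructor validates the single-root and acyclicity
#' invariants.
#'
#' @param heads Integer vector; `heads[i]` is the head of token `i`, 0 for the
#'   root. Exactly one token must have head 0.
#' @return An object of class `dep_tree` with fields `n` and `heads`.
#' @examples
#' dep_tree(c(3, 3, 0, 5, 3))
#' @export
dep_tree <- function(heads) {
  heads <- as.integer(heads)
  n <- length(heads)
  if (n < 1L) stopf("dependency tree must have at least one token")
  if (anyNA(heads)) stopf("token without head (NA) at position %d",
                          which(is.na(heads))[1])
  if (any(heads < 0L | heads > n)) {
    stopf("head index out of range at token %d", which(heads < 0L | heads > n)[1])
  }
  if (sum(heads == 0L) != 1L) {
    stopf("dependency tree must have exactly one root, found %d", sum(heads == 0L))
  }
  # acyclicity: walking up from any token must reach the root in <= n steps
  for (i in seq_len(n)) {
    v <- i
    steps <- 0L
    while (heads[v] != 0L) {
      v <- heads[v]
      steps <- steps + 1L
      if (steps > n) stopf("cycle detected in head array (token %d)", i)
    }
  }
  structure(list(n = n, heads = heads), class = "dep_tree")
}

#' @export
print.dep_tree <- function(x, ...) {
  cat("<dep_tree> ", x$n, " tokens, heads: ", paste(x$heads, collapse = " "),
      "\n", sep = "")
  invisible(x)
}

as_dep_tree <- function(x) {
  if (inherits(x, "dep_tree")) x else dep_tree(x)
}

# depth of every token (root has depth 0)
tree_depths <- function(tree) {
  heads <- tree$heads
  depth <- integer(tree$n)
  for (i in seq_len(tree$n)) {
    v <- i
    d <- 0L
    while (heads[v] != 0L) {
      v <- heads[v]
      d <- d + 1L
    }
    depth[i] <- d
  }
  depth
}

# inclusive chain of ancestors from token up to the root
ancestor_chain <- function(heads, i) {
  chain <- i
  while (heads[i] != 0L) {
    i <- heads[i]
    chain <- c(chain, i)
  }
  chain
}

# undirected edge list (2-column matrix) of the tree, one row per arc
tree_edges <- function(tree) {
  i <- which(tree$heads != 0L)
  cbind(i, tree$heads[i], deparse.level = 0)
}

# undirected neighbour lists
tree_neighbors <- function(tree) {
  nb <- vector("list", tree$n)
  e <- tree_edges(tree)
  for (k in seq_len(nrow(e))) {
    nb[[e[k, 1]]] <- c(nb[[e[k, 1]]], e[k, 2])
    nb[[e[k, 2]]] <- c(nb[[e[k, 2]]], e[k, 1])
  }
  nb
}

check_span <- function(tree, span, what) {
  span <- unique(as.integer(span))
  if (length(span) == 0L || anyNA(span) || any(span < 1L | span > tree$n)) {
    stopf("invalid %s: must be a non-empty subset of 1..%d", what, tree$n)
  }
  span
}

#' Lowest common ancestor of two token spans
#'
#' Returns the deepest node that is an ancestor (inclusive) of every token in
#' both spans. This node is the root of the LCA subtree used by path-centric
#' pruning.
#'
#' @param tree A [dep_tree()] (or a raw head array).
#' @param span1,span2 Non-empty integer vectors of token indices.
#' @return A single token index.
#' @examples
#' lca(dep_tree(c(3, 3, 0, 5, 3)), 1, c(4, 5))  # 3
#' @export
lca <- function(tree, span1, span2) {
  tree <- as_dep_tree(tree)
  span1 <- check_span(tree, span1, "span1")
  span2 <- check_span(tree, span2, "span2")
  heads <- tree$heads
  depth <- tree_depths(tree)
  pair_lca <- function(a, b) {
    while (depth[a] > depth[b]) a <- heads[a]
    while (depth[b] > depth[a]) b <- heads[b]
    while (a != b) {
      a <- heads[a]
      b <- heads[b]
    }
    a
  }
  Reduce(pair_lca, c(span1, span2))
}

# all nodes whose ancestor chain (inclusive) contains `root`
lca_subtree <- function(tree, root) {
  heads <- tree$heads
  which(vapply(seq_len(tree$n),
               function(i) root %in% ancestor_chain(heads, i),
               logical(1)))
}

# The dependency path between the two spans: union of the walks from each
# span's shallowest token up to the LCA, plus every entity token (entity
# tokens must survive pruning for entity pooling to be defined).
dependency_path <- function(tree, span1, span2) {
  tree <- as_dep_tree(tree)
  span1 <- check_span(tree, span1, "span1")
  span2 <- check_span(tree, span2, "span2")
  a <- lca(tree, span1, span2)
  depth <- tree_depths(tree)
  heads <- tree$heads
  walk_to <- function(i) {
    out <- i
    while (i != a) {
      i <- heads[i]
      out <- c(out, i)
    }
    out
  }
  top1 <- span1[which.min(depth[span1])]
  top2 <- span2[which.min(depth[span2])]
  sort(unique(c(walk_to(top1), walk_to(top2), span1, span2)))
}

#' Path-centric pruning of a dependency tree
#'
#' Keeps the tokens of the LCA subtree whose tree-distance to the dependency
#' path between the two entity spans is at most `N`. `N = 0` prunes down to
#' the path itself, `N = 1` additionally keeps tokens directly attached to the
#' path, and `N = Inf` retains the entire LCA subtree. Entity tokens are
#' always kept, and the kept set is monotone non-decreasing in `N`.
#'
#' @param tree A [dep_tree()] (or head array).
#' @param chem_span,prot_span Token index sets of the two argument mentions.
#' @param N Non-negative integer pruning distance, or `Inf`.
#' @return Sorted integer vector of kept token indices.
#' @examples
#' tr <- dep_tree(c(3, 3, 0, 5, 3))
#' prune(tr, 1, c(4, 5), 0)  # 1 3 4 5
#' prune(tr, 1, c(4, 5), 1)  # 1 2 3 4 5
#' @export
prune <- function(tree, chem_span, prot_span, N) {
  tree <- as_dep_tree(tree)
  if (length(N) != 1L || is.na(N) || N < 0) {
    stopf("N must be a single non-negative number or Inf")
  }
  a <- lca(tree, chem_span, prot_span)
  subtree <- lca_subtree(tree, a)
  if (is.infinite(N)) return(sort(subtree))
  path <- dependency_path(tree, chem_span, prot_span)
  # BFS from the path set within the undirected tree restricted to the subtree
  nb <- tree_neighbors(tree)
  in_sub <- logical(tree$n)
  in_sub[subtree] <- TRUE
  dist <- rep(NA_integer_, tree$n)
  dist[path] <- 0L
  frontier <- path
  while (length(frontier) > 0L) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in nb[[v]]) {
        if (in_sub[w] && is.na(dist[w])) {
          dist[w] <- dist[v] + 1L
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  sort(which(!is.na(dist) & dist <= N))
}

#' Build the self-looped adjacency of a pruned dependency graph
#'
#' Converts a tree plus a kept-token set into the symmetric 0/1 adjacency
#' matrix `A` over all `n` tokens (edges only between kept tokens that stand
#' in a head relation), the self-looped matrix `A_tilde = A + I`, and the
#' per-token degrees `d = rowSums(A_tilde)`. Tokens outside the kept set
#' retain only their self-loop (`d = 1`), so the graph convolution leaves
#' them as transformed copies of themselves.
#'
#' @param tree A [dep_tree()] (or head array).
#' @param kept Integer vector of kept token indices (possibly empty).
#' @param n Number of tokens; defaults to `tree$n`.
#' @return An object of class `pruned_graph` with fields `kept`, `A`,
#'   `A_tilde`, `d`, `n`.
#' @export
build_adjacency <- function(tree, kept, n = NULL) {
  tree <- as_dep_tree(tree)
  n <- as.integer(n %||% tree$n)
  kept <- unique(as.integer(kept))
  if (any(kept < 1L | kept > n)) stopf("kept set out of range 1..%d", n)
  A <- matrix(0, n, n)
  in_kept <- logical(n)
  in_kept[kept] <- TRUE
  for (i in seq_len(tree$n)) {
    h <- tree$heads[i]
    if (h > 0L && in_kept[i] && in_kept[h]) {
      A[i, h] <- 1
      A[h, i] <- 1
    }
  }
  A_tilde <- A + diag(n)
  structure(list(kept = sort(kept), A = A, A_tilde = A_tilde,
                 d = rowSums(A_tilde), n = n),
            class = "pruned_graph")
}

#' @export
print.pruned_graph <- function(x, ...) {
  cat("<pruned_graph> ", x$n, " tokens, ", length(x$kept), " kept, ",
      sum(x$A) / 2, " edges\n", sep = "")
  invisible(x)
}
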