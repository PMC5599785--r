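# Independent tree oracles used across test files.

# decode a Pruefer sequence (length n-2, entries in 1..n) to an edge matrix
pruefer_decode <- function(seq, n) {
  if (n == 2) return(matrix(c(1L, 2L), 1, 2))
  degree <- rep(1L, n)
  for (s in seq) degree[s] <- degree[s] + 1L
  edges <- matrix(0L, n - 1, 2)
  for (k in seq_along(seq)) {
    leaf <- which.max(degree == 1L)  # smallest degree-1 node
    edges[k, ] <- c(leaf, seq[k])
    degree[leaf] <- 0L
    degree[seq[k]] <- degree[seq[k]] - 1L
  }
  edges[n - 1, ] <- which(degree == 1L)
  edges
}

random_pruefer_tree <- function(n) {
  seq <- if (n > 2) sample.int(n, n - 2, replace = TRUE) else integer(0)
  tree_from_edges(pruefer_decode(seq, n), n)
}

# cache of every labelled tree on n nodes, as linear-index matrices into an
# n x n weight matrix: rows = trees, columns = the n-1 edges
all_trees_cache <- new.env(parent = emptyenv())
all_tree_edge_indices <- function(n) {
  key <- as.character(n)
  if (!is.null(all_trees_cache[[key]])) return(all_trees_cache[[key]])
  if (n == 2) {
    idx <- matrix((2L - 1L) * n + 1L, 1, 1)
  } else {
    seqs <- as.matrix(expand.grid(rep(list(seq_len(n)), n - 2)))
    idx <- matrix(0L, nrow(seqs), n - 1)
    for (t in seq_len(nrow(seqs))) {
      e <- pruefer_decode(seqs[t, ], n)
      idx[t, ] <- (e[, 2] - 1L) * n + e[, 1]
    }
  }
  all_trees_cache[[key]] <- idx
  idx
}

# exhaustive maximum spanning-tree weight over all n^(n-2) labelled trees
max_tree_weight_bruteforce <- function(W) {
  n <- nrow(W)
  idx <- all_tree_edge_indices(n)
  # as.vector forces linear indexing (a 2-column integer matrix would
  # otherwise be taken as (row, col) pairs)
  max(rowSums(matrix(W[as.vector(idx)], nrow(idx))))
}

# random valid connectivity matrix: symmetric, zero diagonal, in [0, 1]
random_connectivity <- function(n, round_to = NULL) {
  w <- stats::runif(n * (n - 1) / 2)
  if (!is.null(round_to)) w <- round(w, round_to)  # force ties
  W <- matrix(0, n, n)
  W[upper.tri(W)] <- w
  W + t(W)
}

star_tree <- function(n) tree_from_edges(cbind(1L, 2:n), n)
path_tree <- function(n) tree_from_edges(cbind(1:(n - 1), 2:n), n)

# igraph mirror of a spanning_tree, for metric cross-checks
as_igraph_tree <- function(t) {
  igraph::graph_from_edgelist(as.matrix(t$edges[, c("i", "j")]),
                              directed = FALSE)
}
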