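# Maximum-weight spanning tree of a connectivity matrix and its global
# topology metrics. On similarity weights the "minimum spanning tree" of the
# distance 1 - w is identical to the maximum-weight tree on w; Kruskal on
# descending weights is used directly.

#' Build the strongest-connection spanning tree
#'
#' Kruskal's algorithm over edges sorted by descending weight, with ties
#' broken by ascending (i, j) node-index pair so the result is deterministic
#' even when weights repeat. The returned tree maximises total edge weight
#' over all spanning trees of the complete weighted graph.
#'
#' @param m Symmetric connectivity matrix (n >= 2), zero diagonal, weights in
#'   \[0, 1\].
#' @return A `spanning_tree`: list with `n_nodes`, `edges` (data.frame
#'   `i`, `j`, `weight`, 1-based, exactly n - 1 rows), `labels`.
#' @export
build_tree <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  n <- nrow(m)
  if (n < 2) stop("need at least 2 nodes")
  if (ncol(m) != n) stop("matrix is not square")
  if (max(abs(m - t(m))) > 1e-12) stop("matrix is not symmetric")
  idx <- which(upper.tri(m), arr.ind = TRUE)
  w <- m[upper.tri(m)]
  ord <- order(-w, idx[, 1], idx[, 2])
  parent <- seq_len(n)
  find <- function(a) {
    while (parent[a] != a) {
      parent[a] <<- parent[parent[a]]
      a <- parent[a]
    }
    a
  }
  ei <- integer(n - 1)
  ej <- integer(n - 1)
  ew <- numeric(n - 1)
  taken <- 0L
  for (k in ord) {
    a <- find(idx[k, 1])
    b <- find(idx[k, 2])
    if (a != b) {
      parent[a] <- b
      taken <- taken + 1L
      ei[taken] <- idx[k, 1]
      ej[taken] <- idx[k, 2]
      ew[taken] <- w[k]
      if (taken == n - 1L) break
    }
  }
  labels <- rownames(m)
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(n))
  structure(list(n_nodes = n,
                 edges = data.frame(i = ei, j = ej, weight = ew),
                 labels = labels),
            class = "spanning_tree")
}

#' @export
print.spanning_tree <- function(x, ...) {
  cat(sprintf("<spanning_tree: %d nodes, %d edges, total weight %.4f>\n",
              x$n_nodes, nrow(x$edges), sum(x$edges$weight)))
  invisible(x)
}

#' Construct a spanning tree directly from an edge list
#'
#' Mainly for synthetic topologies and tests. Validates connectivity and
#' acyclicity.
#'
#' @param edges Two-column matrix or data.frame of 1-based node pairs.
#' @param n_nodes Number of nodes.
#' @param weights Optional edge weights (default 1).
#' @param labels Optional node labels.
#' @return A `spanning_tree`.
#' @export
tree_from_edges <- function(edges, n_nodes, weights = NULL, labels = NULL) {
  edges <- as.matrix(edges)[, 1:2, drop = FALSE]
  if (nrow(edges) != n_nodes - 1) {
    stop("a tree on ", n_nodes, " nodes needs ", n_nodes - 1, " edges, got ",
         nrow(edges))
  }
  if (is.null(weights)) weights <- rep(1, nrow(edges))
  if (is.null(labels)) labels <- sprintf("ch%02d", seq_len(n_nodes))
  t <- structure(list(n_nodes = as.integer(n_nodes),
                      edges = data.frame(i = as.integer(edges[, 1]),
                                         j = as.integer(edges[, 2]),
                                         weight = weights),
                      labels = labels),
                 class = "spanning_tree")
  if (any(vapply(tree_components(t, 0L), length, integer(1)) != n_nodes)) {
    stop("edge list is not a connected acyclic tree")
  }
  t
}

# adjacency list of a tree
tree_adjacency <- function(t) {
  adj <- vector("list", t$n_nodes)
  for (k in seq_len(nrow(t$edges))) {
    i <- t$edges$i[k]
    j <- t$edges$j[k]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

tree_degrees <- function(t) {
  tabulate(c(t$edges$i, t$edges$j), nbins = t$n_nodes)
}

# connected components after removing node `drop` (0 = keep all); returns a
# list of integer vectors
tree_components <- function(t, drop = 0L) {
  adj <- tree_adjacency(t)
  seen <- rep(FALSE, t$n_nodes)
  if (drop > 0L) seen[drop] <- TRUE
  comps <- list()
  for (s in seq_len(t$n_nodes)) {
    if (seen[s]) next
    comp <- integer(0)
    queue <- s
    seen[s] <- TRUE
    while (length(queue) > 0) {
      v <- queue[1]
      queue <- queue[-1]
      comp <- c(comp, v)
      for (u in adj[[v]]) {
        if (!seen[u]) {
          seen[u] <- TRUE
          queue <- c(queue, u)
        }
      }
    }
    comps[[length(comps) + 1]] <- comp
  }
  comps
}

# hop distances from one node to all nodes (BFS)
tree_bfs_depths <- function(adj, start, n) {
  depth <- rep(-1L, n)
  depth[start] <- 0L
  queue <- start
  while (length(queue) > 0) {
    v <- queue[1]
    queue <- queue[-1]
    for (u in adj[[v]]) {
      if (depth[u] < 0L) {
        depth[u] <- depth[v] + 1L
        queue <- c(queue, u)
      }
    }
  }
  depth
}

tree_eccentricities <- function(t) {
  adj <- tree_adjacency(t)
  vapply(seq_len(t$n_nodes),
         function(v) max(tree_bfs_depths(adj, v, t$n_nodes)), integer(1))
}

#' Normalised maximum degree
#'
#' Maximum node degree divided by the edge count M = N - 1. 1 for a star,
#' 2/M for a path.
#'
#' @param t A `spanning_tree`.
#' @return Scalar in (0, 1\].
#' @export
degree_norm <- function(t) {
  max(tree_degrees(t)) / (t$n_nodes - 1)
}

#' Leaf fraction
#'
#' Number of degree-1 nodes divided by M = N - 1. High values mean a
#' star-like, hub-dominated tree; the minimum 2/M is attained by a path.
#'
#' @param t A `spanning_tree`.
#' @return Scalar in \[2/M, 1\].
#' @export
leaf_fraction <- function(t) {
  sum(tree_degrees(t) == 1) / (t$n_nodes - 1)
}

#' Normalised diameter
#'
#' Longest hop distance between any two nodes, divided by M = N - 1.
#'
#' @param t A `spanning_tree`.
#' @return Scalar in (0, 1\].
#' @export
diameter_norm <- function(t) {
  max(tree_eccentricities(t)) / (t$n_nodes - 1)
}

#' Normalised mean eccentricity
#'
#' A node's eccentricity is its longest hop distance to any other node; the
#' mean over nodes is divided by M = N - 1. The per-node maximum and minimum
#' are attached as attributes `max` and `min` (also normalised).
#'
#' @param t A `spanning_tree`.
#' @return Scalar; attributes `max`, `min`.
#' @export
eccentricity_norm <- function(t) {
  ecc <- tree_eccentricities(t)
  M <- t$n_nodes - 1
  structure(mean(ecc) / M, max = max(ecc) / M, min = min(ecc) / M)
}

#' Maximum normalised betweenness centrality
#'
#' Per node i, the fraction of ordered pairs (j, k), j != k, both != i,
#' whose unique tree path passes through i, normalised by (n-1)(n-2). In a
#' tree this equals ((n-1)^2 - sum of squared component sizes after removing
#' i) / ((n-1)(n-2)). Returns the maximum over nodes.
#'
#' @param t A `spanning_tree` with at least 3 nodes.
#' @return Scalar in \[0, 1\].
#' @export
bc_max <- function(t) {
  max(tree_betweenness(t))
}

#' @rdname bc_max
#' @return `tree_betweenness`: vector of per-node normalised betweenness.
#' @export
tree_betweenness <- function(t) {
  n <- t$n_nodes
  if (n < 3) stop("betweenness centrality needs at least 3 nodes")
  vapply(seq_len(n), function(v) {
    sizes <- vapply(tree_components(t, v), length, integer(1))
    ((n - 1)^2 - sum(sizes^2)) / ((n - 1) * (n - 2))
  }, numeric(1))
}

#' Tree hierarchy
#'
#' `T_H = N_leaf / (2 * M * BC_max)`: balances integration (many leaves)
#' against overload of the most central node. 0.5 for a star.
#'
#' @param t A `spanning_tree` with at least 3 nodes.
#' @return Positive scalar.
#' @export
tree_hierarchy <- function(t) {
  b <- bc_max(t)
  if (b <= 0) stop("tree hierarchy undefined: bc_max is zero")
  sum(tree_degrees(t) == 1) / (2 * (t$n_nodes - 1) * b)
}

#' Kappa (degree divergence)
#'
#' `kappa = <s^2> / <s>` over all N node degrees; grows with the broadness
#' of the degree distribution (32 for a 64-node star, ~1.98 for a path).
#'
#' @param t A `spanning_tree`.
#' @return Scalar >= 2(N-1)/N.
#' @export
kappa <- function(t) {
  s <- tree_degrees(t)
  mean(s^2) / mean(s)
}

#' All seven global tree metrics of one tree
#'
#' @param t A `spanning_tree`.
#' @return Named numeric vector: `degree`, `leaf_fraction`, `diameter`,
#'   `eccentricity`, `bc`, `tree_hierarchy`, `kappa`.
#' @export
tree_metrics <- function(t) {
  c(degree = degree_norm(t),
    leaf_fraction = leaf_fraction(t),
    diameter = diameter_norm(t),
    eccentricity = as.numeric(eccentricity_norm(t)),
    bc = bc_max(t),
    tree_hierarchy = tree_hierarchy(t),
    kappa = kappa(t))
}

#' Subject-level metric record from per-epoch trees
#'
#' Computes the seven tree metrics per tree, averages them arithmetically
#' across the subject's epochs, and appends the subject's mean PLI.
#'
#' @param trees Non-empty list of same-size `spanning_tree` objects.
#' @param mean_pli Scalar mean connectivity to carry along.
#' @return Named numeric vector with the seven averaged metrics plus `pli`.
#' @export
metric_record <- function(trees, mean_pli = NA_real_) {
  if (!is.list(trees) || length(trees) == 0) stop("need a non-empty list of trees")
  sizes <- vapply(trees, function(t) t$n_nodes, integer(1))
  if (length(unique(sizes)) != 1) {
    stop("trees differ in size: ", paste(unique(sizes), collapse = ", "))
  }
  per_tree <- vapply(trees, tree_metrics, numeric(7))
  c(pli = mean_pli, rowMeans(per_tree))
}

#' Write a tree as a 3-column edge list
#'
#' Tab-separated `label_i`, `label_j`, `weight`.
#'
#' @param t A `spanning_tree`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_tree <- function(t, path) {
  d <- data.frame(label_i = t$labels[t$edges$i], label_j = t$labels[t$edges$j],
                  weight = t$edges$weight)
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
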