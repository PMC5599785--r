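# Spanning-tree construction and global topology metrics.

test_that("build_tree maximises total weight (tiny enumerable cases)", {
  W <- matrix(0, 3, 3)
  W[1, 2] <- W[2, 1] <- 0.9
  W[1, 3] <- W[3, 1] <- 0.5
  W[2, 3] <- W[3, 2] <- 0.8
  t <- build_tree(W)
  expect_equal(sum(t$edges$weight), 1.7)
  got <- sort(paste(pmin(t$edges$i, t$edges$j), pmax(t$edges$i, t$edges$j)))
  expect_equal(got, c("1 2", "2 3"))

  # hub matrix -> exact star on the hub
  n <- 10
  W <- matrix(0.1, n, n)
  W[1, ] <- W[, 1] <- 0.9
  diag(W) <- 0
  th <- build_tree(W)
  expect_equal(sort(tree_degrees(th), decreasing = TRUE)[1], n - 1)
  expect_true(all(th$edges$i == 1 | th$edges$j == 1))

  expect_error(build_tree(matrix(0, 1, 1)), "at least 2")
  expect_error(build_tree(matrix(runif(6), 2, 3)), "square")
})

test_that("build_tree weight equals igraph's MST on 1 - w distances", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(5:16, 1)
    W <- random_connectivity(n)
    mine <- sum(build_tree(W)$edges$weight)
    g <- igraph::graph_from_adjacency_matrix(1 - W, mode = "undirected",
                                             weighted = TRUE, diag = FALSE)
    mst <- igraph::mst(g, weights = igraph::E(g)$weight)
    ref <- sum(1 - igraph::E(mst)$weight)
    expect_equal(mine, ref, tolerance = 1e-12)
  }
})

test_that("tie-breaking yields one deterministic tree", {
  set.seed(37)
  W <- random_connectivity(12, round_to = 1)  # heavy ties
  t1 <- build_tree(W)
  t2 <- build_tree(W)
  expect_identical(t1$edges, t2$edges)
  # ties broken by ascending (i, j): equal-weight matrix gives the star on 1
  U <- matrix(0.5, 5, 5)
  diag(U) <- 0
  tu <- build_tree(U)
  expect_true(all(tu$edges$i == 1))
})

test_that("closed-form metrics for star, path and small trees", {
  s64 <- star_tree(64)
  expect_equal(degree_norm(s64), 1)
  expect_equal(leaf_fraction(s64), 1)
  expect_equal(diameter_norm(s64), 2 / 63)
  expect_equal(as.numeric(eccentricity_norm(s64)), (1 + 63 * 2) / 64 / 63)
  expect_equal(bc_max(s64), 1)
  expect_equal(tree_hierarchy(s64), 0.5)
  expect_equal(kappa(s64), 32)

  p64 <- path_tree(64)
  expect_equal(degree_norm(p64), 2 / 63)
  expect_equal(leaf_fraction(p64), 2 / 63)
  expect_equal(diameter_norm(p64), 1)
  expect_equal(as.numeric(eccentricity_norm(p64)), 47.5 / 63)
  expect_equal(kappa(p64), 250 / 126)
  # path hierarchy from its own components
  expect_equal(tree_hierarchy(p64), 2 / (2 * 63 * bc_max(p64)))

  # balanced binary-ish tree on 7 nodes: leaves 4..7
  b7 <- tree_from_edges(rbind(c(1, 2), c(1, 3), c(2, 4), c(2, 5),
                              c(3, 6), c(3, 7)), 7)
  expect_equal(leaf_fraction(b7), 4 / 6)

  # path of 4: both interior nodes tie at 4/6
  p4 <- path_tree(4)
  expect_equal(tree_betweenness(p4)[2], 4 / 6)
  expect_equal(bc_max(p4), 4 / 6)

  # 2-node tree degeneracies
  t2 <- tree_from_edges(cbind(1, 2), 2)
  expect_equal(diameter_norm(t2), 1)
  expect_equal(as.numeric(eccentricity_norm(t2)), 1)
  expect_equal(kappa(t2), 1)
  expect_error(bc_max(t2), "at least 3")
})

test_that("metrics agree with igraph on random trees", {
  set.seed(41)
  for (rep in 1:15) {
    n <- sample(4:40, 1)
    t <- random_pruefer_tree(n)
    g <- as_igraph_tree(t)
    expect_equal(diameter_norm(t), igraph::diameter(g) / (n - 1))
    expect_equal(as.numeric(eccentricity_norm(t)),
                 mean(igraph::eccentricity(g)) / (n - 1))
    expect_equal(max(tree_degrees(t)), max(igraph::degree(g)))
    # igraph betweenness counts unordered pairs; ours is over ordered pairs
    # normalised by (n-1)(n-2), so the two differ by exactly 2/((n-1)(n-2))
    expect_equal(tree_betweenness(t),
                 2 * igraph::betweenness(g) / ((n - 1) * (n - 2)),
                 tolerance = 1e-12)
  }
})

test_that("metric bounds and kappa inequality hold on random trees", {
  set.seed(43)
  for (rep in 1:200) {
    n <- 64
    t <- random_pruefer_tree(n)
    M <- n - 1
    expect_true(leaf_fraction(t) >= 2 / M && leaf_fraction(t) <= 1)
    expect_true(diameter_norm(t) > 0 && diameter_norm(t) <= 1)
    b <- bc_max(t)
    expect_true(b >= 0 && b <= 1)
    expect_gte(kappa(t), 2 * M / n)  # variance non-negativity
    expect_gt(tree_hierarchy(t), 0)
    ec <- eccentricity_norm(t)
    expect_lte(as.numeric(ec), attr(ec, "max"))
    expect_gte(as.numeric(ec), attr(ec, "min"))
    expect_equal(sum(tree_degrees(t)), 2 * M)
  }
})

test_that("path-to-star interpolation moves the metrics monotonically", {
  # broom family: hub 1 carries k direct leaves plus one path of the rest
  n <- 24
  broom <- function(k) {
    edges <- cbind(1L, seq_len(k) + 1L)
    if (k + 2 <= n) {
      tail_nodes <- (k + 2):n
      edges <- rbind(edges,
                     cbind(c(1L, tail_nodes[-length(tail_nodes)]),
                           tail_nodes))
    }
    tree_from_edges(edges, n)
  }
  ks <- c(1, 4, 8, 12, 16, 20, n - 1)
  lf <- vapply(ks, function(k) leaf_fraction(broom(k)), numeric(1))
  kp <- vapply(ks, function(k) kappa(broom(k)), numeric(1))
  dm <- vapply(ks, function(k) diameter_norm(broom(k)), numeric(1))
  ec <- vapply(ks, function(k) as.numeric(eccentricity_norm(broom(k))),
               numeric(1))
  expect_true(all(diff(lf) >= 0))
  expect_true(all(diff(kp) >= 0))
  expect_true(all(diff(dm) <= 0))
  expect_true(all(diff(ec) <= 0))
})

test_that("metric_record averages per-tree metrics and carries mean PLI", {
  s <- star_tree(8)
  p <- path_tree(8)
  single <- metric_record(list(s), mean_pli = 0.4)
  expect_equal(unname(single["pli"]), 0.4)
  expect_equal(unname(single["leaf_fraction"]), 1)
  expect_equal(metric_record(list(s, s, s))[-1], metric_record(list(s))[-1])
  both <- metric_record(list(s, p))
  expect_equal(unname(both["leaf_fraction"]),
               (leaf_fraction(s) + leaf_fraction(p)) / 2)
  expect_error(metric_record(list(s, star_tree(9))), "differ in size")
  expect_error(metric_record(list()), "non-empty")
})

test_that("trees round-trip through the edge-list writer", {
  set.seed(47)
  W <- random_connectivity(6)
  dimnames(W) <- list(paste0("e", 1:6), paste0("e", 1:6))
  t <- build_tree(W)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_tree(t, path)
  d <- read.table(path, header = TRUE, sep = "\t")
  expect_equal(nrow(d), 5)
  expect_equal(d$weight, t$edges$weight, tolerance = 1e-12)
  expect_equal(d$label_i, t$labels[t$edges$i])
})
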