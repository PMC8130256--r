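test_that("equal-weight alternatives are retained as network reticulations", {
  # equilateral triangle: every pair is a tie, all three edges belong to
  # some minimum spanning tree
  m <- matrix(1, 3, 3, dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  diag(m) <- 0
  msn <- minimum_spanning_network(m)
  expect_equal(nrow(msn$edges), 3)
  # strict chain: distances force the unique path a-b-c-d
  m2 <- as.matrix(dist(c(a = 0, b = 1, c = 3, d = 6)))
  msn2 <- minimum_spanning_network(m2)
  expect_equal(nrow(msn2$edges), 3)
  expect_setequal(paste(msn2$edges$from, msn2$edges$to),
                  c("a b", "b c", "c d"))
})

test_that("network edges equal the union of all minimum spanning trees", {
  set.seed(51)
  for (rep in 1:5) {
    # round to one decimal to provoke ties
    x <- matrix(runif(8 * 2), 8)
    m <- round(as.matrix(dist(x)), 1)
    rownames(m) <- colnames(m) <- letters[1:8]
    msn <- minimum_spanning_network(m)
    oracle <- naive_msn_edges(m)
    expect_identical(edge_key(msn$edges), edge_key(oracle))
  }
})

test_that("every minimum spanning tree edge weight appears in the network", {
  set.seed(52)
  m <- as.matrix(dist(matrix(runif(14), 7)))
  rownames(m) <- colnames(m) <- letters[1:7]
  msn <- minimum_spanning_network(m)
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                           weighted = TRUE)
  mst <- igraph::mst(g)
  expect_equal(sum(msn$edges$weight[order(msn$edges$weight)][1:6]),
               sum(igraph::E(mst)$weight), tolerance = 1e-12)
  # with no ties the network is exactly a tree
  expect_equal(nrow(msn$edges), 6)
})

test_that("split decomposition reproduces an additive tree exactly", {
  set.seed(53)
  for (nt in c(5, 8)) {
    tr <- ape::rtree(nt)
    D <- ape::cophenetic.phylo(tr)
    o <- order(rownames(D))
    D <- D[o, o]
    s <- neighbor_net(D)
    expect_true(s$residual < 1e-8)
    expect_true(max(abs(split_distances(s) - D)) < 1e-8)
    # recovered splits match the generating tree's bipartitions and weights
    ts <- ddradpop:::tree_splits(tr)
    tip_of <- match(tr$tip.label, rownames(D))   # tree index -> taxon index
    n <- nt
    tree_tab <- tapply(ts$weights,
                       sapply(ts$splits, function(sp)
                         split_key(sort(tip_of[sp]), n)),
                       sum)
    tree_tab <- tree_tab[tree_tab > 1e-10]
    net_tab <- tapply(s$weights,
                      sapply(s$splits, split_key, n = n), sum)
    net_tab <- net_tab[net_tab > 1e-10]
    expect_setequal(names(net_tab), names(tree_tab))
    expect_equal(unname(net_tab[names(tree_tab)]), unname(tree_tab),
                 tolerance = 1e-8)
  }
})

test_that("a forward-constructed circular metric is recovered split by split", {
  # build a distance matrix as a known positive combination of splits
  # compatible with the ordering 1..6, then ask neighbor_net for it back
  taxa <- paste0("t", 1:6)
  splits <- list(2L, c(2L, 3L), c(3L, 4L, 5L), 5L, c(4L, 5L, 6L), 6L, 3L)
  weights <- c(0.5, 0.8, 1.1, 0.4, 0.9, 0.6, 0.3)
  n <- 6
  m <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (k in seq_along(splits)) {
    side <- logical(n); side[splits[[k]]] <- TRUE
    m <- m + weights[k] * outer(side, side, "!=")
  }
  s <- neighbor_net(m)
  expect_true(s$residual < 1e-8)
  got <- tapply(s$weights, sapply(s$splits, split_key, n = n), sum)
  want <- tapply(weights, sapply(splits, split_key, n = n), sum)
  expect_setequal(names(got), names(want))
  expect_equal(unname(got[names(want)]), unname(want), tolerance = 1e-8)
})

test_that("neighbor joining recovers a random tree topology from its distances", {
  set.seed(54)
  tr <- ape::rtree(10)
  D <- ape::cophenetic.phylo(tr)
  nj_tr <- neighbor_joining(D)
  expect_equal(ape::dist.topo(ape::unroot(tr), nj_tr), 0,
               ignore_attr = TRUE)
  path <- tempfile(fileext = ".nwk")
  neighbor_joining(D, path)
  reread <- ape::read.tree(path)
  expect_setequal(reread$tip.label, tr$tip.label)
  unlink(path)
})

test_that("split systems round-trip through the Nexus SPLITS format", {
  set.seed(55)
  tr <- ape::rtree(6)
  D <- ape::cophenetic.phylo(tr)
  s <- neighbor_net(D)
  path <- tempfile(fileext = ".nex")
  write_splits_nexus(s, path)
  s2 <- read_splits_nexus(path)
  expect_identical(s2$taxa, s$taxa)
  expect_identical(s2$cycle, as.integer(s$cycle))
  expect_identical(lapply(s2$splits, as.integer),
                   lapply(s$splits, as.integer))
  expect_equal(s2$weights, s$weights, tolerance = 1e-9)
  unlink(path)
})

test_that("non-Nexus input is rejected by the splits reader", {
  path <- tempfile()
  writeLines("not a nexus file", path)
  expect_error(read_splits_nexus(path), "not a Nexus")
  unlink(path)
})

test_that("networks are exported as well-formed GraphML", {
  m <- as.matrix(dist(c(a = 0, b = 1, c = 3)))
  msn <- minimum_spanning_network(m)
  path <- tempfile(fileext = ".graphml")
  write_msn_graphml(msn, path)
  g <- igraph::read_graph(path, format = "graphml")
  expect_equal(igraph::vcount(g), 3)
  expect_equal(igraph::ecount(g), nrow(msn$edges))
  unlink(path)
})

test_that("induced split distances honour the triangle inequality", {
  set.seed(56)
  m <- as.matrix(dist(matrix(runif(18), 9)))
  rownames(m) <- colnames(m) <- paste0("x", 1:9)
  s <- neighbor_net(m)
  Dhat <- split_distances(s)
  n <- nrow(Dhat)
  worst <- max(sapply(1:n, function(k)
    max(Dhat - outer(Dhat[, k], Dhat[k, ], "+"))))
  expect_true(worst <= 1e-9)
})
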