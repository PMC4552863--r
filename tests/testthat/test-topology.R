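test_that("unrewired small-world cluster is the exact ring lattice", {
  set.seed(1)
  A <- sw_cluster(10, k_ring = 4, p_rewire = 0)
  expect_equal(unname(colSums(A)), rep(4, 10))
  expect_equal(sum(A) / 2, 20)
  # neighbors at ring distance 1 and 2
  expect_equal(A[1, c(2, 3, 9, 10)], rep(1, 4))
})

test_that("rewiring conserves the edge count and connectivity", {
  set.seed(2)
  for (p in c(0.1, 0.5, 1)) {
    A <- sw_cluster(10, 4, p)
    expect_equal(sum(A) / 2, 20)
    expect_true(igraph::is_connected(as_igraph(A)))
  }
  expect_error(sw_cluster(10, 3, 0.1), "even")
  expect_error(sw_cluster(4, 4, 0.1), "n > k_ring")
})

test_that("ring of clusters has block-diagonal A and a hub cycle in B", {
  set.seed(3)
  net <- ring_of_clusters(6, 10, k_ring = 4, p_rewire = 0.1)
  expect_s3_class(net, "connectome")
  expect_equal(net$n, 60)
  expect_equal(length(unique(net$labels)), 6)
  # A strictly intra-cluster
  different <- outer(net$labels, net$labels, "!=")
  expect_true(all(net$A[different] == 0))
  # B strictly inter-cluster, exactly N_c links forming one cycle over hubs
  expect_true(all(net$B[!different] == 0))
  expect_equal(sum(net$B) / 2, 6)
  gB <- as_igraph(net$B)
  deg <- igraph::degree(gB)
  expect_equal(sort(unique(deg)), c(0, 2))
  sub <- igraph::induced_subgraph(gB, which(deg > 0))
  expect_true(igraph::is_connected(sub))
  expect_equal(igraph::vcount(sub), 6)
})

test_that("generated connectomes satisfy the type invariants across seeds", {
  for (seed in 1:25) {
    set.seed(seed)
    kind <- sample(c("small_world", "erdos_renyi", "barabasi_albert",
                     "perturbed_star"), 1)
    net <- ring_of_clusters(3, 6, kind = kind)
    for (M in list(net$A, net$B)) {
      expect_true(all(M %in% c(0, 1)))
      expect_identical(M, t(M))
      expect_true(all(diag(M) == 0))
    }
    expect_identical(net$C, pmax(net$A, net$B))
    expect_true(igraph::is_connected(as_igraph(net)))
  }
})

test_that("alternative cluster families hit their closed-form edge counts", {
  set.seed(4)
  # pure star
  A <- alt_cluster("perturbed_star", 9, f = 0)
  deg <- colSums(A)
  expect_equal(max(deg), 8)
  expect_equal(sort(deg), c(rep(1, 8), 8))
  # perturbed star preserves the edge count
  A <- alt_cluster("perturbed_star", 20, f = 0.2)
  expect_equal(sum(A) / 2, 19)
  # Barabasi-Albert: m edges per vertex after the seed clique
  m <- 2
  A <- alt_cluster("barabasi_albert", 12, m = m)
  expect_equal(sum(A) / 2 - choose(m, 2), (12 - m) * m)
  # complete-graph limit of Erdos-Renyi
  A <- alt_cluster("erdos_renyi", 7, p = 1)
  expect_equal(sum(A) / 2, choose(7, 2))
})

test_that("Erdos-Renyi edge counts are binomial", {
  set.seed(5)
  n <- 12; p <- 0.4; draws <- 60
  total <- 0
  for (i in seq_len(draws)) {
    g <- igraph::sample_gnp(n, p)  # unconditioned draws for the null
    total <- total + igraph::ecount(g)
  }
  pv <- stats::binom.test(total, draws * choose(n, 2), p)$p.value
  expect_gt(pv, 0.01)
})

test_that("connectome files round-trip through all three formats", {
  set.seed(6)
  net <- ring_of_clusters(3, 5)
  for (fmt in c("edge_list", "csv_matrix", "graphml")) {
    path <- tempfile(fileext = switch(fmt, graphml = ".graphml",
                                      csv_matrix = ".csv", ".txt"))
    write_connectome(net, path, format = fmt)
    back <- read_connectome(path, format = fmt)
    expect_equal(back$C, net$C, ignore_attr = TRUE)
  }
})

test_that("loading symmetrizes, drops self-loops, and removes isolates", {
  # directed edge list -> undirected closure
  f <- tempfile()
  writeLines(c("# comment", "1 2", "2 3", "3 1"), f)
  net <- read_connectome(f, format = "edge_list")
  expect_equal(net$n, 3)
  expect_identical(net$A, t(net$A))
  expect_equal(sum(net$A) / 2, 3)
  # matrix with an all-zero row/column loses that node
  M <- matrix(0, 4, 4)
  M[1, 2] <- M[2, 1] <- M[2, 3] <- M[3, 2] <- 1
  f2 <- tempfile(fileext = ".csv")
  write.table(M, f2, sep = ",", row.names = FALSE, col.names = FALSE)
  expect_message(net2 <- read_connectome(f2, format = "csv_matrix"),
                 "isolated")
  expect_equal(net2$n, 3)
  # self-loops dropped with a warning
  f3 <- tempfile()
  writeLines(c("1 1", "1 2"), f3)
  expect_warning(net3 <- read_connectome(f3, format = "edge_list"),
                 "self-loop")
  expect_equal(sum(net3$A) / 2, 1)
  # malformed input names the offending line
  f4 <- tempfile()
  writeLines(c("1 2", "oops"), f4)
  expect_error(read_connectome(f4, format = "edge_list"), "line 2")
})

test_that("the constructor rejects invalid adjacency matrices", {
  expect_error(connectome(matrix(c(0, 2, 2, 0), 2)), "binary")
  expect_error(connectome(matrix(c(0, 1, 0, 0), 2)), "symmetric")
  expect_error(connectome(diag(2)), "diagonal")
  expect_error(connectome(matrix(0, 2, 3)), "square")
})
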