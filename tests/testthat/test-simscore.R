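test_that("topology operator matches its elementwise definition", {
  # single edge in each network: degrees are all 1, so the two compatible
  # neighbour pairs receive full support
  G1 <- net_snapshot(c("a", "b"), rbind(c("a", "b")))
  G2 <- net_snapshot(c("x", "y"), rbind(c("x", "y")))
  op <- topology_support(G1, G2)
  A <- as.matrix(op)
  # pair (u, v) -> index (v-1)*m + u over sorted node orders
  p <- function(u, v) (v - 1L) * 2L + u
  expect_equal(A[p(1, 1), p(2, 2)], 1) # (a,x) <- (b,y)
  expect_equal(A[p(1, 2), p(2, 1)], 1) # (a,y) <- (b,x)
  expect_equal(A[p(2, 2), p(1, 1)], 1)
  expect_equal(sum(A), 4)

  # edgeless snapshots give the zero operator
  op0 <- topology_support(net_snapshot(c("a", "b")), net_snapshot("x"))
  expect_true(all(as.matrix(op0) == 0))
})

test_that("operator entries and column sums follow the degree formula", {
  withr::local_seed(5)
  for (rep in 1:5) {
    n1 <- random_temporal_network(sample(3:5, 1), 1, p = 0.6)
    n2 <- random_temporal_network(sample(3:6, 1), 1, p = 0.5,
                                  labels = sprintf("m%02d", 1:sample(3:6, 1)))
    G1 <- get_snapshot(n1, 1)
    G2 <- get_snapshot(n2, 1)
    op <- topology_support(G1, G2)
    A <- as.matrix(op)
    m <- length(G1$nodes)
    n <- length(G2$nodes)
    g1 <- igraph_snapshot(n1, 1)
    g2 <- igraph_snapshot(n2, 1)
    d1 <- igraph::degree(g1)[G1$nodes]
    d2 <- igraph::degree(g2)[G2$nodes]
    # naive elementwise construction from the definition
    ref <- matrix(0, m * n, m * n)
    for (u in 1:m) for (v in 1:n) for (w in 1:m) for (z in 1:n) {
      if (igraph::are_adjacent(g1, G1$nodes[u], G1$nodes[w]) &&
          igraph::are_adjacent(g2, G2$nodes[v], G2$nodes[z])) {
        ref[(v - 1) * m + u, (z - 1) * m + w] <- 1 / (d1[w] * d2[z])
      }
    }
    expect_equal(A, ref, tolerance = 1e-12)
    cs <- colSums(A)
    pos <- as.vector(outer(d1 > 0, d2 > 0)) > 0
    expect_true(all(abs(cs[pos] - 1) < 1e-12))
    expect_true(all(cs[!pos] == 0))
  }
})

test_that("propagation: alpha = 0 short-circuit and edgeless closed form", {
  G1 <- net_snapshot(c("a", "b"), rbind(c("a", "b")))
  G2 <- net_snapshot(c("x", "y", "z"), rbind(c("x", "y")))
  op <- topology_support(G1, G2)
  H <- matrix(c(1, 2, 3, 4, 5, 6), 2, 3)
  S0 <- propagate(op, H, alpha = 0)
  expect_identical(attr(S0, "iterations"), 1L)
  expect_equal(as.numeric(S0), as.numeric(H / sum(H))) # exactly H^0
  expect_equal(attr(S0, "scale"), sum(H))

  # both snapshots edgeless: A = 0, fixed point (1 - alpha) * h0
  opz <- topology_support(net_snapshot(c("a", "b")),
                          net_snapshot(c("x", "y", "z")))
  Sz <- propagate(opz, H, alpha = 0.7)
  expect_equal(as.numeric(Sz), as.numeric(0.3 * H / sum(H)),
               tolerance = 1e-12)
  expect_true(attr(Sz, "converged"))
})

test_that("propagation fixed point solves (I - alpha A) x = (1-alpha) h0", {
  withr::local_seed(17)
  for (rep in 1:8) {
    n1 <- random_temporal_network(sample(2:4, 1), 1, p = 0.7)
    n2 <- random_temporal_network(sample(3:6, 1), 1, p = 0.5,
                                  labels = sprintf("m%02d", 1:6))
    op <- topology_support(get_snapshot(n1, 1), get_snapshot(n2, 1))
    m <- length(n1$nodes)
    n <- length(n2$nodes)
    H <- matrix(runif(m * n), m, n)
    alpha <- runif(1, 0.1, 0.95)
    S <- propagate(op, H, alpha = alpha, tol = 1e-12, max_iter = 500)
    A <- as.matrix(op)
    h0 <- as.vector(H / sum(H))
    x <- solve(diag(m * n) - alpha * A, (1 - alpha) * h0)
    expect_lt(max(abs(as.vector(S) - x)), 1e-8)
    expect_true(all(as.vector(S) >= 0))
  }
})

test_that("hitting max_iter warns and flags non-convergence", {
  G1 <- net_snapshot(c("a", "b", "c"), rbind(c("a", "b"), c("b", "c")))
  op <- topology_support(G1, G1)
  H <- matrix(runif(9), 3, 3)
  expect_warning(
    S <- propagate(op, H, alpha = 0.9, tol = 1e-15, max_iter = 3L),
    "did not reach"
  )
  expect_false(attr(S, "converged"))
})

test_that("per-time scores aggregate across time points", {
  withr::local_seed(23)
  labels2 <- sprintf("m%02d", 1:5)
  snap1 <- rbind(c("a", "b"), c("b", "c"))
  snap2 <- rbind(c("m01", "m02"), c("m02", "m03"), c("m04", "m05"))
  H <- matrix(runif(15), 3, 5,
              dimnames = list(c("a", "b", "c"), labels2))

  n1_t1 <- temporal_network(list(snap1))
  n2_t1 <- temporal_network(list(snap2), nodes = labels2)
  s1 <- score_all_time_points(n1_t1, n2_t1, H, alpha = 0.7)
  expect_equal(s1$aggregate, s1$per_time[[1L]])

  # identical snapshots repeated: aggregate is t * per-time
  n1_t3 <- temporal_network(list(snap1, snap1, snap1))
  n2_t3 <- temporal_network(list(snap2, snap2, snap2), nodes = labels2)
  s3 <- score_all_time_points(n1_t3, n2_t3, H, alpha = 0.7)
  expect_equal(s3$aggregate, 3 * s3$per_time[[1L]], tolerance = 1e-9)
  expect_equal(s3$per_time[[1L]], s1$per_time[[1L]], tolerance = 1e-12)

  # alpha = 0: aggregate is t * normalized H
  s0 <- score_all_time_points(n1_t3, n2_t3, H, alpha = 0)
  expect_equal(s0$aggregate, 3 * H / sum(H), tolerance = 1e-12,
               ignore_attr = TRUE)

  expect_error(score_all_time_points(n1_t1, n2_t3, H), "time-point counts")
})

test_that("homology TSV reader fills absent pairs with zero", {
  f <- withr::local_tempfile()
  writeLines(c("# scores", "a\tx\t2.5", "b\ty\t1"), f)
  H <- read_homology(f, query_nodes = c("a", "b"),
                     target_nodes = c("x", "y", "z"))
  expect_equal(dim(H), c(2L, 3L))
  expect_equal(H["a", "x"], 2.5)
  expect_equal(H["b", "y"], 1)
  expect_equal(sum(H != 0), 2L)
  # writer round trip
  f2 <- withr::local_tempfile()
  write_homology(H, f2)
  H2 <- read_homology(f2, rownames(H), colnames(H))
  expect_equal(H2, H)
  expect_error(read_homology(f, query_nodes = "a", target_nodes = "x"),
               "unknown node")
})

test_that("score set writer emits per-time and aggregate tables", {
  n1 <- temporal_network(list(rbind(c("a", "b"))))
  n2 <- temporal_network(list(rbind(c("x", "y"))))
  H <- matrix(1:4 / 10, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  s <- score_all_time_points(n1, n2, H)
  prefix <- file.path(withr::local_tempdir(), "scores")
  paths <- write_score_set(s, prefix)
  expect_equal(length(paths), 2L)
  tab <- read.table(paths[2L], sep = "\t", stringsAsFactors = FALSE)
  expect_equal(nrow(tab), 4L)
  expect_equal(tab[tab$V1 == "a" & tab$V2 == "x", "V3"],
               s$aggregate["a", "x"], tolerance = 1e-10)
})
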