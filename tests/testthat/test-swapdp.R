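# Reconstruction of the three-component illustration: aligned target nodes
# b1..b11 split into components {b1..b4}, {b5..b7}, {b8..b11} (b8 is the
# hub of the third), gap nodes {b12, b13, b14}; b14 bridges the second and
# third components, so swapping b11 with b14 merges them (NCC 3 -> 2)
# while swapping out the hub b8 shatters its component (NCC -> 4).
fig2_fixture <- function() {
  edges <- rbind(
    c("b01", "b02"), c("b02", "b03"), c("b03", "b04"),
    c("b05", "b06"), c("b06", "b07"),
    c("b08", "b09"), c("b08", "b10"), c("b08", "b11"),
    c("b14", "b07"), c("b14", "b10")
  )
  target <- temporal_network(list(edges),
                             nodes = sprintf("b%02d", 1:14))
  qn <- sprintf("a%02d", 1:11)
  query <- temporal_network(list(cbind(qn[-11], qn[-1])), nodes = qn)
  psi <- node_map(setNames(sprintf("b%02d", 1:11), qn), target$nodes)
  zero <- make_scores(list(matrix(0, 11, 14)), qn, target$nodes)
  list(query = query, target = target, psi = psi, scores = zero)
}

test_that("swapping is an involution and disjoint swaps commute", {
  fx <- fig2_fixture()
  psi <- fx$psi
  s1 <- apply_swap(psi, "b11", "b14")
  expect_equal(s1$psi[["a11"]], "b14")
  expect_true("b11" %in% s1$gap)
  expect_equal(apply_swap(s1, "b14", "b11")$psi, psi$psi)
  # disjoint swaps commute
  ab <- apply_swap(apply_swap(psi, "b11", "b14"), "b01", "b12")
  ba <- apply_swap(apply_swap(psi, "b01", "b12"), "b11", "b14")
  expect_equal(ab$psi, ba$psi)
  expect_error(apply_swap(psi, "b14", "b12"), "not an aligned")
  expect_error(apply_swap(psi, "b01", "b02"), "not a gap")
})

test_that("the bridge swap merges components and wins when delta dominates", {
  fx <- fig2_fixture()
  g2 <- get_snapshot(fx$target, 1)
  expect_equal(ncc(induced_subnetwork(g2, fx$psi$image)), 3L)
  merged <- apply_swap(fx$psi, "b11", "b14")
  expect_equal(ncc(induced_subnetwork(g2, merged$image)), 2L)
  shattered <- apply_swap(fx$psi, "b08", "b14")
  expect_equal(ncc(induced_subnetwork(g2, shattered$image)), 4L)

  delta <- 1
  bd0 <- alignment_score(fx$query, fx$target, fx$scores, fx$psi, delta)
  bd1 <- alignment_score(fx$query, fx$target, fx$scores, merged, delta)
  expect_equal(bd0$total - bd1$total, -delta) # penalty drops by delta

  best <- best_single_swap(fx$query, fx$target, fx$scores, fx$psi,
                           "b11", delta)
  expect_equal(unname(best$swap["v"]), "b14")
  expect_equal(best$score, bd1$total)
})

test_that("best single swap equals an exhaustive scan", {
  withr::local_seed(53)
  for (rep in 1:10) {
    m <- sample(2:4, 1)
    n <- m + sample(1:3, 1)
    n1 <- random_temporal_network(m, sample(1:2, 1), 0.6,
                                  labels = sprintf("q%02d", 1:m))
    n2 <- random_temporal_network(n, n1$t, 0.4,
                                  labels = sprintf("t%02d", 1:n))
    sc <- random_scores(n1, n2)
    psi <- random_node_map(n1$nodes, n2$nodes)
    delta <- max(sc$aggregate)
    u <- sample(psi$image, 1)
    got <- best_single_swap(n1, n2, sc, psi, u, delta)
    expect_equal(got$score,
                 brute_force_single_swap(n1, n2, sc, psi, u, delta),
                 tolerance = 1e-10)
  }
  fx <- fig2_fixture()
  full <- node_map(setNames(sprintf("b%02d", 1:14),
                            sprintf("a%02d", 1:14)),
                   fx$target$nodes)
  expect_error(
    best_single_swap(fx$query, fx$target, fx$scores, full, "b01", 1),
    "no gap nodes"
  )
})

test_that("k = 1 DP equals the exhaustive single-swap optimum", {
  withr::local_seed(59)
  for (rep in 1:8) {
    m <- sample(2:4, 1)
    n <- m + sample(1:3, 1)
    n1 <- random_temporal_network(m, sample(1:2, 1), 0.6,
                                  labels = sprintf("q%02d", 1:m))
    n2 <- random_temporal_network(n, n1$t, 0.4,
                                  labels = sprintf("t%02d", 1:n))
    sc <- random_scores(n1, n2)
    psi0 <- initial_alignment(sc)
    delta <- default_delta(sc)
    res <- select_swaps(n1, n2, sc, psi0, k = 1, delta = delta)
    base <- naive_alignment_score(n1, n2, sc, psi0, delta)
    best1 <- base
    for (u in psi0$image) {
      best1 <- max(best1,
                   brute_force_single_swap(n1, n2, sc, psi0, u, delta))
    }
    expect_equal(res$final_score, best1, tolerance = 1e-10)
    expect_equal(res$breakdown$total, res$final_score, tolerance = 1e-10)
  }
})

test_that("DP score is sandwiched between initial and exhaustive optimum", {
  withr::local_seed(61)
  for (rep in 1:10) {
    m <- sample(2:4, 1)
    n <- m + sample(2:3, 1)
    tt <- sample(1:2, 1)
    n1 <- random_temporal_network(m, tt, 0.6, labels = sprintf("q%02d", 1:m))
    n2 <- random_temporal_network(n, tt, 0.4, labels = sprintf("t%02d", 1:n))
    sc <- random_scores(n1, n2)
    psi0 <- initial_alignment(sc)
    delta <- default_delta(sc)
    k <- min(2L, length(psi0$gap))
    res <- select_swaps(n1, n2, sc, psi0, k = k, delta = delta)
    init <- naive_alignment_score(n1, n2, sc, psi0, delta)
    opt <- brute_force_swapsets(n1, n2, sc, psi0, k, delta)
    expect_gte(res$final_score + 1e-10, init)
    expect_lte(res$final_score - 1e-10, opt)
    # the applied swap set reproduces the reported score from scratch
    expect_equal(naive_alignment_score(n1, n2, sc, res$psi, delta),
                 res$final_score, tolerance = 1e-10)
  }
})

test_that("connected images with dominant delta yield no swaps", {
  # image already connected at the single time point; any swap only moves
  # similarity mass around and delta exceeds every entry, so the DP keeps
  # the initial alignment
  n1 <- temporal_network(list(rbind(c("q1", "q2"))))
  n2 <- temporal_network(list(rbind(c("x", "y"), c("y", "z"))))
  sc <- make_scores(list(rbind(c(1, 0.1, 0), c(0.1, 1, 0))),
                    n1$nodes, n2$nodes)
  psi0 <- initial_alignment(sc)
  expect_equal(unname(psi0$psi), c("x", "y"))
  res <- select_swaps(n1, n2, sc, psi0, k = 1, delta = default_delta(sc))
  expect_equal(nrow(res$swaps), 0L)
  expect_equal(res$final_score, res$initial_score)
})

test_that("default k reflects the worst time point, floored and capped", {
  # connected image at all time points -> floor of 1
  n2 <- temporal_network(list(rbind(c("x", "y"), c("y", "z"))))
  psi <- node_map(c(a = "x", b = "y"), n2$nodes)
  expect_equal(default_k(n2, psi), 1L)
  # 5 isolated aligned nodes, |F| large -> 5 - 1 = 4
  n2b <- temporal_network(list(rbind(c("g1", "g2"))),
                          nodes = c(paste0("i", 1:5), paste0("g", 1:6)))
  psi_b <- node_map(setNames(paste0("i", 1:5), paste0("q", 1:5)), n2b$nodes)
  expect_equal(default_k(n2b, psi_b), 4L)
  # cap at |F|: 9 isolated aligned nodes but only 2 gap nodes
  n2c <- temporal_network(list(matrix(character(0), ncol = 2)),
                          nodes = c(paste0("i", 1:9), "g1", "g2"))
  psi_c <- node_map(setNames(paste0("i", 1:9), paste0("q", 1:9)), n2c$nodes)
  expect_equal(default_k(n2c, psi_c), 2L)
  # no gap nodes at all -> 0 (phase II impossible)
  psi_full <- node_map(setNames(n2$nodes, c("a", "b", "c")), n2$nodes)
  expect_equal(default_k(n2, psi_full), 0L)
})

test_that("select_swaps validates k and warns on a weak delta", {
  n1 <- temporal_network(list(rbind(c("q1", "q2"))))
  n2 <- temporal_network(list(rbind(c("x", "y"))), nodes = c("x", "y", "z"))
  sc <- random_scores(n1, n2)
  psi0 <- initial_alignment(sc)
  expect_error(select_swaps(n1, n2, sc, psi0, k = 5, delta = 10), "<= |F|",
               fixed = TRUE)
  expect_warning(select_swaps(n1, n2, sc, psi0, k = 1, delta = 0),
                 "not guaranteed")
})

test_that("coverage gadget: component counts obey the beta identity", {
  sets <- list(A = c("x1", "x2", "x3"), B = c("x3", "x4"), C = "x5")
  red <- mcp_reduction(sets, k = 2)
  m <- 3L
  n <- 5L
  g <- get_snapshot(red$target, 1)
  # the induced aligned subnetwork has no edges: n + m singleton components
  ind <- induced_subnetwork(g, red$aligned)
  expect_equal(nrow(ind$edges), 0L)
  expect_equal(ncc(ind), n + m)
  # swap f1, f2 in for b1, b2: covered tau = |A u B| = 4,
  # beta = (m - k) + (n - tau) + 1
  image <- c(setdiff(red$aligned, c("b01", "b02")), "f01", "f02")
  expect_equal(ncc(induced_subnetwork(g, image)), (m - 2L) + (n - 4L) + 1L)
  # one set covering the whole universe, k = 1: NCC drops from n + m to m
  red2 <- mcp_reduction(list(S = c("e1", "e2", "e3")), k = 1)
  g2 <- get_snapshot(red2$target, 1)
  expect_equal(ncc(induced_subnetwork(g2, red2$aligned)), 3L + 1L)
  img2 <- c(setdiff(red2$aligned, "b01"), "f01")
  expect_equal(ncc(induced_subnetwork(g2, img2)), 1L)
})
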