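test_that("hot rate follows its closed form and flags infeasibility", {
  expect_equal(hot_rate(0.3, 0.3, 0.5), 0.3)   # equal rates: identity
  expect_equal(hot_rate(0.4, 0.1, 0), 0.4)     # no cold edges
  expect_equal(hot_rate(0.2, 0.05, 0.25), (0.2 - 0.05 * 0.25) / 0.75)
  expect_error(hot_rate(0.8, 0.05, 0.25), "infeasible hot rate 1.05",
               fixed = TRUE)
  expect_error(hot_rate(0.5, 0.1, 1), "gamma")
  expect_error(hot_rate(0.1, 0.2, 0.5), "epsilon_c <= epsilon")
})

test_that("scale-free target generation is connected with the right density", {
  g5 <- generate_target_t0(5, 4, seed = 1)
  # attachment a = 2: a*(n-a) + choose(a,2) = 2*3 + 1 = 7 edges
  expect_equal(nrow(g5$edges), 7L)
  for (s in 1:5) {
    g <- generate_target_t0(40, 4, seed = s)
    expect_equal(ncc(g), 1L)
    expect_equal(nrow(g$edges), 2L * 40L - 3L)
  }
  g1k <- generate_target_t0(1000, 4, seed = 9)
  mean_deg <- 2 * nrow(g1k$edges) / 1000
  expect_gt(mean_deg, 3.6)
  expect_lt(mean_deg, 4.4)
  expect_identical(generate_target_t0(50, 4, seed = 3)$edges,
                   generate_target_t0(50, 4, seed = 3)$edges)
  expect_error(generate_target_t0(3, 4), "n >= mean_degree")
  expect_error(generate_target_t0(10, 3), "even")
})

test_that("planted queries are connected induced subnetworks", {
  tgt <- generate_target_t0(60, 4, seed = 2)
  # whole target: gamma = 1 territory
  all_p <- plant_query(tgt, 60, seed = 1)
  expect_equal(all_p$cold_nodes, tgt$nodes)
  expect_equal(nrow(all_p$cold_edges), nrow(tgt$edges))
  one_p <- plant_query(tgt, 1, seed = 1)
  expect_equal(nrow(one_p$cold_edges), 0L)
  for (s in 1:25) {
    p <- plant_query(tgt, 12, seed = s)
    expect_equal(ncc(p$query_t0), 1L)
    # induced subnetwork on cold nodes == query, edge for edge
    expect_equal(induced_subnetwork(tgt, p$cold_nodes)$edges,
                 p$query_t0$edges)
    expect_equal(unname(p$truth), names(p$truth)) # origin labels kept
  }
})

test_that("evolution conserves edge counts and respects zero/full rates", {
  tgt <- generate_target_t0(50, 4, seed = 4)
  p <- plant_query(tgt, 15, seed = 4)
  frozen <- evolve_snapshot(tgt, p$cold_nodes, p$cold_edges, 0, 0, seed = 1)
  expect_equal(frozen$edges, tgt$edges)
  expect_equal(attr(frozen, "cold_edges"), p$cold_edges)
  churned <- evolve_snapshot(tgt, p$cold_nodes, p$cold_edges, 1, 1, seed = 1)
  expect_equal(nrow(churned$edges), nrow(tgt$edges))
  expect_equal(nrow(attr(churned, "cold_edges")), nrow(p$cold_edges))
  # replacement cold edges stay inside the cold region
  ce <- attr(churned, "cold_edges")
  expect_true(all(ce %in% p$cold_nodes))
})

test_that("realized turnover matches the requested rates", {
  eps_c <- 0.1
  eps_h <- 0.3
  removed_cold <- 0L
  total_cold <- 0L
  removed_hot <- 0L
  total_hot <- 0L
  for (s in 1:10) {
    tgt <- generate_target_t0(150, 4, seed = s)
    p <- plant_query(tgt, 40, seed = s)
    nxt <- evolve_snapshot(tgt, p$cold_nodes, p$cold_edges, eps_c, eps_h,
                           seed = s + 100)
    key <- function(e) paste(e[, 1L], e[, 2L])
    all_k <- key(tgt$edges)
    cold_k <- key(p$cold_edges)
    hot_k <- setdiff(all_k, cold_k)
    surv <- key(nxt$edges)
    removed_cold <- removed_cold + sum(!(cold_k %in% surv))
    total_cold <- total_cold + length(cold_k)
    removed_hot <- removed_hot + sum(!(hot_k %in% surv))
    total_hot <- total_hot + length(hot_k)
  }
  se_c <- sqrt(eps_c * (1 - eps_c) / total_cold)
  se_h <- sqrt(eps_h * (1 - eps_h) / total_hot)
  expect_lt(abs(removed_cold / total_cold - eps_c), 3 * se_c)
  expect_lt(abs(removed_hot / total_hot - eps_h), 3 * se_h)
})

test_that("homology draws favour planted pairs and are reproducible", {
  qn <- sprintf("v%02d", 1:10)
  tn <- sprintf("v%02d", 1:40)
  truth <- setNames(qn, qn)
  H1 <- synth_homology(truth, qn, tn, cold_nodes = qn, mu = 2,
                       sigma = 0.25, seed = 5)
  H2 <- synth_homology(truth, qn, tn, cold_nodes = qn, mu = 2,
                       sigma = 0.25, seed = 5)
  expect_identical(H1, H2)
  planted_all <- H1[cbind(qn, qn)]
  off <- H1
  off[cbind(qn, qn)] <- NA
  expect_gt(mean(planted_all), mean(off, na.rm = TRUE))
  # sigma -> 0: scores pin to exp(2 mu) on planted pairs, exp(mu) elsewhere
  Hd <- synth_homology(truth, qn, tn, cold_nodes = qn, mu = 2,
                       sigma = 1e-9, seed = 1)
  expect_equal(unname(diag(Hd[qn, qn])), rep(exp(4), 10), tolerance = 1e-6)
  expect_equal(Hd["v01", "v30"], exp(2), tolerance = 1e-6)
})

test_that("full instances are reproducible and respect their invariants", {
  params <- synthetic_params(n_target = 80, q_size = 20, t = 4,
                             epsilon = 0.2, epsilon_c = 0.05, seed = 42)
  a <- generate_instance(params)
  b <- generate_instance(params)
  expect_identical(a$target$snapshots, b$target$snapshots)
  expect_identical(a$query$snapshots, b$query$snapshots)
  expect_identical(a$homology, b$homology)
  expect_equal(a$gamma, nrow(a$cold_edges) / nrow(a$target$snapshots[[1]]))
  # query snapshot 0 is the cold induced subnetwork, and stays connected
  expect_equal(get_snapshot(a$query, 1)$edges,
               induced_subnetwork(get_snapshot(a$target, 1),
                                  a$cold_nodes)$edges)
  for (i in seq_len(a$query$t)) {
    expect_equal(ncc(get_snapshot(a$query, i)), 1L)
    expect_equal(nrow(a$query$snapshots[[i]]),
                 nrow(a$query$snapshots[[1]]))
    expect_equal(nrow(a$target$snapshots[[i]]),
                 nrow(a$target$snapshots[[1]]))
  }
  # frozen evolution: every snapshot equals the first
  frozen <- generate_instance(synthetic_params(
    n_target = 60, q_size = 15, t = 3, epsilon = 0, epsilon_c = 0, seed = 7
  ))
  for (i in 2:3) {
    expect_equal(frozen$target$snapshots[[i]], frozen$target$snapshots[[1]])
    expect_equal(frozen$query$snapshots[[i]], frozen$query$snapshots[[1]])
  }
  # t = 1: no evolution at all
  t1 <- generate_instance(synthetic_params(
    n_target = 60, q_size = 15, t = 1, epsilon = 0.8, epsilon_c = 0.2,
    seed = 7
  ))
  expect_equal(t1$target$t, 1L)
  # infeasible hot rate aborts
  expect_error(
    generate_instance(synthetic_params(n_target = 30, q_size = 25, t = 2,
                                       epsilon = 0.8, epsilon_c = 0.05,
                                       seed = 1)),
    "infeasible hot rate"
  )
})

test_that("instances serialize to a directory and read back consistently", {
  params <- synthetic_params(n_target = 40, q_size = 10, t = 2,
                             epsilon = 0.1, epsilon_c = 0.05, seed = 3)
  inst <- generate_instance(params)
  dir <- withr::local_tempdir()
  write_instance(inst, dir)
  expect_true(all(file.exists(file.path(
    dir, c("query.tsv", "target.tsv", "homology.tsv", "truth.tsv",
           "params.yaml")
  ))))
  tgt <- read_temporal_network(file.path(dir, "target.tsv"))
  expect_equal(tgt$snapshots, inst$target$snapshots)
  H <- read_homology(file.path(dir, "homology.tsv"),
                     inst$query$nodes, inst$target$nodes)
  expect_equal(H, inst$homology, tolerance = 1e-10)
  y <- yaml::read_yaml(file.path(dir, "params.yaml"))
  expect_equal(y$epsilon, 0.1)
})

test_that("parameter validation catches inconsistent settings", {
  expect_error(synthetic_params(epsilon = 0.1, epsilon_c = 0.2),
               "epsilon_c <= epsilon")
  expect_error(synthetic_params(n_target = 10, q_size = 20), "q_size")
  expect_error(synthetic_params(mean_degree = 3), "even")
  expect_error(synthetic_params(t = 0), "t must be")
})
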