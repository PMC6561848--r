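# Independent naive re-implementations and fixture builders used as
# oracles throughout the suite. Everything here deliberately avoids the
# package's internal code paths: components come from igraph, scores from
# explicit loops, optima from exhaustive enumeration.

# random Erdos-Renyi-ish temporal network over n nodes, t snapshots
random_temporal_network <- function(n, t, p = 0.3,
                                    labels = sprintf("n%02d", seq_len(n))) {
  pairs <- t(combn(labels, 2L))
  snaps <- lapply(seq_len(t), function(i) {
    keep <- runif(nrow(pairs)) < p
    pairs[keep, , drop = FALSE]
  })
  temporal_network(snaps, nodes = labels)
}

# assemble a tempo_scores object directly from per-time matrices
make_scores <- function(per_time, query_nodes, target_nodes, alpha = 0.7) {
  per_time <- lapply(per_time, function(M) {
    dimnames(M) <- list(query_nodes, target_nodes)
    M
  })
  structure(
    list(query_nodes = query_nodes, target_nodes = target_nodes,
         H = per_time[[1L]], scale = 1, alpha = alpha, tol = 1e-9,
         per_time = per_time, aggregate = Reduce(`+`, per_time),
         t = length(per_time), iterations = rep(1L, length(per_time)),
         converged = rep(TRUE, length(per_time))),
    class = "tempo_scores"
  )
}

random_scores <- function(net1, net2, scale = 1) {
  m <- length(net1$nodes)
  n <- length(net2$nodes)
  make_scores(
    lapply(seq_len(net1$t), function(i) {
      matrix(runif(m * n) * scale, m, n)
    }),
    net1$nodes, net2$nodes
  )
}

igraph_snapshot <- function(net, i) {
  e <- net$snapshots[[i]]
  g <- igraph::make_empty_graph(n = 0, directed = FALSE)
  g <- igraph::add_vertices(g, length(net$nodes), name = net$nodes)
  if (nrow(e) > 0L) {
    g <- igraph::add_edges(
      g, rbind(net$nodes[e[, 1L]], net$nodes[e[, 2L]])
    )
  }
  g
}

# component count of the subgraph induced by `nodes`, via igraph
naive_ncc <- function(net, i, nodes) {
  g <- igraph_snapshot(net, i)
  igraph::count_components(igraph::induced_subgraph(g, nodes))
}

# connectivity-penalized alignment score from first principles
naive_alignment_score <- function(net1, net2, scores, psi, delta) {
  total <- 0
  for (i in seq_len(net1$t)) {
    sim <- 0
    for (u in psi$query) {
      sim <- sim + scores$per_time[[i]][u, psi$psi[[u]]]
    }
    comp <- naive_ncc(net2, i, unname(psi$psi))
    total <- total + sim - delta * (comp - 1)
  }
  total
}

naive_recovered <- function(psi, truth) {
  hits <- 0L
  for (u in psi$query) {
    if (identical(unname(psi$psi[[u]]), unname(truth[[u]]))) hits <- hits + 1L
  }
  100 * hits / length(psi$query)
}

naive_conserved <- function(net1, net2, psi, i) {
  e1 <- net1$snapshots[[i]]
  g2 <- igraph_snapshot(net2, i)
  cnt <- 0L
  if (nrow(e1) > 0L) {
    for (r in seq_len(nrow(e1))) {
      a <- psi$psi[[net1$nodes[e1[r, 1L]]]]
      b <- psi$psi[[net1$nodes[e1[r, 2L]]]]
      if (igraph::are_adjacent(g2, a, b)) cnt <- cnt + 1L
    }
  }
  cnt
}

naive_ics <- function(net1, net2, psi) {
  total <- 0
  for (i in seq_len(net1$t)) {
    g2 <- igraph::induced_subgraph(igraph_snapshot(net2, i),
                                   unname(psi$psi))
    denom <- igraph::ecount(g2)
    if (denom > 0L) {
      total <- total + naive_conserved(net1, net2, psi, i) / denom
    }
  }
  total
}

naive_ec <- function(net1, net2, psi) {
  total <- 0
  for (i in seq_len(net1$t)) {
    denom <- nrow(net1$snapshots[[i]])
    if (denom > 0L) {
      total <- total + naive_conserved(net1, net2, psi, i) / denom
    }
  }
  total
}

# exhaustive maximum-weight injective assignment of rows to columns
brute_force_matching <- function(W) {
  m <- nrow(W)
  n <- ncol(W)
  best <- -Inf
  rec <- function(row, used, acc) {
    if (row > m) {
      if (acc > best) best <<- acc
      return(invisible(NULL))
    }
    for (col in seq_len(n)) {
      if (!used[col]) {
        used[col] <- TRUE
        rec(row + 1L, used, acc + W[row, col])
        used[col] <- FALSE
      }
    }
  }
  rec(1L, logical(n), 0)
  best
}

all_permutations <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_permutations(v[-i])) out <- c(out, list(c(v[i], p)))
  }
  out
}

# exhaustive best swap set of size <= k (score via the naive scorer)
brute_force_swapsets <- function(net1, net2, scores, psi0, k, delta) {
  best <- naive_alignment_score(net1, net2, scores, psi0, delta)
  image <- psi0$image
  gap <- psi0$gap
  for (r in seq_len(min(k, length(image), length(gap)))) {
    us_sets <- combn(image, r, simplify = FALSE)
    vs_sets <- combn(gap, r, simplify = FALSE)
    for (us in us_sets) {
      for (vs in vs_sets) {
        for (vp in all_permutations(vs)) {
          psi <- psi0
          for (j in seq_len(r)) psi <- apply_swap(psi, us[j], vp[j])
          sc <- naive_alignment_score(net1, net2, scores, psi, delta)
          if (sc > best) best <- sc
        }
      }
    }
  }
  best
}

# exhaustive best single swap (u fixed), via the naive scorer
brute_force_single_swap <- function(net1, net2, scores, psi0, u, delta) {
  best <- -Inf
  for (v in psi0$gap) {
    sc <- naive_alignment_score(net1, net2, scores,
                                apply_swap(psi0, u, v), delta)
    if (sc > best) best <- sc
  }
  best
}

# identity-ish random node_map fixture
random_node_map <- function(query_nodes, target_nodes) {
  node_map(setNames(sample(target_nodes, length(query_nodes)), query_nodes),
           target_nodes)
}
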