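#' Parameters of the co-evolving network simulator
#'
#' Bundles and validates the simulator's knobs. Defaults mirror the
#' benchmark conditions the method was designed around: a scale-free
#' target with mean degree 4, a 50-node connected planted query,
#' log-normal homology with location `mu = 2` and scale `sigma = 0.25`
#' (planted pairs drawn at location `2 * mu`), and per-category edge
#' turnover with cold rate `epsilon_c <= epsilon`.
#'
#' @param n_target Target network node count.
#' @param mean_degree Target mean node degree (attachment count is
#'   `mean_degree / 2`, so it must be a positive even number). Default 4.
#' @param q_size Planted query node count. Default 50.
#' @param t Number of time points. Default 5.
#' @param epsilon Overall temporal edge-turnover rate in `[0, 1]`.
#' @param epsilon_c Cold (planted-region) turnover rate,
#'   `0 <= epsilon_c <= epsilon`.
#' @param mu,sigma Log-normal location and scale of homology scores.
#' @param seed Master RNG seed (integer); named sub-streams for the
#'   target, the planting, each evolution step and the homology draw are
#'   derived from it so each component is individually reproducible.
#' @return A validated list of class `synthetic_params`.
#' @export
synthetic_params <- function(n_target = 250L, mean_degree = 4, q_size = 50L,
                             t = 5L, epsilon = 0.05, epsilon_c = 0.05,
                             mu = 2, sigma = 0.25, seed = NULL) {
  if (epsilon_c < 0 || epsilon < epsilon_c || epsilon > 1) {
    stop("need 0 <= epsilon_c <= epsilon <= 1")
  }
  if (q_size > n_target) stop("q_size cannot exceed n_target")
  if (t < 1L) stop("t must be at least 1")
  if (mu <= 0 || sigma <= 0) stop("mu and sigma must be positive")
  if (mean_degree <= 0 || mean_degree %% 2 != 0) {
    stop("mean_degree must be a positive even number ",
         "(attachment count = mean_degree / 2)")
  }
  structure(
    list(n_target = as.integer(n_target), mean_degree = mean_degree,
         q_size = as.integer(q_size), t = as.integer(t), epsilon = epsilon,
         epsilon_c = epsilon_c, mu = mu, sigma = sigma, seed = seed),
    class = "synthetic_params"
  )
}

# run code under a derived sub-stream seed, restoring the caller's RNG state;
# NULL master seed leaves the ambient RNG stream in charge
with_substream <- function(seed, name, code) {
  if (is.null(seed)) return(force(code))
  derived <- derive_seed(seed, name)
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(derived)
  force(code)
}

derive_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)) * 131)
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483587)
}

#' Generate the scale-free target snapshot at time 1
#'
#' Barabási–Albert preferential attachment with `mean_degree / 2` edges
#' added per node, giving a connected, scale-free graph whose mean degree
#' approaches `mean_degree` as n grows (with attachment count a, the
#' construction yields `a * (n - a) + choose(a, 2)` edges; for a = 2 that
#' is `2n - 3`).
#'
#' @param n Node count (`n >= mean_degree`).
#' @param mean_degree Target mean degree (positive even number).
#' @param seed Optional seed for this draw.
#' @return A [net_snapshot()] with zero-padded labels `v0001, ...`.
#' @export
generate_target_t0 <- function(n, mean_degree = 4, seed = NULL) {
  attach_m <- mean_degree / 2
  if (attach_m < 1 || attach_m %% 1 != 0) {
    stop("mean_degree must be a positive even number")
  }
  if (n < mean_degree) stop("need n >= mean_degree")
  g <- with_substream(seed, "target-t0", {
    igraph::sample_pa(n, m = attach_m, directed = FALSE,
                      algorithm = "psumtree")
  })
  labels <- node_labels(n)
  el <- igraph::as_edgelist(g, names = FALSE)
  net_snapshot(labels, cbind(labels[el[, 1L]], labels[el[, 2L]]))
}

node_labels <- function(n) {
  sprintf(paste0("v%0", nchar(as.character(n)), "d"), seq_len(n))
}

#' Plant a connected query inside the target
#'
#' Draws a connected induced subnetwork of `q_size` nodes by random
#' frontier growth (start at a uniform node; repeatedly absorb a uniform
#' neighbour of the current set). Its nodes and edges are marked *cold*;
#' everything else in the target is *hot*. Query nodes keep their origin
#' labels, so the planted ground-truth mapping is label identity.
#'
#' @param target_t0 The target snapshot ([net_snapshot()]); must be
#'   connected when `q_size > 1`.
#' @param q_size Query size.
#' @param seed Optional seed.
#' @return List with `query_t0` (induced [net_snapshot()]), `cold_nodes`,
#'   `cold_edges` (two-column matrix), `truth` (named character,
#'   query -> target).
#' @export
plant_query <- function(target_t0, q_size, seed = NULL) {
  stopifnot(inherits(target_t0, "net_snapshot"))
  n <- length(target_t0$nodes)
  if (q_size < 1L || q_size > n) stop("q_size out of range")
  e <- canonical_edges(target_t0$edges, target_t0$nodes)
  adj <- adjacency_from_edges(n, e)
  if (q_size > 1L &&
      cpp_count_components_subset(adj, seq_len(n)) != 1L) {
    stop("target snapshot must be connected to plant a connected query")
  }
  sel <- with_substream(seed, "query-plant", {
    start <- sample.int(n, 1L)
    members <- logical(n)
    members[start] <- TRUE
    chosen <- start
    while (length(chosen) < q_size) {
      frontier <- unique(unlist(adj[chosen], use.names = FALSE))
      frontier <- frontier[!members[frontier]]
      nxt <- frontier[sample.int(length(frontier), 1L)]
      members[nxt] <- TRUE
      chosen <- c(chosen, nxt)
    }
    sort(chosen)
  })
  cold_nodes <- target_t0$nodes[sel]
  query_t0 <- induced_subnetwork(target_t0, cold_nodes)
  list(
    query_t0 = query_t0,
    cold_nodes = cold_nodes,
    cold_edges = query_t0$edges,
    truth = stats::setNames(cold_nodes, cold_nodes)
  )
}

#' Hot-edge turnover rate
#'
#' Given the overall temporal rate, the cold rate and the realized cold
#' edge fraction gamma, the hot edges must turn over at
#' \deqn{\varepsilon^h = (\varepsilon - \varepsilon^c \gamma)/(1-\gamma)}
#' so that the expected overall turnover equals \eqn{\varepsilon}. Values
#' outside `[0, 1]` mean the requested combination is infeasible and
#' raise an error.
#'
#' @param epsilon Overall rate, `epsilon_c <= epsilon <= 1`.
#' @param epsilon_c Cold rate.
#' @param gamma Cold-edge fraction in `[0, 1)`.
#' @return The hot rate, a number in `[0, 1]`.
#' @export
hot_rate <- function(epsilon, epsilon_c, gamma) {
  if (epsilon_c < 0 || epsilon < epsilon_c || epsilon > 1) {
    stop("need 0 <= epsilon_c <= epsilon <= 1")
  }
  if (gamma < 0 || gamma >= 1) {
    stop("gamma must lie in [0, 1): with gamma = 1 there are no hot edges")
  }
  eh <- (epsilon - epsilon_c * gamma) / (1 - gamma)
  if (eh < 0 || eh > 1) {
    stop("infeasible hot rate ", signif(eh, 4), " = (", epsilon, " - ",
         epsilon_c, " * ", signif(gamma, 4), ") / (1 - ", signif(gamma, 4),
         "); lower epsilon or raise epsilon_c/gamma")
  }
  eh
}

#' Evolve a snapshot by one time step
#'
#' Each cold edge is removed with probability `eps_c` and replaced by a
#' new edge between two random cold nodes; each hot edge is removed with
#' probability `eps_h` and replaced by a new edge between two random
#' nodes of which at least one is hot. Replacements are resampled to
#' avoid self-loops and duplicates of currently present edges, inherit
#' the category of the edge they replace, and keep the edge count
#' constant (if no admissible slot is found after many tries, the
#' replacement is skipped with a warning).
#'
#' @param G A [net_snapshot()] over the full node set.
#' @param cold_nodes Character vector of cold nodes; all other nodes are
#'   hot.
#' @param cold_edges Two-column character matrix flagging which edges of
#'   `G` are cold; all other edges are hot.
#' @param eps_c,eps_h Removal probabilities in `[0, 1]`.
#' @param seed Optional seed.
#' @return A [net_snapshot()] with attribute `cold_edges` (the updated
#'   cold-edge matrix).
#' @export
evolve_snapshot <- function(G, cold_nodes, cold_edges, eps_c, eps_h,
                            seed = NULL) {
  stopifnot(inherits(G, "net_snapshot"))
  if (eps_c < 0 || eps_c > 1 || eps_h < 0 || eps_h > 1) {
    stop("turnover rates must lie in [0, 1]")
  }
  nodes <- G$nodes
  n <- length(nodes)
  cold_idx <- match(cold_nodes, nodes)
  if (anyNA(cold_idx)) stop("cold node(s) missing from the snapshot")
  is_cold_node <- logical(n)
  is_cold_node[cold_idx] <- TRUE
  hot_idx <- which(!is_cold_node)

  e <- canonical_edges(G$edges, nodes)
  ck <- edge_keys(canonical_edges(as_edge_chr(cold_edges), nodes))
  keys <- edge_keys(e)
  is_cold_edge <- keys %in% ck
  res <- with_substream(seed, "evolve", {
    present <- new.env(parent = emptyenv(), size = length(keys) * 2L)
    for (kk in keys) assign(kk, TRUE, envir = present)
    rates <- ifelse(is_cold_edge, eps_c, eps_h)
    removed <- stats::runif(length(keys)) < rates
    out_u <- e[, 1L]
    out_v <- e[, 2L]
    out_cold <- is_cold_edge
    keep_mask <- rep(TRUE, length(keys))
    for (idx in which(removed)) {
      rm(list = keys[idx], envir = present)
      slot <- sample_replacement(
        cold = is_cold_edge[idx], cold_idx = cold_idx, hot_idx = hot_idx,
        n = n, present = present
      )
      if (is.null(slot)) {
        warning("no admissible replacement slot for a removed ",
                if (is_cold_edge[idx]) "cold" else "hot",
                " edge; edge count drops by one this step")
        keep_mask[idx] <- FALSE
      } else {
        out_u[idx] <- slot[1L]
        out_v[idx] <- slot[2L]
        assign(paste(slot[1L], slot[2L], sep = "|"), TRUE, envir = present)
      }
    }
    list(u = out_u[keep_mask], v = out_v[keep_mask],
         cold = out_cold[keep_mask])
  })
  new_edges <- cbind(nodes[res$u], nodes[res$v])
  out <- net_snapshot(nodes, new_edges)
  attr(out, "cold_edges") <- new_edges[res$cold, , drop = FALSE]
  out
}

# draw one admissible replacement edge (pair of node indices, min first);
# cold edges connect two cold nodes, hot edges need >= 1 hot endpoint
sample_replacement <- function(cold, cold_idx, hot_idx, n, present,
                               tries = 200L) {
  for (i in seq_len(tries)) {
    if (cold) {
      if (length(cold_idx) < 2L) return(NULL)
      pick <- cold_idx[sample.int(length(cold_idx), 2L)]
    } else {
      if (length(hot_idx) < 1L || n < 2L) return(NULL)
      a <- hot_idx[sample.int(length(hot_idx), 1L)]
      b <- sample.int(n, 1L)
      if (a == b) next
      pick <- c(a, b)
    }
    u <- min(pick)
    v <- max(pick)
    if (!exists(paste(u, v, sep = "|"), envir = present,
                inherits = FALSE)) {
      return(c(u, v))
    }
  }
  NULL
}

#' Synthetic homology scores
#'
#' Draws the homology matrix H once (it is shared by all time points):
#' the entry for a query node and its planted origin is log-normal with
#' location `2 * mu`, every other pair log-normal with location `mu`,
#' both with scale `sigma`. On the location-parameter reading, planted
#' pairs therefore concentrate near `exp(2 * mu)` and the background near
#' `exp(mu)`, biasing the aligner toward the planted region without
#' fixing it.
#'
#' @param truth Named character vector, query node -> origin target node.
#' @param V1,V2 Query and target node label vectors.
#' @param cold_nodes Cold target nodes (the planted region).
#' @param mu,sigma Log-normal location and scale.
#' @param seed Optional seed.
#' @return Numeric `|V1| x |V2|` matrix with dimnames.
#' @export
synth_homology <- function(truth, V1, V2, cold_nodes, mu = 2, sigma = 0.25,
                           seed = NULL) {
  if (mu <= 0 || sigma <= 0) stop("mu and sigma must be positive")
  V1 <- sort(as.character(V1))
  V2 <- sort(as.character(V2))
  meanlog <- matrix(mu, length(V1), length(V2), dimnames = list(V1, V2))
  planted_t <- unname(truth[V1])
  planted <- cbind(seq_along(V1), match(planted_t, V2))
  planted <- planted[!is.na(planted[, 2L]) &
                       planted_t %in% cold_nodes, , drop = FALSE]
  meanlog[planted] <- 2 * mu
  with_substream(seed, "homology", {
    H <- matrix(
      stats::rlnorm(length(meanlog), meanlog = as.vector(meanlog),
                    sdlog = sigma),
      length(V1), length(V2), dimnames = list(V1, V2)
    )
    H
  })
}

#' Generate a full co-evolving synthetic instance
#'
#' Composes the simulator: a scale-free target at time 1, a planted
#' connected query (cold region), independent evolution of target (cold
#' and hot edges at their own rates) and query (all edges cold, turning
#' over at `epsilon_c`, with replacements among query nodes and
#' connectivity re-established by bounded resampling — removals that
#' would disconnect the query are rejected), plus the log-normal homology
#' matrix.
#'
#' @param params A [synthetic_params()] object.
#' @return An object of class `tempo_synthetic`: `query` and `target`
#'   [temporal_network()]s, `cold_nodes`, `cold_edges` (initial marks),
#'   `gamma` (realized cold-edge ratio), `eps_h`, `truth`, `homology`,
#'   and `params`.
#' @export
generate_instance <- function(params) {
  stopifnot(inherits(params, "synthetic_params"))
  seed <- params$seed
  target_t0 <- generate_target_t0(params$n_target, params$mean_degree,
                                  seed = seed)
  plant <- plant_query(target_t0, params$q_size, seed = seed)
  n_edges <- nrow(canonical_edges(target_t0$edges, target_t0$nodes))
  gamma <- nrow(plant$cold_edges) / n_edges
  eps_h <- if (params$epsilon == params$epsilon_c) {
    params$epsilon # identical rates are feasible even at gamma = 1
  } else {
    hot_rate(params$epsilon, params$epsilon_c, gamma)
  }

  target_snaps <- vector("list", params$t)
  target_snaps[[1L]] <- target_t0
  cold_edges <- plant$cold_edges
  cur <- target_t0
  for (i in seq_len(params$t - 1L)) {
    cur <- evolve_snapshot(
      cur, plant$cold_nodes, cold_edges, params$epsilon_c, eps_h,
      seed = if (is.null(seed)) NULL else derive_seed(seed, paste0("tgt", i))
    )
    cold_edges <- attr(cur, "cold_edges")
    target_snaps[[i + 1L]] <- cur
  }

  query_snaps <- vector("list", params$t)
  query_snaps[[1L]] <- plant$query_t0
  curq <- plant$query_t0
  for (i in seq_len(params$t - 1L)) {
    curq <- evolve_query_snapshot(
      curq, params$epsilon_c,
      seed = if (is.null(seed)) NULL else derive_seed(seed, paste0("qry", i))
    )
    query_snaps[[i + 1L]] <- curq
  }

  H <- synth_homology(plant$truth, plant$query_t0$nodes, target_t0$nodes,
                      plant$cold_nodes, params$mu, params$sigma,
                      seed = seed)
  structure(
    list(
      query = temporal_network(lapply(query_snaps, `[[`, "edges"),
                               nodes = plant$query_t0$nodes),
      target = temporal_network(lapply(target_snaps, `[[`, "edges"),
                                nodes = target_t0$nodes),
      cold_nodes = plant$cold_nodes,
      cold_edges = plant$cold_edges,
      gamma = gamma,
      eps_h = eps_h,
      truth = plant$truth,
      homology = H,
      params = params
    ),
    class = "tempo_synthetic"
  )
}

# query evolution: every edge is cold (rate eps_c), replacements connect two
# random query nodes, and the snapshot must stay connected: replacement
# slots are resampled (bounded) and a removal with no connectivity-
# preserving replacement is rejected
evolve_query_snapshot <- function(G, eps_c, seed = NULL, tries = 100L) {
  nodes <- G$nodes
  n <- length(nodes)
  e <- canonical_edges(G$edges, nodes)
  with_substream(seed, "evolve-query", {
    work <- e
    removed <- stats::runif(nrow(work)) < eps_c
    for (idx in which(removed)) {
      others <- work[-idx, , drop = FALSE]
      keys <- edge_keys(others)
      for (ti in seq_len(tries)) {
        pick <- sort(sample.int(n, 2L))
        kk <- paste(pick[1L], pick[2L], sep = "|")
        if (kk %in% keys) next
        cand <- rbind(others, pick)
        adj <- adjacency_from_edges(n, cand)
        if (cpp_count_components_subset(adj, seq_len(n)) == 1L) {
          # replace in place so later removal indices stay valid; a
          # removal with no connectivity-preserving slot is rejected,
          # leaving the original edge untouched
          work[idx, ] <- pick
          break
        }
      }
    }
    net_snapshot(nodes, cbind(nodes[work[, 1L]], nodes[work[, 2L]]))
  })
}

#' @export
print.tempo_synthetic <- function(x, ...) {
  cat("Synthetic co-evolving instance\n")
  cat("  target: ", length(x$target$nodes), " nodes, t = ", x$target$t,
      "; query: ", length(x$query$nodes), " nodes\n", sep = "")
  cat("  epsilon = ", x$params$epsilon, ", epsilon_c = ",
      x$params$epsilon_c, ", realized gamma = ", signif(x$gamma, 4),
      ", eps_h = ", signif(x$eps_h, 4), "\n", sep = "")
  invisible(x)
}

#' Write a synthetic instance to a directory
#'
#' Writes `query.tsv` and `target.tsv` (long-format temporal TSV),
#' `homology.tsv`, `truth.tsv` and `params.yaml`.
#'
#' @param instance A [generate_instance()] result.
#' @param dir Output directory (created if missing).
#' @export
write_instance <- function(instance, dir) {
  stopifnot(inherits(instance, "tempo_synthetic"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_temporal_network(instance$query, file.path(dir, "query.tsv"))
  write_temporal_network(instance$target, file.path(dir, "target.tsv"))
  write_homology(instance$homology, file.path(dir, "homology.tsv"))
  writeLines(paste(names(instance$truth), instance$truth, sep = "\t"),
             file.path(dir, "truth.tsv"))
  p <- instance$params
  yaml::write_yaml(
    list(n_target = p$n_target, mean_degree = p$mean_degree,
         q_size = p$q_size, t = p$t, epsilon = p$epsilon,
         epsilon_c = p$epsilon_c, mu = p$mu, sigma = p$sigma,
         seed = p$seed, gamma = instance$gamma, eps_h = instance$eps_h),
    file.path(dir, "params.yaml")
  )
  invisible(dir)
}
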