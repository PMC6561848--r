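#' Swap one aligned target node for a gap node
#'
#' Produces the alignment \eqn{\psi'} with \eqn{\psi'(q) = v_{new}} for the
#' unique query node q with \eqn{\psi(q) = u_{old}}, unchanged elsewhere;
#' `u_old` joins the gap set and `v_new` leaves it. Swapping back restores
#' the original alignment, and swaps touching disjoint node pairs commute.
#'
#' @param psi A [node_map()].
#' @param u_old An aligned target node (in the image of `psi`).
#' @param v_new A gap node.
#' @return A new [node_map()].
#' @export
apply_swap <- function(psi, u_old, v_new) {
  stopifnot(inherits(psi, "node_map"))
  if (!(u_old %in% psi$image)) {
    stop("'", u_old, "' is not an aligned target node")
  }
  if (!(v_new %in% psi$gap)) {
    stop("'", v_new, "' is not a gap node")
  }
  p <- psi$psi
  p[p == u_old] <- v_new
  node_map(p, psi$target_nodes)
}

#' Best single swap for one aligned node
#'
#' Scans every gap node \eqn{v_i \in F} and returns the swap
#' \eqn{(u_i, v_i)} maximizing the full alignment score, together with the
#' achieved score. Ties resolve to the lexicographically smallest gap-node
#' label.
#'
#' @param net1,net2 Temporal networks.
#' @param scores A `tempo_scores` object.
#' @param psi A [node_map()].
#' @param u_i Aligned target node to swap out.
#' @param delta Edge-insertion penalty.
#' @return List with `swap` (character c(u, v)), `score`, and `psi` (the
#'   swapped alignment).
#' @export
best_single_swap <- function(net1, net2, scores, psi, u_i, delta) {
  stopifnot(inherits(psi, "node_map"))
  if (length(psi$gap) == 0L) {
    stop("no gap nodes: no swaps are possible")
  }
  if (!(u_i %in% psi$image)) stop("'", u_i, "' is not an aligned node")
  ctx <- score_context(net1, net2, scores, delta)
  best <- NULL
  best_score <- -Inf
  for (v in psi$gap) { # psi$gap is sorted, so ties keep the smallest label
    cand <- apply_swap(psi, u_i, v)
    sc <- breakdown_from_context(
      ctx, psi_target_index(cand, net1, net2, scores))$total
    if (sc > best_score) {
      best_score <- sc
      best <- list(swap = c(u = u_i, v = v), score = sc, psi = cand)
    }
  }
  best
}

#' Select up to k swaps by dynamic programming
#'
#' Phase II of the temporal aligner. Iteration 1 finds, for every aligned
#' node \eqn{u_i}, its best single swap. Iteration r (2..k) extends, for
#' every \eqn{u_i}, some size-(r-1) solution of another aligned node by
#' one swap \eqn{(u_i, v_i)}, subject to the feasibility conditions: the
#' incoming set must not already swap \eqn{u_i} nor use \eqn{v_i}, and
#' \eqn{v_i} must be a gap node of the *initial* alignment. The returned
#' swap set is the best solution encountered with the unswapped alignment
#' as the baseline, so the reported score never falls below the initial
#' score; when every extension of a branch is infeasible the branch
#' carries its smaller solution forward, and if no swap set of size up to
#' k improves on a smaller one, the smaller set is returned with a
#' message.
#'
#' @param net1,net2 Query and target [temporal_network()]s.
#' @param scores A [score_all_time_points()] result.
#' @param psi0 The initial alignment ([node_map()]).
#' @param k Maximum number of swaps, `1 <= k <= |F|`.
#' @param delta Edge-insertion penalty; a warning is raised if it is
#'   smaller than the largest per-time-point similarity (monotone
#'   improvement is then not guaranteed).
#' @return List with `swaps` (data frame u, v), `psi` (refined
#'   [node_map()]), `breakdown` (final [alignment_score()]),
#'   `initial_score`, `final_score`, `iteration_best` (running best score
#'   after each iteration), `iteration_raw` (per-iteration maxima of the
#'   size-r solutions), `truncated`.
#' @export
select_swaps <- function(net1, net2, scores, psi0, k, delta) {
  stopifnot(inherits(psi0, "node_map"),
            inherits(net1, "temporal_network"),
            inherits(net2, "temporal_network"),
            inherits(scores, "tempo_scores"))
  l <- length(psi0$gap)
  if (k < 1L || k > l) {
    stop("k must satisfy 1 <= k <= |F| = ", l)
  }
  per_time_max <- max(vapply(scores$per_time, max, numeric(1)))
  if (delta < per_time_max) {
    warning("delta (", signif(delta, 6), ") is below the largest ",
            "per-time-point similarity (", signif(per_time_max, 6),
            "): monotone score improvement is not guaranteed")
  }
  S_list <- aligned_sim_matrices(scores, net1, net2)
  psi_idx <- match(psi0$psi[net1$nodes], net2$nodes)
  gap_idx <- match(psi0$gap, net2$nodes)
  res <- cpp_select_swaps(
    n_target = length(net2$nodes),
    edges_by_time = net2$snapshots,
    sim_by_time = S_list,
    psi0 = as.integer(psi_idx),
    gap_nodes_num = as.numeric(gap_idx),
    delta = delta,
    k = as.integer(k)
  )
  swaps <- data.frame(
    u = net2$nodes[res$swaps[, 1L]],
    v = net2$nodes[res$swaps[, 2L]],
    stringsAsFactors = FALSE
  )
  psi <- node_map(stats::setNames(net2$nodes[res$psi], net1$nodes),
                  net2$nodes)
  if (isTRUE(res$truncated)) {
    message("returned ", nrow(swaps), " swap(s) out of the allowed ", k,
            ": no larger set improved the score")
  }
  list(
    swaps = swaps,
    psi = psi,
    breakdown = alignment_score(net1, net2, scores, psi, delta),
    initial_score = res$initial_score,
    final_score = res$final_score,
    iteration_best = res$iteration_best,
    iteration_raw = res$iteration_raw,
    truncated = res$truncated
  )
}

# per-time similarity matrices reordered to (net1 nodes) x (net2 nodes)
aligned_sim_matrices <- function(scores, net1, net2) {
  qi <- match(net1$nodes, scores$query_nodes)
  ti <- match(net2$nodes, scores$target_nodes)
  if (anyNA(qi) || anyNA(ti)) {
    stop("score set does not cover the networks' node sets")
  }
  lapply(scores$per_time, function(S) S[qi, ti, drop = FALSE])
}

#' Default number of swaps
#'
#' The number of swaps worth attempting is bounded by the number of
#' components that could be merged: the default is the maximum over time
#' points of \eqn{NCC(\Psi(V^1) \mid G^2_i) - 1}, floored at 1 and capped
#' at the number of gap nodes (0 when there are no gap nodes at all).
#'
#' @param net2 Target [temporal_network()].
#' @param psi0 Initial alignment ([node_map()]).
#' @return Integer swap budget.
#' @export
default_k <- function(net2, psi0) {
  stopifnot(inherits(net2, "temporal_network"), inherits(psi0, "node_map"))
  l <- length(psi0$gap)
  if (l == 0L) return(0L)
  adj <- network_adjacency(net2)
  members <- match(psi0$image, net2$nodes)
  worst <- max(vapply(adj, function(a) {
    cpp_count_components_subset(a, members)
  }, integer(1)))
  max(1L, min(worst - 1L, l))
}

#' Target-network gadget reducing Maximum Coverage to swap selection
#'
#' Builds the single-time-point instance that encodes a Maximum Coverage
#' problem as component minimization: one aligned node `a<j>` per universe
#' element, per set i an isolated aligned node `b<i>` and a gap node
#' `f<i>` adjacent to the `a` nodes of its elements, plus a clique over
#' all `f` nodes. The induced aligned subnetwork starts with zero edges —
#' n + m singleton components — and swapping gap nodes `f_i` in (for `b`
#' nodes) merges the covered elements into one component, so after
#' swapping k sets covering tau elements the component count is
#' \eqn{\beta = (m - k) + (n - \tau) + 1 = (m + n - k + 1) - \tau}.
#'
#' @param sets List of non-empty element sets (character or coercible).
#' @param k Swap budget of the coverage instance (recorded, not used in
#'   the construction).
#' @return List with `target` (a t = 1 [temporal_network()]), `aligned`
#'   (character vector), `gap` (character vector), `k`, `universe`.
#' @export
mcp_reduction <- function(sets, k) {
  if (length(sets) == 0L) stop("'sets' must be a non-empty collection")
  sets <- lapply(sets, function(s) unique(as.character(s)))
  if (any(lengths(sets) == 0L)) stop("all sets must be non-empty")
  universe <- sort(unique(unlist(sets)))
  m <- length(sets)
  n <- length(universe)
  a_nodes <- sprintf("a%02d", seq_len(n))
  b_nodes <- sprintf("b%02d", seq_len(m))
  f_nodes <- sprintf("f%02d", seq_len(m))
  names(a_nodes) <- universe
  edges <- NULL
  for (i in seq_len(m)) {
    edges <- rbind(edges, cbind(f_nodes[i], a_nodes[sets[[i]]]))
  }
  if (m > 1L) {
    pairs <- utils::combn(f_nodes, 2L)
    edges <- rbind(edges, t(pairs))
  }
  target <- temporal_network(list(edges), nodes = c(a_nodes, b_nodes))
  list(target = target, aligned = sort(c(a_nodes, b_nodes)),
       gap = f_nodes, k = k, universe = universe)
}
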