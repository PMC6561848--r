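#' Recovered region
#'
#' Percentage of query nodes aligned to the very target node they were
#' planted from: \eqn{100 \cdot |\{u : \psi(u) = truth(u)\}| / |V^1|}.
#'
#' @param psi A [node_map()] (or a fitted `tempo_alignment`, whose final
#'   mapping is used).
#' @param truth Named character vector, query node -> origin target node;
#'   must cover every query node.
#' @return A percentage in `[0, 100]`.
#' @export
recovered_region <- function(psi, truth) {
  psi <- as_node_map(psi)
  if (!all(psi$query %in% names(truth))) {
    stop("'truth' must cover every query node")
  }
  100 * mean(psi$psi == unname(truth[psi$query]))
}

as_node_map <- function(psi) {
  if (inherits(psi, "tempo_alignment")) return(psi$alignment)
  stopifnot(inherits(psi, "node_map"))
  psi
}

#' Induced conserved structure (ICS)
#'
#' Per time point, the fraction of query edges whose images are target
#' edges, with denominator the edge count of the subnetwork of the target
#' induced by the aligned image; the fractions are summed over time
#' points, so the total lies in `[0, t]`. A time point whose induced
#' subnetwork has no edges contributes 0.
#'
#' @param net1,net2 Query and target [temporal_network()]s.
#' @param psi A [node_map()] or fitted `tempo_alignment`.
#' @return The ICS sum over time points.
#' @export
ics <- function(net1, net2, psi) {
  ratios <- conserved_ratios(net1, net2, psi)
  sum(ifelse(ratios$induced > 0L, ratios$conserved / ratios$induced, 0))
}

#' Edge correctness (EC)
#'
#' Like [ics()], but the per-time denominator is the query's own edge
#' count \eqn{|E^1_i|}; time points with an edgeless query contribute 0.
#'
#' @inheritParams ics
#' @return The EC sum over time points.
#' @export
ec <- function(net1, net2, psi) {
  ratios <- conserved_ratios(net1, net2, psi)
  sum(ifelse(ratios$query > 0L, ratios$conserved / ratios$query, 0))
}

conserved_ratios <- function(net1, net2, psi) {
  psi <- as_node_map(psi)
  stopifnot(inherits(net1, "temporal_network"),
            inherits(net2, "temporal_network"))
  if (net1$t != net2$t) stop("time-point counts differ")
  # map query node index -> target node index
  map <- match(psi$psi[net1$nodes], net2$nodes)
  if (anyNA(map)) stop("psi maps outside the target network")
  img <- sort(map)
  conserved <- integer(net1$t)
  induced <- integer(net1$t)
  qcount <- integer(net1$t)
  in_img <- logical(length(net2$nodes))
  in_img[img] <- TRUE
  for (i in seq_len(net1$t)) {
    e1 <- net1$snapshots[[i]]
    e2 <- net2$snapshots[[i]]
    qcount[i] <- nrow(e1)
    if (nrow(e2) > 0L) {
      induced[i] <- sum(in_img[e2[, 1L]] & in_img[e2[, 2L]])
    }
    if (nrow(e1) > 0L && nrow(e2) > 0L) {
      a <- map[e1[, 1L]]
      b <- map[e1[, 2L]]
      k1 <- paste(pmin(a, b), pmax(a, b), sep = "|")
      conserved[i] <- sum(k1 %in% edge_keys(e2))
    }
  }
  list(conserved = conserved, induced = induced, query = qcount)
}

#' Alignment significance against random alignments
#'
#' Scores the given alignment (S*), then draws `n_random` uniform random
#' injective maps of the query into the target (a random node subset with
#' a random query-to-node assignment), scores each identically, and
#' returns \eqn{z = (S^* - S_\mu)/\sigma} with \eqn{S_\mu, \sigma} the
#' sample mean and standard deviation of the random scores.
#'
#' @param net1,net2 Temporal networks.
#' @param scores A `tempo_scores` object.
#' @param psi A [node_map()] or fitted `tempo_alignment`.
#' @param delta Edge-insertion penalty (held fixed across the null).
#' @param n_random Number of random alignments (default 1000).
#' @param seed Optional seed for the null draws (an RNG stream
#'   independent of the simulator's).
#' @return List with `zscore`, `score` (S*), `random_mean`, `random_sd`,
#'   `n_random`.
#' @export
zscore <- function(net1, net2, scores, psi, delta, n_random = 1000L,
                   seed = NULL) {
  psi <- as_node_map(psi)
  if (n_random < 2L) stop("n_random must be at least 2")
  m <- length(net1$nodes)
  n <- length(net2$nodes)
  if (n < m) stop("the target must be at least as large as the query")
  ctx <- score_context(net1, net2, scores, delta)
  s_star <- breakdown_from_context(
    ctx, psi_target_index(psi, net1, net2, scores))$total
  qidx <- match(net1$nodes, scores$query_nodes)
  null_scores <- with_substream(seed, "zscore-null", {
    vapply(seq_len(n_random), function(r) {
      tid <- sample.int(n, m) # random subset + random assignment in one draw
      tidx <- list(
        net2_idx = tid,
        score_q = qidx,
        score_t = match(net2$nodes[tid], scores$target_nodes)
      )
      breakdown_from_context(ctx, tidx)$total
    }, numeric(1))
  })
  mu <- mean(null_scores)
  sd0 <- stats::sd(null_scores)
  if (sd0 == 0) {
    stop("degenerate null: all ", n_random,
         " random alignment scores are identical")
  }
  list(zscore = (s_star - mu) / sd0, score = s_star, random_mean = mu,
       random_sd = sd0, n_random = as.integer(n_random))
}

#' Evaluate single-time-point alignments across all time points
#'
#' The comparison protocol for static aligners: each supplied alignment
#' (typically computed from one snapshot pair by an external method) is
#' imposed on all t time points, scored with the full temporal objective,
#' and the per-alignment totals plus their average are returned.
#'
#' @param psi_list List of [node_map()]s, one per time point (or any
#'   number of externally produced alignments).
#' @param net1,net2 Temporal networks.
#' @param scores A `tempo_scores` object.
#' @param delta Edge-insertion penalty.
#' @return List with `breakdowns` (one [alignment_score()] result per
#'   alignment), `totals`, and `average`.
#' @export
impose_static_alignment <- function(psi_list, net1, net2, scores, delta) {
  if (!is.list(psi_list) || length(psi_list) == 0L) {
    stop("'psi_list' must be a non-empty list of alignments")
  }
  breakdowns <- lapply(psi_list, function(p) {
    alignment_score(net1, net2, scores, as_node_map(p), delta)
  })
  totals <- vapply(breakdowns, `[[`, numeric(1), "total")
  list(breakdowns = breakdowns, totals = totals, average = mean(totals))
}
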