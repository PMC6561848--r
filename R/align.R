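#' Construct an alignment (node map)
#'
#' An alignment is an injective map \eqn{\psi} assigning every query node a
#' distinct target node; the target nodes left unassigned are the *gap
#' nodes* \eqn{F = V^2 - \Psi(V^1)}.
#'
#' @param psi Named character vector: names are query nodes, values target
#'   nodes. Must be injective.
#' @param target_nodes Character vector of all target nodes (superset of
#'   the values of `psi`).
#' @return An object of class `node_map` with fields `psi`, `query`,
#'   `target_nodes`, `image`, `gap`.
#' @export
node_map <- function(psi, target_nodes) {
  psi <- unlist(psi)
  if (is.null(names(psi)) || any(!nzchar(names(psi)))) {
    stop("'psi' must be a named character vector (query -> target)")
  }
  psi <- vapply(psi, as.character, "")
  if (anyDuplicated(names(psi))) stop("duplicate query nodes in 'psi'")
  if (anyDuplicated(psi)) {
    stop("'psi' is not injective: target node(s) used twice: ",
         paste(unique(psi[duplicated(psi)]), collapse = ", "))
  }
  target_nodes <- sort(unique(as.character(target_nodes)))
  if (!all(psi %in% target_nodes)) {
    stop("psi maps to node(s) outside the target node set: ",
         paste(setdiff(psi, target_nodes), collapse = ", "))
  }
  query <- sort(names(psi))
  psi <- psi[query]
  structure(
    list(psi = psi, query = query, target_nodes = target_nodes,
         image = unname(psi), gap = setdiff(target_nodes, psi)),
    class = "node_map"
  )
}

#' @export
print.node_map <- function(x, ...) {
  cat("Alignment: ", length(x$query), " query nodes -> ",
      length(x$target_nodes), " target nodes (", length(x$gap),
      " gap nodes)\n", sep = "")
  show <- utils::head(seq_along(x$query), 6L)
  cat(paste0("  ", x$query[show], " -> ", x$psi[show], collapse = "\n"),
      "\n")
  if (length(x$query) > 6L) cat("  ...\n")
  invisible(x)
}

#' Score an alignment of two temporal networks
#'
#' Evaluates, per time point i,
#' \deqn{score(G^1_i, G^2_i \mid \psi) = \sum_{u \in V^1} S_i(u, \psi(u))
#'   - \delta\,(NCC(\Psi(V^1) \mid G^2_i) - 1)}
#' where NCC counts connected components of the subnetwork of the target
#' induced by the aligned image (isolated aligned nodes each count as one
#' component), and \eqn{NCC - 1} is the minimum number of edge insertions
#' that would connect them, each charged \eqn{\delta}. The total is the
#' sum over all time points. Node pairs absent from the score set
#' contribute 0 similarity (with a warning).
#'
#' @param net1,net2 Query and target [temporal_network()]s, equal `t`.
#' @param scores A [score_all_time_points()] result (or any `tempo_scores`).
#' @param psi A [node_map()] over (`net1$nodes`, `net2$nodes`).
#' @param delta Non-negative edge-insertion penalty; see [default_delta()].
#' @return An object of class `score_breakdown`: per-time similarity, NCC
#'   and score vectors plus `total` and `delta`.
#' @export
alignment_score <- function(net1, net2, scores, psi, delta) {
  ctx <- score_context(net1, net2, scores, delta)
  tidx <- psi_target_index(psi, net1, net2, scores)
  breakdown_from_context(ctx, tidx)
}

# precomputed quantities shared by repeated scorings (e.g. the z-score null)
score_context <- function(net1, net2, scores, delta) {
  stopifnot(inherits(net1, "temporal_network"),
            inherits(net2, "temporal_network"),
            inherits(scores, "tempo_scores"))
  if (net1$t != net2$t) stop("time-point counts differ between networks")
  if (!is.numeric(delta) || length(delta) != 1L || !is.finite(delta) ||
      delta < 0) {
    stop("'delta' must be a single non-negative number")
  }
  if (scores$t != net1$t) {
    stop("score set has ", scores$t, " time points, networks have ", net1$t)
  }
  list(
    t = net1$t,
    delta = delta,
    S = scores$per_time,
    adj2 = network_adjacency(net2)
  )
}

# map a node_map to target-column indices aligned with the score matrices;
# returns integer vector over net1 nodes (NA -> missing, scored as 0)
psi_target_index <- function(psi, net1, net2, scores) {
  stopifnot(inherits(psi, "node_map"))
  if (!identical(psi$query, net1$nodes)) {
    missing_q <- setdiff(net1$nodes, psi$query)
    if (length(missing_q) > 0L) {
      stop("psi is not total on the query: missing ",
           paste(utils::head(missing_q, 5L), collapse = ", "))
    }
  }
  tq <- psi$psi[net1$nodes]
  tidx <- match(tq, scores$target_nodes)
  if (anyNA(tidx)) {
    warning("score entries missing for ", sum(is.na(tidx)),
            " aligned pair(s); treated as 0")
  }
  qidx <- match(net1$nodes, scores$query_nodes)
  if (anyNA(qidx)) {
    warning("score rows missing for ", sum(is.na(qidx)),
            " query node(s); treated as 0")
  }
  # target indices in net2 (for NCC), plus score-matrix indices
  list(
    net2_idx = match(tq, net2$nodes),
    score_q = qidx,
    score_t = tidx
  )
}

breakdown_from_context <- function(ctx, tidx) {
  tt <- ctx$t
  sim <- numeric(tt)
  nccs <- integer(tt)
  ok <- !is.na(tidx$score_q) & !is.na(tidx$score_t)
  members <- tidx$net2_idx
  if (anyNA(members)) stop("psi maps outside the target network")
  for (i in seq_len(tt)) {
    Si <- ctx$S[[i]]
    sim[i] <- sum(Si[cbind(tidx$score_q[ok], tidx$score_t[ok])])
    nccs[i] <- cpp_count_components_subset(ctx$adj2[[i]], members)
  }
  score <- sim - ctx$delta * (nccs - 1)
  structure(
    list(per_time_similarity = sim, per_time_ncc = nccs,
         per_time_score = score, total = sum(score), delta = ctx$delta,
         t = tt),
    class = "score_breakdown"
  )
}

#' @export
print.score_breakdown <- function(x, ...) {
  df <- data.frame(time = seq_len(x$t) - 1L,
                   similarity = signif(x$per_time_similarity, 6),
                   ncc = x$per_time_ncc,
                   score = signif(x$per_time_score, 6))
  print(df, row.names = FALSE)
  cat("total score: ", format(x$total, digits = 8), "  (delta = ",
      format(x$delta, digits = 6), ")\n", sep = "")
  invisible(x)
}

#' Default edge-insertion penalty
#'
#' Returns \eqn{\delta = \max_{u,v} S(u,v)} over the aggregate score
#' matrix. Because each \eqn{S_i} is non-negative and their sum is S, this
#' dominates every per-time-point similarity, which is the precondition
#' under which swap refinement can never decrease the alignment score.
#'
#' @param scores A `tempo_scores` object.
#' @return A single non-negative number.
#' @export
default_delta <- function(scores) {
  stopifnot(inherits(scores, "tempo_scores"))
  if (length(scores$aggregate) == 0L) {
    stop("empty score matrix: cannot derive a default delta")
  }
  max(scores$aggregate)
}

#' Initial alignment by maximum-weight bipartite matching
#'
#' Builds the complete weighted bipartite graph between query and target
#' nodes with the time-aggregated similarities S(u, v) as weights and
#' returns a maximum-total-weight injective assignment of every query
#' node. Node labels are processed in sorted order, so ties resolve
#' deterministically across runs and platforms.
#'
#' @param scores A [score_all_time_points()] result; requires
#'   `|V^1| <= |V^2|`.
#' @return A [node_map()].
#' @export
initial_alignment <- function(scores) {
  stopifnot(inherits(scores, "tempo_scores"))
  m <- length(scores$query_nodes)
  n <- length(scores$target_nodes)
  if (m > n) {
    stop("the query must be the smaller network: |V^1| = ", m,
         " > |V^2| = ", n)
  }
  W <- scores$aggregate
  # complete bipartite graph; +1 offset keeps weights positive so the
  # maximum-weight matching is also maximum-cardinality (covers all of V^1)
  el <- cbind(rep(seq_len(m), times = n), m + rep(seq_len(n), each = m))
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::V(g)$type <- c(rep(FALSE, m), rep(TRUE, n))
  w <- as.vector(W) + 1
  mm <- igraph::max_bipartite_match(g, weights = w,
                                    eps = 1e-10 * max(1, max(w)))
  match_idx <- mm$matching[seq_len(m)] - m
  if (anyNA(match_idx)) {
    # all weights are positive so this should not trigger; guard anyway
    free <- setdiff(seq_len(n), match_idx[!is.na(match_idx)])
    match_idx[is.na(match_idx)] <- free[seq_len(sum(is.na(match_idx)))]
  }
  psi <- stats::setNames(scores$target_nodes[match_idx], scores$query_nodes)
  node_map(psi, scores$target_nodes)
}

#' Write an alignment to disk
#'
#' One `query<TAB>target` line per aligned pair, preceded by comment
#' header lines recording any metadata passed in `meta`.
#'
#' @param psi A [node_map()].
#' @param path Output file path.
#' @param meta Optional named list written as `# name: value` header lines
#'   (e.g. delta, alpha, total score).
#' @export
write_alignment <- function(psi, path, meta = NULL) {
  stopifnot(inherits(psi, "node_map"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (!is.null(meta)) {
    for (nm in names(meta)) {
      writeLines(paste0("# ", nm, ": ", format(meta[[nm]], digits = 12)),
                 con)
    }
  }
  writeLines(paste(psi$query, psi$psi, sep = "\t"), con)
  invisible(path)
}

#' Read an alignment from disk
#'
#' @param path File written by [write_alignment()].
#' @param target_nodes Full target node set (needed to recover the gap
#'   set). If `NULL`, the image itself is used and the gap set is empty.
#' @return A [node_map()].
#' @export
read_alignment <- function(path, target_nodes = NULL) {
  lines <- readLines(path)
  body <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  fields <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(fields) != 2L)) {
    stop("malformed alignment file: expected query<TAB>target lines")
  }
  q <- vapply(fields, `[[`, "", 1L)
  tg <- vapply(fields, `[[`, "", 2L)
  if (is.null(target_nodes)) target_nodes <- tg
  node_map(stats::setNames(tg, q), target_nodes)
}
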