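#' Align two temporal networks
#'
#' Fits a single node mapping between a query and a target temporal
#' network that stays high-scoring across all time points. Phase I
#' propagates homology through each snapshot's topology
#' ([score_all_time_points()]) and takes the maximum-weight bipartite
#' matching of the time-aggregated similarities ([initial_alignment()]).
#' Phase II refines the mapping with the swap-selection dynamic program
#' ([select_swaps()]), trading similarity against the connected-component
#' penalty of the objective
#' \deqn{\sum_{i=1}^{t}\Big(\sum_{u \in V^1} S_i(u,\psi(u)) -
#'   \delta\,(NCC(\Psi(V^1)\mid G^2_i)-1)\Big).}
#' With the default penalty \eqn{\delta = \max_{u,v} S(u,v)} the refined
#' score never falls below the initial one.
#'
#' @param query,target [temporal_network()]s with the same number of time
#'   points; the query must not be larger than the target.
#' @param homology Non-negative homology matrix (query x target), e.g.
#'   from [read_homology()] or [synth_homology()].
#' @param alpha Mixing weight of the topological term in `[0, 1]`;
#'   default 0.7.
#' @param delta Edge-insertion penalty; `NULL` (default) uses
#'   [default_delta()].
#' @param k Swap budget; `NULL` (default) uses [default_k()]. `k = 0`
#'   skips Phase II.
#' @param tol,max_iter Convergence control for [propagate()].
#' @return An object of class `tempo_alignment` with components
#'   `alignment` (final [node_map()]), `initial` (Phase-I map), `swaps`,
#'   `score` / `score_initial` ([alignment_score()] breakdowns), `scores`
#'   (the `tempo_scores`), `delta`, `k`, `alpha`, `iteration_best` and
#'   `iteration_raw` (DP score trajectories).
#' @examples
#' params <- synthetic_params(n_target = 60, q_size = 12, t = 2,
#'                            epsilon = 0.2, epsilon_c = 0.05, seed = 7)
#' inst <- generate_instance(params)
#' fit <- tempo_align(inst$query, inst$target, inst$homology)
#' fit
#' recovered_region(fit, inst$truth)
#' @export
tempo_align <- function(query, target, homology, alpha = 0.7, delta = NULL,
                        k = NULL, tol = 1e-9, max_iter = 200L) {
  stopifnot(inherits(query, "temporal_network"),
            inherits(target, "temporal_network"))
  if (length(query$nodes) > length(target$nodes)) {
    stop("the query must be the smaller network")
  }
  scores <- score_all_time_points(query, target, homology, alpha = alpha,
                                  tol = tol, max_iter = max_iter)
  psi0 <- initial_alignment(scores)
  if (is.null(delta)) delta <- default_delta(scores)
  if (is.null(k)) k <- default_k(target, psi0)
  breakdown0 <- alignment_score(query, target, scores, psi0, delta)
  if (k >= 1L && length(psi0$gap) > 0L) {
    ph2 <- select_swaps(query, target, scores, psi0, k = k, delta = delta)
    alignment <- ph2$psi
    swaps <- ph2$swaps
    breakdown <- ph2$breakdown
    iteration_best <- ph2$iteration_best
    iteration_raw <- ph2$iteration_raw
  } else {
    alignment <- psi0
    swaps <- data.frame(u = character(0), v = character(0))
    breakdown <- breakdown0
    iteration_best <- numeric(0)
    iteration_raw <- numeric(0)
  }
  structure(
    list(alignment = alignment, initial = psi0, swaps = swaps,
         score = breakdown, score_initial = breakdown0, scores = scores,
         delta = delta, k = as.integer(k), alpha = alpha,
         iteration_best = iteration_best, iteration_raw = iteration_raw),
    class = "tempo_alignment"
  )
}

#' @export
print.tempo_alignment <- function(x, ...) {
  cat("Temporal network alignment\n")
  cat("  ", length(x$alignment$query), " query nodes -> ",
      length(x$alignment$target_nodes), " target nodes (",
      length(x$alignment$gap), " gap nodes)\n", sep = "")
  cat("  alpha = ", x$alpha, ", delta = ", signif(x$delta, 6), ", k = ",
      x$k, ", swaps applied = ", nrow(x$swaps), "\n", sep = "")
  cat("  score: initial ", format(x$score_initial$total, digits = 8),
      " -> final ", format(x$score$total, digits = 8), "\n", sep = "")
  invisible(x)
}

#' @export
summary.tempo_alignment <- function(object, ...) {
  out <- list(
    n_query = length(object$alignment$query),
    n_target = length(object$alignment$target_nodes),
    n_gap = length(object$alignment$gap),
    alpha = object$alpha, delta = object$delta, k = object$k,
    swaps = object$swaps,
    per_time = data.frame(
      time = seq_len(object$score$t) - 1L,
      similarity_initial = object$score_initial$per_time_similarity,
      ncc_initial = object$score_initial$per_time_ncc,
      similarity_final = object$score$per_time_similarity,
      ncc_final = object$score$per_time_ncc,
      score_final = object$score$per_time_score
    ),
    total_initial = object$score_initial$total,
    total_final = object$score$total,
    iteration_best = object$iteration_best
  )
  class(out) <- "summary.tempo_alignment"
  out
}

#' @export
print.summary.tempo_alignment <- function(x, ...) {
  cat("Temporal network alignment: ", x$n_query, " query nodes, ",
      x$n_target, " target nodes, ", x$n_gap, " gap nodes\n", sep = "")
  cat("alpha = ", x$alpha, ", delta = ", signif(x$delta, 6), ", k = ",
      x$k, "\n", sep = "")
  cat("\nPer-time-point breakdown:\n")
  print(x$per_time, row.names = FALSE, digits = 6)
  cat("\ntotal score: initial ", format(x$total_initial, digits = 8),
      " -> final ", format(x$total_final, digits = 8), "\n", sep = "")
  if (nrow(x$swaps) > 0L) {
    cat("\nSwaps applied (aligned node -> gap node):\n")
    print(x$swaps, row.names = FALSE)
  }
  if (length(x$iteration_best) > 0L) {
    cat("\nDP running best score by iteration:\n  ",
        paste(format(x$iteration_best, digits = 8), collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Plot an alignment fit
#'
#' Two base-graphics panels: the per-time-point component count of the
#' aligned region before and after refinement, and the running best DP
#' score across swap iterations (with the initial score as baseline).
#'
#' @param x A `tempo_alignment`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.tempo_alignment <- function(x, ...) {
  old <- graphics::par(mfrow = c(1L, 2L))
  on.exit(graphics::par(old))
  tt <- seq_len(x$score$t) - 1L
  ylim <- range(c(x$score_initial$per_time_ncc, x$score$per_time_ncc, 1L))
  graphics::plot(tt, x$score_initial$per_time_ncc, type = "b", pch = 1,
                 xlab = "time point", ylab = "NCC of aligned region",
                 ylim = ylim, main = "Component count", ...)
  graphics::lines(tt, x$score$per_time_ncc, type = "b", pch = 16)
  graphics::legend("topright", legend = c("initial", "refined"),
                   pch = c(1, 16), bty = "n")
  if (length(x$iteration_best) > 0L) {
    iters <- seq_along(x$iteration_best)
    graphics::plot(c(0L, iters), c(x$score_initial$total, x$iteration_best),
                   type = "s", xlab = "swap iteration",
                   ylab = "best alignment score", main = "DP refinement",
                   ...)
  } else {
    graphics::plot.new()
    graphics::title(main = "No swap refinement performed")
  }
  invisible(x)
}
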