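#' Topological support operator for one time point
#'
#' Builds the pair-similarity operator \eqn{A_i} of the IsoRank-style
#' propagation for a query snapshot and a target snapshot. Conceptually,
#' \deqn{A_i[(u,v),(w,z)] = \frac{1}{|N(w|G^1_i)|\,|N(z|G^2_i)|}}
#' when \eqn{w \in N(u|G^1_i)} and \eqn{z \in N(v|G^2_i)}, and 0 otherwise:
#' the pair (w, z) distributes its similarity evenly over its neighbouring
#' pairs, which makes \eqn{A_i} column stochastic on every column (w, z)
#' with both degrees positive. Columns of isolated nodes are identically
#' zero (no teleportation). The operator is stored matrix-free as the pair
#' of sparse adjacency matrices plus inverse degrees; its linear action on
#' a query-by-target score matrix X is
#' \deqn{A_i X = M_1 (X \oslash d_1 d_2^\top) M_2}
#' with \eqn{M_1, M_2} the adjacency matrices and \eqn{\oslash} elementwise
#' division (zero where a degree is zero).
#'
#' @param G1_i,G2_i Query and target snapshots ([net_snapshot()]).
#' @return An object of class `topology_operator`.
#' @seealso [apply_operator()], [as.matrix.topology_operator()]
#' @export
topology_support <- function(G1_i, G2_i) {
  stopifnot(inherits(G1_i, "net_snapshot"), inherits(G2_i, "net_snapshot"))
  A1 <- snapshot_sparse_adjacency(G1_i)
  A2 <- snapshot_sparse_adjacency(G2_i)
  d1 <- Matrix::rowSums(A1)
  d2 <- Matrix::rowSums(A2)
  inv1 <- ifelse(d1 > 0, 1 / d1, 0)
  inv2 <- ifelse(d2 > 0, 1 / d2, 0)
  structure(
    list(adj1 = A1, adj2 = A2, invdeg1 = inv1, invdeg2 = inv2,
         query_nodes = G1_i$nodes, target_nodes = G2_i$nodes),
    class = "topology_operator"
  )
}

snapshot_sparse_adjacency <- function(G) {
  n <- length(G$nodes)
  e <- canonical_edges(G$edges, G$nodes)
  Matrix::sparseMatrix(
    i = c(e[, 1L], e[, 2L]), j = c(e[, 2L], e[, 1L]), x = 1,
    dims = c(n, n)
  )
}

#' Apply a topology operator to a pair-score matrix
#'
#' Computes the linear action \eqn{X \mapsto A_i X} on a query-by-target
#' score matrix.
#'
#' @param op A [topology_support()] operator.
#' @param X Numeric matrix, `length(op$query_nodes)` rows by
#'   `length(op$target_nodes)` columns.
#' @return A numeric matrix of the same shape.
#' @export
apply_operator <- function(op, X) {
  stopifnot(inherits(op, "topology_operator"))
  X <- as.matrix(X)
  if (nrow(X) != length(op$query_nodes) ||
      ncol(X) != length(op$target_nodes)) {
    stop("score matrix shape does not match the operator's node sets")
  }
  Y <- X * tcrossprod(op$invdeg1, op$invdeg2)
  as.matrix(op$adj1 %*% Y %*% op$adj2)
}

#' Materialize a topology operator as a dense pair matrix
#'
#' Expands the matrix-free operator into the full
#' \eqn{(mn) \times (mn)} matrix over node pairs, with pair \eqn{(u, v)}
#' mapped to index \eqn{(v-1)m + u} (query index fastest). Intended for
#' small instances: verification, teaching, and the direct linear-system
#' solution of the propagation fixed point.
#'
#' @param x A `topology_operator`.
#' @param ... Unused.
#' @return A dense `(mn) x (mn)` matrix.
#' @export
as.matrix.topology_operator <- function(x, ...) {
  m <- length(x$query_nodes)
  n <- length(x$target_nodes)
  E <- diag(m * n)
  out <- matrix(0, m * n, m * n)
  for (p in seq_len(m * n)) {
    X <- matrix(E[, p], m, n)
    out[, p] <- as.vector(apply_operator(x, X))
  }
  out
}

#' Propagate homology through topology to a similarity fixed point
#'
#' Iterates \eqn{H^r = \alpha A_i H^{r-1} + (1-\alpha) H^0} from
#' \eqn{H^0}, the input homology matrix scaled to sum to one, until the
#' max-norm change drops to `tol` or `max_iter` iterations are reached.
#' With `alpha = 0` the topology contributes nothing and \eqn{H^0} is
#' returned after one iteration, exactly. Because \eqn{A_i} is column
#' stochastic on its support, the iteration is a contraction for
#' `alpha < 1` and converges to the solution of
#' \eqn{(I - \alpha A_i)\,s = (1-\alpha)\,h^0}.
#'
#' @param op A [topology_support()] operator.
#' @param H Non-negative homology matrix (query x target).
#' @param alpha Mixing parameter in `[0, 1]`: weight of the topological
#'   term. Default 0.7.
#' @param tol Max-norm convergence tolerance (on the normalized scale).
#' @param max_iter Iteration cap; hitting it raises a warning, not an
#'   error, and the result carries `converged = FALSE`.
#' @param normalize If `TRUE` (default), scale `H` to sum to one before
#'   iterating, which makes `tol` scale-free; the applied factor is
#'   recorded in the `"scale"` attribute.
#' @return The converged score matrix \eqn{S_i} with attributes
#'   `iterations`, `converged`, `residual` and `scale`.
#' @export
propagate <- function(op, H, alpha = 0.7, tol = 1e-9, max_iter = 200L,
                      normalize = TRUE) {
  stopifnot(inherits(op, "topology_operator"))
  H <- as.matrix(H)
  if (any(!is.finite(H)) || any(H < 0)) {
    stop("homology matrix must be finite and non-negative")
  }
  if (alpha < 0 || alpha > 1) stop("'alpha' must lie in [0, 1]")
  if (tol <= 0) stop("'tol' must be positive")
  scale <- 1
  if (normalize) {
    s <- sum(H)
    if (s > 0) {
      scale <- s
      H <- H / s
    }
  }
  cur <- H
  it <- 0L
  res <- Inf
  converged <- FALSE
  if (alpha == 0) {
    it <- 1L
    res <- 0
    converged <- TRUE
  } else {
    while (it < max_iter) {
      nxt <- alpha * apply_operator(op, cur) + (1 - alpha) * H
      it <- it + 1L
      res <- max(abs(nxt - cur))
      cur <- nxt
      if (res <= tol) {
        converged <- TRUE
        break
      }
    }
    if (!converged) {
      warning("propagation did not reach tol = ", tol, " after ",
              max_iter, " iterations (residual ", signif(res, 3), ")")
    }
  }
  structure(cur, iterations = it, converged = converged, residual = res,
            scale = scale)
}

#' Per-time-point similarities and their aggregate over time
#'
#' Runs [topology_support()] + [propagate()] for every time point of two
#' temporal networks and aggregates: \eqn{S(u,v) = \sum_i S_i(u,v)}. The
#' homology matrix is shared by all time points (homology does not change
#' over time; topology does) and is normalized once, so all per-time
#' scores live on one common scale.
#'
#' @param net1,net2 Query and target [temporal_network()]s with equal `t`.
#' @param H Homology matrix. Either dimnames-carrying (rows named by query
#'   nodes, columns by target nodes; reordered by name) or unnamed with
#'   dimensions matching the node counts in sorted label order.
#' @param alpha,tol,max_iter Passed to [propagate()].
#' @return An object of class `tempo_scores` with fields `query_nodes`,
#'   `target_nodes`, `H` (input scale), `scale` (normalization factor),
#'   `alpha`, `per_time` (list of t matrices), `aggregate`, `iterations`,
#'   `converged`.
#' @export
score_all_time_points <- function(net1, net2, H, alpha = 0.7, tol = 1e-9,
                                  max_iter = 200L) {
  stopifnot(inherits(net1, "temporal_network"),
            inherits(net2, "temporal_network"))
  if (net1$t != net2$t) {
    stop("time-point counts differ: query has ", net1$t, ", target has ",
         net2$t)
  }
  H <- conform_homology(H, net1$nodes, net2$nodes)
  scale <- sum(H)
  h0 <- if (scale > 0) H / scale else H
  if (scale == 0) scale <- 1
  per_time <- vector("list", net1$t)
  iters <- integer(net1$t)
  conv <- logical(net1$t)
  for (i in seq_len(net1$t)) {
    op <- topology_support(get_snapshot(net1, i), get_snapshot(net2, i))
    Si <- propagate(op, h0, alpha = alpha, tol = tol, max_iter = max_iter,
                    normalize = FALSE)
    iters[i] <- attr(Si, "iterations")
    conv[i] <- attr(Si, "converged")
    Si <- matrix(as.numeric(Si), nrow(H), ncol(H),
                 dimnames = dimnames(H))
    per_time[[i]] <- Si
  }
  aggregate <- Reduce(`+`, per_time)
  structure(
    list(query_nodes = net1$nodes, target_nodes = net2$nodes, H = H,
         scale = scale, alpha = alpha, tol = tol, per_time = per_time,
         aggregate = aggregate, t = net1$t, iterations = iters,
         converged = conv),
    class = "tempo_scores"
  )
}

conform_homology <- function(H, query_nodes, target_nodes) {
  H <- as.matrix(H)
  m <- length(query_nodes)
  n <- length(target_nodes)
  if (!is.null(rownames(H)) && !is.null(colnames(H))) {
    if (!all(query_nodes %in% rownames(H)) ||
        !all(target_nodes %in% colnames(H))) {
      stop("homology matrix dimnames do not cover the networks' node sets")
    }
    H <- H[query_nodes, target_nodes, drop = FALSE]
  } else if (nrow(H) != m || ncol(H) != n) {
    stop("unnamed homology matrix must be ", m, " x ", n)
  } else {
    dimnames(H) <- list(query_nodes, target_nodes)
  }
  if (any(!is.finite(H)) || any(H < 0)) {
    stop("homology matrix must be finite and non-negative")
  }
  H
}

#' @export
print.tempo_scores <- function(x, ...) {
  cat("Propagated similarity scores: ", length(x$query_nodes), " x ",
      length(x$target_nodes), " node pairs, t = ", x$t, "\n", sep = "")
  cat("  alpha = ", x$alpha, "; homology scale factor = ",
      signif(x$scale, 6), "\n", sep = "")
  cat("  iterations per time point: ", paste(x$iterations, collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Read a homology score table
#'
#' TSV with columns `query_node<TAB>target_node<TAB>score`; `#` comments
#' allowed. Absent pairs default to score 0, so the induced bipartite
#' similarity graph is complete.
#'
#' @param path TSV file path.
#' @param query_nodes,target_nodes Node universes defining the matrix
#'   shape. If `NULL`, the labels seen in the file are used.
#' @return Numeric matrix with query rows and target columns.
#' @export
read_homology <- function(path, query_nodes = NULL, target_nodes = NULL) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          comment.char = "#", stringsAsFactors = FALSE,
                          col.names = c("query", "target", "score"))
  if (is.null(query_nodes)) query_nodes <- sort(unique(df$query))
  if (is.null(target_nodes)) target_nodes <- sort(unique(df$target))
  H <- matrix(0, length(query_nodes), length(target_nodes),
              dimnames = list(query_nodes, target_nodes))
  qi <- match(df$query, query_nodes)
  ti <- match(df$target, target_nodes)
  if (anyNA(qi) || anyNA(ti)) {
    bad <- unique(c(df$query[is.na(qi)], df$target[is.na(ti)]))
    stop("homology table names unknown node(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  H[cbind(qi, ti)] <- df$score
  H
}

#' Write a homology score table
#'
#' Inverse of [read_homology()]: one `query<TAB>target<TAB>score` line per
#' non-zero entry, sorted by (query, target).
#'
#' @param H Numeric matrix with dimnames.
#' @param path Output path.
#' @export
write_homology <- function(H, path) {
  stopifnot(!is.null(rownames(H)), !is.null(colnames(H)))
  nz <- which(H != 0, arr.ind = TRUE)
  q <- rownames(H)[nz[, 1L]]
  tg <- colnames(H)[nz[, 2L]]
  o <- order(q, tg)
  writeLines(paste(q[o], tg[o], format(H[nz][o], digits = 12, trim = TRUE),
                   sep = "\t"), path)
  invisible(path)
}

#' Write per-time and aggregate similarity scores
#'
#' Emits one TSV per time point (`<prefix>_time<i>.tsv`) plus
#' `<prefix>_aggregate.tsv`, each with lines
#' `query<TAB>target<TAB>score` at 12 significant digits.
#'
#' @param scores A [score_all_time_points()] result.
#' @param prefix Output path prefix.
#' @return The written paths, invisibly.
#' @export
write_score_set <- function(scores, prefix) {
  stopifnot(inherits(scores, "tempo_scores"))
  write_one <- function(M, path) {
    grid <- expand.grid(q = scores$query_nodes, tg = scores$target_nodes,
                        stringsAsFactors = FALSE)
    o <- order(grid$q, grid$tg)
    vals <- as.vector(M)[o]
    writeLines(paste(grid$q[o], grid$tg[o],
                     format(vals, digits = 12, trim = TRUE, scientific = FALSE),
                     sep = "\t"), path)
    path
  }
  paths <- character(0)
  for (i in seq_len(scores$t)) {
    paths <- c(paths, write_one(scores$per_time[[i]],
                                paste0(prefix, "_time", i - 1L, ".tsv")))
  }
  paths <- c(paths, write_one(scores$aggregate,
                              paste0(prefix, "_aggregate.tsv")))
  invisible(paths)
}
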