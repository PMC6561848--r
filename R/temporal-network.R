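#' Construct a temporal network
#'
#' A temporal network is a sequence of undirected, simple, unweighted
#' snapshots \eqn{G_1, \dots, G_t} over one shared node set: only the edge
#' set changes between consecutive time points. Nodes that are isolated at
#' every time point are retained, because they still count as connected
#' components of induced subnetworks during alignment scoring.
#'
#' @param snapshots List of edge tables, one per time point in time order.
#'   Each element is a two-column character matrix (or data frame) of edge
#'   endpoints. Self-loops are rejected; duplicate edges (in either
#'   orientation) are collapsed.
#' @param nodes Optional character vector of node labels to include in the
#'   shared node set in addition to all edge endpoints (e.g. nodes isolated
#'   at every time point).
#' @return An object of class `temporal_network` with fields `nodes`
#'   (sorted character labels), `snapshots` (a list of integer edge
#'   matrices indexing into `nodes`, rows ordered with smaller index first)
#'   and `t` (number of time points).
#' @examples
#' net <- temporal_network(list(
#'   rbind(c("a", "b"), c("b", "c")),
#'   rbind(c("a", "c"))
#' ))
#' net$t
#' @export
temporal_network <- function(snapshots, nodes = NULL) {
  if (!is.list(snapshots) || length(snapshots) < 1L) {
    stop("'snapshots' must be a non-empty list of edge tables (t >= 1)")
  }
  snapshots <- lapply(snapshots, as_edge_chr)
  labels <- unique(c(
    nodes,
    unlist(lapply(snapshots, as.character), use.names = FALSE)
  ))
  labels <- sort(labels)
  if (length(labels) == 0L) {
    stop("temporal network has no nodes: supply edges or a node list")
  }
  idx_snaps <- lapply(snapshots, function(e) canonical_edges(e, labels))
  structure(
    list(nodes = labels, snapshots = idx_snaps, t = length(idx_snaps)),
    class = "temporal_network"
  )
}

# coerce an edge table to a 2-column character matrix, rejecting self-loops
as_edge_chr <- function(e) {
  if (is.null(e) || (is.matrix(e) && nrow(e) == 0L) ||
      (is.data.frame(e) && nrow(e) == 0L) || length(e) == 0L) {
    return(matrix(character(0), ncol = 2L))
  }
  if (is.data.frame(e)) e <- as.matrix(e)
  if (!is.matrix(e) || ncol(e) != 2L) {
    stop("an edge table must have exactly two columns (u, v)")
  }
  storage.mode(e) <- "character"
  if (any(e[, 1L] == e[, 2L])) {
    bad <- e[e[, 1L] == e[, 2L], 1L][1L]
    stop("self-loop on node '", bad, "' is not allowed")
  }
  e
}

# label edges -> unique integer edge matrix with row-wise min index first,
# rows sorted by (u, v); labels must cover all endpoints
canonical_edges <- function(edges_chr, labels) {
  if (nrow(edges_chr) == 0L) {
    m <- matrix(integer(0), ncol = 2L)
    colnames(m) <- c("u", "v")
    return(m)
  }
  i <- match(edges_chr[, 1L], labels)
  j <- match(edges_chr[, 2L], labels)
  if (anyNA(i) || anyNA(j)) {
    bad <- unique(c(edges_chr[, 1L][is.na(i)], edges_chr[, 2L][is.na(j)]))
    stop("unknown node label(s): ", paste(bad, collapse = ", "))
  }
  u <- pmin(i, j)
  v <- pmax(i, j)
  keep <- !duplicated(u * (length(labels) + 1) + v)
  u <- u[keep]
  v <- v[keep]
  o <- order(u, v)
  m <- cbind(u = u[o], v = v[o])
  m
}

#' @export
print.temporal_network <- function(x, ...) {
  ne <- vapply(x$snapshots, nrow, integer(1))
  cat("Temporal network: ", length(x$nodes), " nodes, ", x$t,
      " time point(s)\n", sep = "")
  cat("  edges per snapshot: ", paste(ne, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Extract one snapshot of a temporal network
#'
#' @param net A [temporal_network()].
#' @param i Time point index (1-based).
#' @return An object of class `net_snapshot`: a single static graph with
#'   fields `nodes` (character labels) and `edges` (two-column character
#'   matrix).
#' @export
get_snapshot <- function(net, i) {
  stopifnot(inherits(net, "temporal_network"))
  if (i < 1L || i > net$t) stop("time point index out of range")
  e <- net$snapshots[[i]]
  net_snapshot(net$nodes, cbind(net$nodes[e[, 1L]], net$nodes[e[, 2L]]))
}

#' Construct a single network snapshot
#'
#' @param nodes Character vector of node labels.
#' @param edges Two-column character matrix of undirected edges (may have
#'   zero rows). Endpoints must occur in `nodes`.
#' @return An object of class `net_snapshot`.
#' @export
net_snapshot <- function(nodes, edges = matrix(character(0), ncol = 2L)) {
  nodes <- sort(unique(as.character(nodes)))
  edges <- as_edge_chr(edges)
  idx <- canonical_edges(edges, nodes)
  structure(
    list(nodes = nodes, edges = cbind(nodes[idx[, 1L]], nodes[idx[, 2L]])),
    class = "net_snapshot"
  )
}

#' @export
print.net_snapshot <- function(x, ...) {
  cat("Network snapshot: ", length(x$nodes), " nodes, ", nrow(x$edges),
      " edges\n", sep = "")
  invisible(x)
}

#' Induced subnetwork of a node subset
#'
#' Returns the subnetwork consisting of `nodes` and every edge of `G` with
#' both endpoints in `nodes` (\eqn{\bar E = \{\bar V \times \bar V\} \cap E}).
#'
#' @param G A [net_snapshot()].
#' @param nodes Character vector, a subset of `G$nodes`.
#' @return A `net_snapshot` on `nodes`.
#' @export
induced_subnetwork <- function(G, nodes) {
  stopifnot(inherits(G, "net_snapshot"))
  nodes <- unique(as.character(nodes))
  unknown <- setdiff(nodes, G$nodes)
  if (length(unknown) > 0L) {
    stop("unknown node(s): ", paste(unknown, collapse = ", "))
  }
  keep <- G$edges[, 1L] %in% nodes & G$edges[, 2L] %in% nodes
  net_snapshot(nodes, G$edges[keep, , drop = FALSE])
}

#' Number of connected components
#'
#' Counts maximal connected components of a snapshot. Isolated nodes each
#' count as one component. This quantity, evaluated on the subnetwork of
#' the target induced by the aligned nodes, drives the edge-insertion
#' penalty of the alignment score.
#'
#' @param G A [net_snapshot()].
#' @return Integer component count.
#' @export
ncc <- function(G) {
  stopifnot(inherits(G, "net_snapshot"))
  n <- length(G$nodes)
  if (n == 0L) return(0L)
  e <- canonical_edges(G$edges, G$nodes)
  adj <- adjacency_from_edges(n, e)
  cpp_count_components_subset(adj, seq_len(n))
}

# adjacency list (list of integer vectors, 1-based) from an integer edge matrix
adjacency_from_edges <- function(n, edges) {
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(edges) > 0L) {
    ends <- c(edges[, 1L], edges[, 2L])
    nbrs <- c(edges[, 2L], edges[, 1L])
    o <- order(ends)
    adj[unique(ends[o])] <- split(nbrs[o], ends[o])
  }
  adj
}

# per-snapshot adjacency lists for a temporal network
network_adjacency <- function(net) {
  n <- length(net$nodes)
  lapply(net$snapshots, function(e) adjacency_from_edges(n, e))
}

# edge keys "i|j" (integer indices) for fast set membership
edge_keys <- function(edges) {
  if (nrow(edges) == 0L) return(character(0))
  paste(edges[, 1L], edges[, 2L], sep = "|")
}
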