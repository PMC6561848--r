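#' Read a temporal network from disk
#'
#' Two dialects are supported. The canonical `"long"` dialect is a single
#' TSV with columns `time<TAB>u<TAB>v`, `#`-prefixed comment lines, an
#' optional `#nodes: a,b,c` declaration adding (possibly isolated) nodes,
#' and an optional `#t: k` declaration fixing the number of time points
#' (needed for snapshots without any edge). The `"per-snapshot"` dialect
#' is a character vector of edge-list files (`u<TAB>v`), one per time
#' point, in time order. Without a `#t:` declaration, time indices in the
#' long format need not be 0-based or contiguous: they are densified to
#' `0..t-1` preserving their numeric order.
#'
#' @param path File path (long format) or vector of file paths
#'   (per-snapshot format).
#' @param dialect `"long"` or `"per-snapshot"`.
#' @return A [temporal_network()].
#' @export
read_temporal_network <- function(path, dialect = c("long", "per-snapshot")) {
  dialect <- match.arg(dialect)
  if (dialect == "per-snapshot") {
    snaps <- lapply(path, function(p) read_edge_list(p))
    return(temporal_network(snaps))
  }
  lines <- readLines(path)
  declared <- character(0)
  nd <- grepl("^#nodes:", lines)
  if (any(nd)) {
    declared <- unlist(strsplit(sub("^#nodes:\\s*", "", lines[nd]), ","))
    declared <- trimws(declared)
    declared <- declared[nzchar(declared)]
  }
  declared_t <- NA_integer_
  td <- grepl("^#t:", lines)
  if (any(td)) {
    declared_t <- as.integer(trimws(sub("^#t:\\s*", "", lines[td][1L])))
    if (is.na(declared_t) || declared_t < 1L) {
      stop("invalid #t: declaration in ", path)
    }
  }
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  body <- lines[keep]
  lineno <- which(keep)
  if (length(body) == 0L && length(declared) == 0L) {
    stop("empty temporal network file: ", path)
  }
  if (length(body) == 0L) {
    tt_n <- if (is.na(declared_t)) 1L else declared_t
    return(temporal_network(
      rep(list(matrix(character(0), ncol = 2L)), tt_n),
      nodes = declared
    ))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 3L)) {
    bad <- lineno[which(nf != 3L)[1L]]
    stop("malformed line ", bad, " in ", path,
         ": expected 3 tab-separated fields (time, u, v)")
  }
  tt <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 1L)))
  if (anyNA(tt)) {
    bad <- lineno[which(is.na(tt))[1L]]
    stop("malformed line ", bad, " in ", path, ": non-numeric time index")
  }
  u <- vapply(fields, `[[`, "", 2L)
  v <- vapply(fields, `[[`, "", 3L)
  if (any(u == v)) {
    bad <- lineno[which(u == v)[1L]]
    stop("self-loop at line ", bad, " in ", path, " is not allowed")
  }
  if (!is.na(declared_t)) {
    # declared time-point count: indices are literal 0-based slots, so
    # edgeless snapshots survive a round trip
    if (any(tt %% 1 != 0 | tt < 0 | tt >= declared_t)) {
      stop("time index outside 0..t-1 despite #t: declaration in ", path)
    }
    ti <- as.integer(tt) + 1L
    n_t <- declared_t
  } else {
    times <- sort(unique(tt))
    ti <- match(tt, times)
    n_t <- length(times)
  }
  snaps <- lapply(seq_len(n_t), function(i) {
    cbind(u[ti == i], v[ti == i])
  })
  temporal_network(snaps, nodes = declared)
}

read_edge_list <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  body <- lines[keep]
  if (length(body) == 0L) return(matrix(character(0), ncol = 2L))
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 2L)) {
    stop("malformed line ", which(keep)[which(nf < 2L)[1L]], " in ", path,
         ": expected at least 2 tab-separated fields")
  }
  # extra columns (e.g. BioGRID exports) are ignored
  cbind(vapply(fields, `[[`, "", 1L), vapply(fields, `[[`, "", 2L))
}

#' Write a temporal network to disk
#'
#' Writes the canonical long-format TSV: `#nodes:` and `#t:` declaration
#' lines (so isolated nodes and edgeless snapshots survive a round trip)
#' followed by one
#' `time<TAB>u<TAB>v` line per edge, with 0-based dense time indices,
#' `u < v` lexicographically, and edges sorted by (time, u, v). Two writes
#' of the same network are byte-identical.
#'
#' @param net A [temporal_network()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_temporal_network <- function(net, path) {
  stopifnot(inherits(net, "temporal_network"))
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("#nodes: ", paste(net$nodes, collapse = ",")), con)
  writeLines(paste0("#t: ", net$t), con)
  for (i in seq_len(net$t)) {
    e <- net$snapshots[[i]]
    if (nrow(e) == 0L) next
    u <- net$nodes[e[, 1L]]
    v <- net$nodes[e[, 2L]]
    # node order is sorted, so index order == lexicographic label order
    writeLines(paste(i - 1L, u, v, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a gene-expression matrix
#'
#' First column holds gene labels; the remaining columns are conditions in
#' time order (header line names them).
#'
#' @param path TSV file path.
#' @return A list of class `expression_table` with fields `genes`,
#'   `conditions`, and `values` (genes x conditions numeric matrix).
#' @export
read_expression <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  expression_table(df[[1L]], as.matrix(df[, -1L, drop = FALSE]))
}

#' Construct an expression table
#'
#' @param genes Character vector of gene labels (no duplicates).
#' @param values Numeric matrix, one row per gene, one column per
#'   condition; column names are the condition labels.
#' @export
expression_table <- function(genes, values) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicate gene labels in expression table")
  values <- as.matrix(values)
  if (nrow(values) != length(genes)) {
    stop("expression matrix has ", nrow(values), " rows for ",
         length(genes), " gene labels")
  }
  conds <- colnames(values)
  if (is.null(conds)) conds <- paste0("c", seq_len(ncol(values)))
  rownames(values) <- genes
  colnames(values) <- conds
  structure(list(genes = genes, conditions = conds, values = values),
            class = "expression_table")
}

#' Build condition-specific networks by expression thresholding
#'
#' Integrates a static interaction network with an expression matrix into a
#' temporal network with one snapshot per condition: an interaction (u, v)
#' is kept at condition i iff both endpoints have expression at least
#' `cutoff` there; interactions where either protein falls below the
#' cut-off are removed from that condition's network. Static edges whose
#' endpoints are absent from the expression table are dropped (a message
#' reports how many).
#'
#' @param expr An [expression_table()].
#' @param static_edges Two-column character matrix (or data frame) of
#'   static interactions; extra columns are ignored.
#' @param cutoff Finite numeric expression cut-off.
#' @return A [temporal_network()] over the genes of `expr`, one snapshot
#'   per condition in condition order.
#' @export
build_condition_networks <- function(expr, static_edges, cutoff) {
  stopifnot(inherits(expr, "expression_table"))
  if (!is.numeric(cutoff) || length(cutoff) != 1L || !is.finite(cutoff)) {
    stop("'cutoff' must be a single finite number")
  }
  if (is.data.frame(static_edges)) static_edges <- as.matrix(static_edges)
  static_edges <- static_edges[, 1:2, drop = FALSE]
  storage.mode(static_edges) <- "character"
  known <- static_edges[, 1L] %in% expr$genes &
    static_edges[, 2L] %in% expr$genes
  if (any(!known)) {
    message(sum(!known), " static edge(s) dropped: endpoint(s) absent ",
            "from the expression table")
  }
  edges <- static_edges[known, , drop = FALSE]
  edges <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]
  snaps <- lapply(expr$conditions, function(ci) {
    on <- expr$values[edges[, 1L], ci] >= cutoff &
      expr$values[edges[, 2L], ci] >= cutoff
    edges[on, , drop = FALSE]
  })
  temporal_network(snaps, nodes = expr$genes)
}

#' Interleaved time-point selection
#'
#' Carves an interleaved subsequence of condition indices out of an ordered
#' series: starting at `offset` (0-based), take every `stride`-th index,
#' `take` times. With `stride` 5 this realizes "take one age group, skip
#' the next four" so that offsets `0..stride-1` give pairwise disjoint,
#' interleaved temporal networks.
#'
#' @param n_points Number of available time points in the series.
#' @param offset 0-based starting index, `0 <= offset < stride`.
#' @param stride Distance between consecutive selected indices.
#' @param take Number of indices to select.
#' @return Integer vector of 0-based indices, length `take`.
#' @examples
#' interleave_time_points(35, 0, 5, 7) # 0 5 10 15 20 25 30
#' @export
interleave_time_points <- function(n_points, offset, stride, take) {
  stopifnot(length(n_points) == 1L, length(offset) == 1L,
            length(stride) == 1L, length(take) == 1L)
  if (offset < 0L || offset >= stride) stop("need 0 <= offset < stride")
  if (take < 1L) stop("'take' must be at least 1")
  last <- offset + (take - 1L) * stride
  if (last >= n_points) {
    max_take <- floor((n_points - 1L - offset) / stride) + 1L
    stop("insufficient time points: with n_points = ", n_points,
         ", offset = ", offset, ", stride = ", stride,
         ", at most take = ", max(max_take, 0L), " is feasible")
  }
  as.integer(offset + stride * (seq_len(take) - 1L))
}
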