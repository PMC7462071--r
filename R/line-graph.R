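#' Build the weighted line graph of a splicing graph
#'
#' Standard line-graph construction: one L-node per edge of the splicing
#' graph G, weighted by that edge's read coverage, and one L-edge per
#' incident edge pair of G (an edge ending at a node paired with an edge
#' leaving it). L is a DAG because G is.
#'
#' @param graph A `splicing_graph`.
#' @return A `line_graph`: list with `n_nodes`, `node_weight` (numeric, the
#'   working weights updated during assembly), `edges` (data.frame `from`,
#'   `to`, `weight`, `g_node` = the shared G-node), `origin` (the G edge
#'   table, backing each L-node), and `succ`/`pred` adjacency lists.
#' @export
build_line_graph <- function(graph) {
  e <- graph$edges
  n <- nrow(e)
  from <- integer(0); to <- integer(0); gnode <- integer(0)
  for (v in seq_len(nrow(graph$nodes))) {
    ins <- which(e$to == v)
    outs <- which(e$from == v)
    if (length(ins) && length(outs)) {
      grid <- expand.grid(i = ins, j = outs)
      from <- c(from, grid$i); to <- c(to, grid$j)
      gnode <- c(gnode, rep(v, nrow(grid)))
    }
  }
  o <- order(from, to)
  ledges <- data.frame(from = from[o], to = to[o],
                       weight = rep(1, length(o)), g_node = gnode[o])
  lg <- list(
    n_nodes = n,
    node_weight = e$weight,
    edges = ledges,
    origin = e,
    graph = graph,
    succ = split(ledges$to, factor(ledges$from, levels = seq_len(n))),
    pred = split(ledges$from, factor(ledges$to, levels = seq_len(n)))
  )
  class(lg) <- "line_graph"
  lg
}

#' @export
print.line_graph <- function(x, ...) {
  cat(sprintf("line_graph: %d nodes, %d edges\n", x$n_nodes, nrow(x$edges)))
  invisible(x)
}

# Witnessed (in-edge, out-edge) pairs per G-node, from the length-3 windows
# of the merged reliable subpaths.
#' @keywords internal
witnessed_pairs <- function(graph, reliable) {
  emap <- edge_index_map(graph)
  out <- list()
  for (e in reliable) {
    nodes <- e$nodes
    if (length(nodes) < 3L) next
    for (t in 2L:(length(nodes) - 1L)) {
      ein <- emap[paste(nodes[t - 1L], nodes[t], sep = ",")]
      eout <- emap[paste(nodes[t], nodes[t + 1L], sep = ",")]
      if (is.na(ein) || is.na(eout)) next
      v <- as.character(nodes[t])
      out[[v]] <- unique(rbind(out[[v]], c(ein, eout)))
    }
  }
  out
}

#' Solve the connection quadratic program at one splicing-graph node
#'
#' Distributes flow between the in-edges and out-edges of a branching node
#' so that row sums approximate the in-edge coverages and column sums the
#' out-edge coverages: minimize
#' \deqn{\sum_i (\sum_j f_{ij} - w_i)^2 + \sum_j (\sum_i f_{ij} - w_j)^2}
#' subject to \eqn{f_{ij} \ge 0}, with the floor
#' \eqn{f_{ij} \ge \epsilon \min(w_i, w_j)} on every pair witnessed by a
#' reliable 3-subpath through the node. Solved by non-negative least
#' squares after shifting out the floors; the active-set pivot order of the
#' solver is deterministic for a fixed input order. If all edge coverages
#' are zero, a uniform unit flow is placed on the witnessed pairs (on all
#' pairs when none is witnessed).
#'
#' @param graph A `splicing_graph`.
#' @param v Node index with at least one in-edge and one out-edge.
#' @param reliable Merged `reliable_set` of the graph (witness source).
#' @param eps_support Witness floor fraction (default 0.05).
#' @return Numeric matrix of flows, rows = in-edge indices (of
#'   `graph$edges`), columns = out-edge indices, with dimnames set to those
#'   indices.
#' @export
solve_connection_qp <- function(graph, v, reliable, eps_support = 0.05) {
  e <- graph$edges
  ins <- which(e$to == v)
  outs <- which(e$from == v)
  stopifnot(length(ins) >= 1L, length(outs) >= 1L)
  wit <- witnessed_pairs(graph, reliable)[[as.character(v)]]
  connection_qp(e$weight[ins], e$weight[outs],
                witness_mask(ins, outs, wit), eps_support,
                dn = list(as.character(ins), as.character(outs)))
}

#' @keywords internal
witness_mask <- function(ins, outs, wit) {
  m <- matrix(FALSE, length(ins), length(outs))
  if (!is.null(wit)) {
    for (r in seq_len(nrow(wit))) {
      i <- match(wit[r, 1L], ins); j <- match(wit[r, 2L], outs)
      if (!is.na(i) && !is.na(j)) m[i, j] <- TRUE
    }
  }
  m
}

# Core NNLS solve on raw weight vectors; `mask` marks witnessed pairs.
#' @keywords internal
connection_qp <- function(w_in, w_out, mask = NULL, eps_support = 0.05,
                          dn = NULL) {
  ni <- length(w_in); nj <- length(w_out)
  if (is.null(mask)) mask <- matrix(FALSE, ni, nj)
  if (all(w_in == 0) && all(w_out == 0)) {
    f <- matrix(0, ni, nj)
    if (any(mask)) f[mask] <- 1 else f[] <- 1
    dimnames(f) <- dn
    return(f)
  }
  nv <- ni * nj
  A <- matrix(0, ni + nj, nv)
  for (i in seq_len(ni)) for (j in seq_len(nj)) {
    k <- (j - 1L) * ni + i
    A[i, k] <- 1
    A[ni + j, k] <- 1
  }
  b <- c(w_in, w_out)
  lb <- matrix(0, ni, nj)
  lb[mask] <- eps_support * outer(w_in, w_out, pmin)[mask]
  # tiny ridge row block keeps the active-set solver away from singular
  # subsystems (the row/column-sum design matrix is rank-deficient)
  A_aug <- rbind(A, diag(1e-4, nv))
  b_aug <- c(b - as.vector(A %*% as.vector(lb)), rep(0, nv))
  g <- pracma::lsqnonneg(A_aug, b_aug)$x
  f <- lb + matrix(g, ni, nj)
  f[abs(f) < 1e-9] <- 0
  dimnames(f) <- dn
  f
}

#' Binarize line-graph edge weights from the connection flows
#'
#' An L-edge (e_i, e_j) through G-node v gets weight 1 when its flow is at
#' least `theta` times the largest flow at v, or when it carries the
#' largest (non-zero) flow leaving e_i (every expressed in-edge continues
#' through its best pairing, so each L-node with successors keeps at least
#' one weight-1 outgoing edge unless its flows are all zero), or when the
#' pair is witnessed by any reliable subpath; otherwise 0. Non-branching
#' incidences (one in-edge, one out-edge) always get weight 1.
#'
#' @param line A `line_graph`.
#' @param flows Named list: G-node (as character) -> flow matrix from
#'   [solve_connection_qp()].
#' @param theta Fraction of the per-node maximum flow (default 0.1).
#' @param witnessed Per-node witnessed pair matrices (internal format from
#'   `witnessed_pairs`); optional.
#' @return The `line_graph` with 0/1 edge weights.
#' @export
binarize_edge_weights <- function(line, flows, theta = 0.1, witnessed = NULL) {
  e <- line$edges
  origin <- line$origin
  for (r in seq_len(nrow(e))) {
    v <- e$g_node[r]
    ins <- which(origin$to == v)
    outs <- which(origin$from == v)
    if (length(ins) == 1L && length(outs) == 1L) {
      e$weight[r] <- 1
      next
    }
    f <- flows[[as.character(v)]]
    wit <- if (!is.null(witnessed)) witnessed[[as.character(v)]] else NULL
    is_wit <- !is.null(wit) &&
      any(wit[, 1L] == e$from[r] & wit[, 2L] == e$to[r])
    if (is_wit) {
      e$weight[r] <- 1
      next
    }
    if (is.null(f)) { e$weight[r] <- 1; next }
    fij <- f[as.character(e$from[r]), as.character(e$to[r])]
    fmax <- max(f)
    row_max <- max(f[as.character(e$from[r]), ])
    e$weight[r] <- as.numeric((fmax > 0 && fij >= theta * fmax) ||
                                (fij > 0 && fij == row_max))
  }
  line$edges <- e
  line
}

#' Weight a line graph end to end
#'
#' Convenience wrapper: builds L(G), solves the connection QP at every
#' branching G-node, and binarizes the L-edge weights.
#'
#' @inheritParams solve_connection_qp
#' @inheritParams binarize_edge_weights
#' @return A weighted, binarized `line_graph`.
#' @export
weight_line_graph <- function(graph, reliable, eps_support = 0.05,
                              theta = 0.1) {
  line <- build_line_graph(graph)
  wit <- witnessed_pairs(graph, reliable)
  e <- graph$edges
  branch <- unique(line$edges$g_node)
  flows <- list()
  for (v in branch) {
    ins <- which(e$to == v); outs <- which(e$from == v)
    if (length(ins) == 1L && length(outs) == 1L) next
    flows[[as.character(v)]] <- connection_qp(
      e$weight[ins], e$weight[outs],
      witness_mask(ins, outs, wit[[as.character(v)]]), eps_support,
      dn = list(as.character(ins), as.character(outs))
    )
  }
  binarize_edge_weights(line, flows, theta, wit)
}

#' Project a splicing-graph path into the line graph
#'
#' The consecutive node pairs of a G-path become the ordered list of their
#' G-edges, i.e. L-nodes; a length-n G-path maps to a length-(n-1) L-path.
#' A pair not joined by a G-edge is an error (the path was not genuine).
#'
#' @param nodes Integer G-node path of length >= 2.
#' @param graph The `splicing_graph`.
#' @return Integer vector of L-node (= G-edge) indices.
#' @export
project_subpath <- function(nodes, graph) {
  stopifnot(length(nodes) >= 2L)
  emap <- edge_index_map(graph)
  keys <- paste(nodes[-length(nodes)], nodes[-1L], sep = ",")
  idx <- emap[keys]
  if (any(is.na(idx)))
    stop("subpath is not a genuine path: missing edge ",
         keys[which(is.na(idx))[1L]])
  unname(idx)
}
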