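# The assembly core: reliable subpaths (projected into the line graph) seed
# greedy bidirectional path extension; committed paths subtract their
# minimum node weight (c_min), which doubles as the transcript's abundance
# proxy.

# Project merged reliable G-subpaths to L-paths; G 2-subpaths become single
# L-nodes. Entries are re-sorted in the canonical order on L-path length.
#' @keywords internal
project_reliable <- function(reliable, graph) {
  out <- list()
  for (e in reliable) {
    if (length(e$nodes) < 2L) next
    l <- project_subpath(e$nodes, graph)
    e$l_nodes <- l
    out[[length(out) + 1L]] <- e
  }
  if (length(out)) {
    len <- vapply(out, function(e) length(e$l_nodes), integer(1))
    prov <- vapply(out, function(e)
      ifelse(e$provenance == "read", 1L, 0L), integer(1))
    score <- vapply(out, function(e) e$score, numeric(1))
    keys <- vapply(out, function(e) path_key(e$l_nodes), character(1))
    out <- out[order(-len, prov, -score, keys)]
  }
  out
}

# Hash of every contiguous window (length >= 1) of every reliable L-path;
# used for the witness tests of the extension hierarchy.
#' @keywords internal
witness_table <- function(entries) {
  env <- new.env(hash = TRUE, parent = emptyenv())
  for (e in entries) {
    l <- e$l_nodes
    for (k in seq_len(length(l))) {
      for (w in path_windows(l, k)) env[[path_key(w)]] <- TRUE
    }
  }
  env
}

#' Choose the next seed for path extension
#'
#' Returns the longest reliable L-subpath not yet covered by any predicted
#' path (ties: assembly-derived before read-derived, then higher score, then
#' lexicographic by node indices); when every reliable subpath is covered,
#' the unused L-node with the largest current weight (ties: smallest index);
#' when every node is used, `NULL` (done).
#'
#' @param entries Projected reliable entries (internal order).
#' @param covered Logical vector over `entries`.
#' @param used Logical vector over L-nodes.
#' @param weights Current L-node weights.
#' @return List with `type` (`"subpath"`/`"node"`) and `l_nodes`, or `NULL`.
#' @export
select_seed <- function(entries, covered, used, weights) {
  open <- which(!covered)
  if (length(open)) {
    # entries are pre-sorted in the canonical order
    return(list(type = "subpath", index = open[1L],
                l_nodes = entries[[open[1L]]]$l_nodes))
  }
  free <- which(!used)
  if (length(free) == 0L) return(NULL)
  pick <- free[order(-weights[free], free)][1L]
  list(type = "node", index = NA_integer_, l_nodes = pick)
}

# One extension step to the right of `path`; NULL when no successor.
#' @keywords internal
step_right <- function(path, line, witness, strict_binary = FALSE) {
  last <- path[length(path)]
  succ <- line$succ[[last]]
  if (length(succ) == 0L) return(NULL)
  w1 <- succ[line$edges$weight[match(paste(last, succ, sep = ","),
                                     paste(line$edges$from, line$edges$to,
                                           sep = ","))] == 1]
  cands <- if (length(w1)) w1 else if (strict_binary) return(NULL) else succ
  if (length(cands) > 1L) {
    for (k in 2L:(length(path) + 1L)) {
      suffix <- path[(length(path) - k + 2L):length(path)]
      sup <- cands[vapply(cands, function(cd)
        isTRUE(witness[[path_key(c(suffix, cd))]]), logical(1))]
      if (length(sup) == 0L) break
      cands <- sup
      if (length(cands) == 1L) break
    }
  }
  if (length(cands) > 1L)
    cands <- cands[order(-line$node_weight[cands], cands)]
  cands[1L]
}

#' Extend a line-graph path to the right
#'
#' Repeatedly appends a right neighbor of the path's last node until it has
#' no outgoing edges, choosing at each step by the extension hierarchy:
#' (1) neighbors reachable by a weight-1 L-edge (all neighbors when none
#' is, unless `strict_binary`); (2) among multiple candidates, those
#' supported by a reliable 2-subpath (current last node, candidate), then a
#' reliable 3-subpath, and so on with increasing witness length while more
#' than one candidate survives and a witness exists; (3) the largest
#' current node weight; (4) the smallest node index.
#'
#' @param path Integer L-node path.
#' @param line A weighted `line_graph`.
#' @param witness Witness table from the projected reliable entries
#'   (internal; built by [assemble_graph()]).
#' @param strict_binary Stop instead of falling back to weight-0 edges
#'   (default FALSE).
#' @return The maximally right-extended path.
#' @export
extend_right <- function(path, line, witness, strict_binary = FALSE) {
  repeat {
    nxt <- step_right(path, line, witness, strict_binary)
    if (is.null(nxt)) return(path)
    path <- c(path, nxt)
  }
}

# Mirror of step_right: prefix witnesses and predecessors.
#' @keywords internal
step_left <- function(path, line, witness, strict_binary = FALSE) {
  first <- path[1L]
  pred <- line$pred[[first]]
  if (length(pred) == 0L) return(NULL)
  w1 <- pred[line$edges$weight[match(paste(pred, first, sep = ","),
                                     paste(line$edges$from, line$edges$to,
                                           sep = ","))] == 1]
  cands <- if (length(w1)) w1 else if (strict_binary) return(NULL) else pred
  if (length(cands) > 1L) {
    for (k in 2L:(length(path) + 1L)) {
      prefix <- path[seq_len(k - 1L)]
      sup <- cands[vapply(cands, function(cd)
        isTRUE(witness[[path_key(c(cd, prefix))]]), logical(1))]
      if (length(sup) == 0L) break
      cands <- sup
      if (length(cands) == 1L) break
    }
  }
  if (length(cands) > 1L)
    cands <- cands[order(-line$node_weight[cands], cands)]
  cands[1L]
}

#' Extend a line-graph path to the left
#'
#' Mirror image of [extend_right()]: prepends predecessors chosen by the
#' same hierarchy with prefix-witness subpaths, until the first node has no
#' incoming edges.
#'
#' @inheritParams extend_right
#' @return The maximally left-extended path.
#' @export
extend_left <- function(path, line, witness, strict_binary = FALSE) {
  repeat {
    prv <- step_left(path, line, witness, strict_binary)
    if (is.null(prv)) return(path)
    path <- c(prv, path)
  }
}

#' Commit a predicted path and update node weights
#'
#' `c_min` is the minimum current node weight along the path; every on-path
#' node weight is reduced by `c_min` (never below zero by construction).
#' The path is recorded with `c_min` as its abundance proxy.
#'
#' @param path Maximal L-node path.
#' @param line A `line_graph`.
#' @return List with `transcript` (list `l_nodes`, `g_nodes`, `c_min`) and
#'   the updated `line`.
#' @export
commit_path <- function(path, line) {
  nodes <- unique(path)
  c_min <- min(line$node_weight[nodes])
  line$node_weight[nodes] <- line$node_weight[nodes] - c_min
  g_nodes <- c(line$origin$from[path[1L]], line$origin$to[path])
  list(transcript = list(l_nodes = path, g_nodes = g_nodes, c_min = c_min),
       line = line)
}

#' Assemble one weighted line graph into transcript paths
#'
#' Iterates seed selection, bidirectional extension and commitment until
#' every reliable subpath is a contiguous subsequence of some predicted
#' path and every L-node lies on some predicted path. Each iteration covers
#' at least one new subpath or node, so the loop terminates; an iteration
#' cap (10 x number of L-nodes + 10) guards against defects.
#'
#' @param line A weighted, binarized `line_graph`.
#' @param reliable Merged `reliable_set` in splicing-graph coordinates.
#' @param strict_binary See [extend_right()].
#' @return List of transcript paths (`l_nodes`, `g_nodes`, `c_min`).
#' @export
assemble_graph <- function(line, reliable, strict_binary = FALSE) {
  entries <- project_reliable(reliable, line$graph)
  witness <- witness_table(entries)
  covered <- logical(length(entries))
  used <- logical(line$n_nodes)
  paths <- list()
  cap <- 10L * line$n_nodes + 10L
  iter <- 0L
  repeat {
    seed <- select_seed(entries, covered, used, line$node_weight)
    if (is.null(seed)) break
    iter <- iter + 1L
    if (iter > cap)
      stop("path extension failed to converge (", iter, " iterations; ",
           sum(!covered), " subpaths and ", sum(!used), " nodes uncovered)")
    p <- seed$l_nodes
    p <- extend_right(p, line, witness, strict_binary)
    p <- extend_left(p, line, witness, strict_binary)
    res <- commit_path(p, line)
    line <- res$line
    paths[[length(paths) + 1L]] <- res$transcript
    used[p] <- TRUE
    for (i in which(!covered)) {
      if (is_contiguous_subseq(entries[[i]]$l_nodes, p)) covered[i] <- TRUE
    }
  }
  paths
}

#' Assemble a whole splicing graph (all components) into transcript paths
#'
#' Isolated covered segments become single-exon transcript paths with
#' `c_min` equal to their mean base coverage; components with edges go
#' through line-graph weighting and [assemble_graph()].
#'
#' @param graph A `splicing_graph`.
#' @param reliable Merged `reliable_set` for the graph.
#' @param eps_support,theta See [weight_line_graph()].
#' @param strict_binary See [extend_right()].
#' @return List of transcript paths; single-exon ones carry `g_nodes` only.
#' @export
assemble_splicing_graph <- function(graph, reliable, eps_support = 0.05,
                                    theta = 0.1, strict_binary = FALSE) {
  paths <- list()
  iso <- setdiff(seq_len(nrow(graph$nodes)),
                 c(graph$edges$from, graph$edges$to))
  for (ni in iso) {
    paths[[length(paths) + 1L]] <- list(
      l_nodes = integer(0), g_nodes = ni, c_min = graph$nodes$cov[ni]
    )
  }
  if (nrow(graph$edges) > 0L) {
    line <- weight_line_graph(graph, reliable, eps_support, theta)
    paths <- c(paths, assemble_graph(line, reliable, strict_binary))
  }
  paths
}

#' Convert transcript paths to GTF records
#'
#' Drops paths whose `c_min` falls below `min_cov` (the post-assembly
#' expression filter: raising it trades recall for precision), merges
#' abutting exon segments into exons, and emits one `transcript` plus its
#' `exon` features per path in 1-based inclusive GTF coordinates, with
#' `gene_id`, `transcript_id` and `cov` attributes.
#'
#' @param paths Transcript paths from [assemble_splicing_graph()].
#' @param graph The `splicing_graph` the paths live in.
#' @param min_cov Minimum `c_min` to report a transcript (default 1.5).
#' @param gene_id Gene identifier used in the attributes.
#' @return Character vector of GTF lines (possibly empty).
#' @export
paths_to_gtf <- function(paths, graph, min_cov = 1.5, gene_id = "gene1") {
  lines <- character(0)
  ti <- 0L
  strand <- if (graph$strand %in% c("+", "-")) graph$strand else "."
  for (p in paths) {
    if (p$c_min < min_cov) next
    ti <- ti + 1L
    segs <- cbind(graph$nodes$start[p$g_nodes], graph$nodes$end[p$g_nodes])
    exons <- merge_abutting(segs)
    tid <- sprintf("%s.%d", gene_id, ti)
    attr_str <- sprintf('gene_id "%s"; transcript_id "%s"; cov "%.4f";',
                        gene_id, tid, p$c_min)
    lines <- c(lines, sprintf("%s\tisopath\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                              graph$chrom, min(exons[, 1L]) + 1L,
                              max(exons[, 2L]), strand, attr_str))
    for (i in seq_len(nrow(exons))) {
      lines <- c(lines, sprintf(
        "%s\tisopath\texon\t%d\t%d\t.\t%s\t.\t%s exon_number \"%d\";",
        graph$chrom, exons[i, 1L] + 1L, exons[i, 2L], strand, attr_str, i))
    }
  }
  lines
}
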