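#' Map an aligned fragment onto a splicing-graph node path
#'
#' Each alignment block maps to the run of abutting exon segments it covers;
#' every gap between consecutive blocks must coincide exactly with a
#' junction edge of the graph, and consecutive segments within a block must
#' be joined by adjacency edges. Any mismatch (a gap that is not a known
#' junction, a block outside all segments beyond `tol`, a missing adjacency)
#' yields `NULL` (unmapped).
#'
#' @param blocks Two-column matrix of 0-based half-open alignment blocks.
#' @param graph A `splicing_graph`.
#' @param tol Tolerance (bp) by which a block may extend past its segment
#'   run (default 0).
#' @return Integer vector of node indices (a genuine path in the graph), or
#'   `NULL` if unmapped.
#' @export
fragment_to_node_path <- function(blocks, graph, tol = 0L) {
  nodes <- graph$nodes
  emap <- edge_index_map(graph)
  jkey <- paste(graph$edges$donor, graph$edges$acceptor, sep = ":")
  path <- integer(0)
  for (bi in seq_len(nrow(blocks))) {
    s <- blocks[bi, 1L]; e <- blocks[bi, 2L]
    hit <- which(nodes$start < e & nodes$end > s)
    if (length(hit) == 0L) return(NULL)
    # segments covering one block must form an abutting run
    if (length(hit) > 1L) {
      for (i in seq_len(length(hit) - 1L)) {
        if (nodes$end[hit[i]] != nodes$start[hit[i + 1L]]) return(NULL)
        k <- paste(hit[i], hit[i + 1L], sep = ",")
        if (is.na(emap[k])) return(NULL)
      }
    }
    if (s < nodes$start[hit[1L]] - tol) return(NULL)
    if (e > nodes$end[hit[length(hit)]] + tol) return(NULL)
    if (bi > 1L) {
      gap_key <- sprintf("%d:%d", blocks[bi - 1L, 2L], s)
      prev <- path[length(path)]
      ek <- paste(prev, hit[1L], sep = ",")
      ei <- emap[ek]
      if (is.na(ei) || !(jkey[ei] == gap_key)) return(NULL)
    }
    path <- c(path, hit)
  }
  path
}

#' Connect two mate paths through the splicing graph
#'
#' Given the node paths of the two mates of a pair (left mate path `p1`,
#' right mate path `p2`), enumerates all graph paths from the last node of
#' `p1` to the first node of `p2`. If exactly one connecting path exists and
#' the combined length rule p + s + q >= 3 holds (p, q = mate path lengths,
#' s = number of strictly interior connector nodes), the mates are joined
#' into one paired subpath. If the mate paths overlap, they are merged
#' directly when the shared region is consistent, under the same length
#' rule with s = 0 (so the merged path may be shorter than 3 nodes when the
#' mates share nodes). Zero connecting paths, two or more connecting paths
#' (or hitting the enumeration cap), or an inconsistent overlap yield `NULL`.
#'
#' @param p1,p2 Integer node paths of the left and right mates.
#' @param graph A `splicing_graph`.
#' @param max_paths Cap on enumerated connectors; reaching it counts as
#'   ambiguous (default 64).
#' @param max_depth Depth cap of the connector search (default 32).
#' @return Integer node path of the paired subpath, or `NULL`.
#' @export
connect_pair <- function(p1, p2, graph, max_paths = 64L, max_depth = 32L) {
  if (is.null(p1) || is.null(p2) || length(p1) == 0L || length(p2) == 0L)
    return(NULL)
  i_end <- p1[length(p1)]
  j_start <- p2[1L]
  if (i_end < j_start) {
    conns <- enumerate_paths(graph, i_end, j_start, max_paths, max_depth)
    if (length(conns) != 1L) return(NULL)
    interior <- conns[[1L]]
    interior <- interior[-c(1L, length(interior))]
    if (length(p1) + length(interior) + length(p2) < 3L) return(NULL)
    return(c(p1, interior, p2))
  }
  # overlap (or containment) case
  pos <- match(j_start, p1)
  if (is.na(pos)) {
    warning("mate paths overlap inconsistently; pair dropped")
    return(NULL)
  }
  ov <- min(length(p1) - pos + 1L, length(p2))
  if (!all(p1[pos:(pos + ov - 1L)] == p2[seq_len(ov)])) {
    warning("mate paths disagree on shared nodes; pair dropped")
    return(NULL)
  }
  if (length(p1) + length(p2) < 3L) return(NULL)  # p + s + q with s = 0
  c(p1, p2[-seq_len(ov)])
}

# DFS path enumeration from `from` to `to`; stops early past the cap.
#' @keywords internal
enumerate_paths <- function(graph, from, to, max_paths = 64L, max_depth = 32L) {
  succ <- split(graph$edges$to, factor(graph$edges$from,
                                       levels = seq_len(nrow(graph$nodes))))
  found <- list()
  capped <- FALSE
  walk <- function(path) {
    if (capped) return()
    last <- path[length(path)]
    if (last == to) {
      found[[length(found) + 1L]] <<- path
      if (length(found) >= max_paths) capped <<- TRUE
      return()
    }
    if (length(path) > max_depth) { capped <<- TRUE; return() }
    for (nxt in succ[[last]]) {
      if (nxt <= to) walk(c(path, nxt))
    }
  }
  walk(from)
  if (capped) return(vector("list", max_paths + 1L))  # counts as ambiguous
  found
}

#' Collect paired subpaths over a splicing graph
#'
#' Maps both mates of every pair to node paths, connects them with
#' [connect_pair()], and aggregates identical node sequences; the coverage
#' of a paired subpath is the number of read pairs generating it. Singletons
#' and unmapped or unconnectable pairs contribute nothing.
#'
#' @param pairs Pair list of one locus.
#' @param graph The locus `splicing_graph`.
#' @param max_paths,max_depth Connector enumeration caps, see
#'   [connect_pair()].
#' @return A list of paired subpaths, each a list with `nodes` and
#'   `coverage`.
#' @export
collect_paired_subpaths <- function(pairs, graph, max_paths = 64L,
                                    max_depth = 32L) {
  tally <- new.env(hash = TRUE, parent = emptyenv())
  paths <- new.env(hash = TRUE, parent = emptyenv())
  for (p in pairs) {
    if (is.null(p$right)) next
    p1 <- fragment_to_node_path(p$left$blocks, graph)
    p2 <- fragment_to_node_path(p$right$blocks, graph)
    if (is.null(p1) || is.null(p2)) next
    merged <- connect_pair(p1, p2, graph, max_paths, max_depth)
    if (is.null(merged)) next
    key <- path_key(merged)
    tally[[key]] <- if (is.null(tally[[key]])) 1L else tally[[key]] + 1L
    paths[[key]] <- merged
  }
  keys <- sort(ls(tally))
  lapply(keys, function(k) list(nodes = paths[[k]], coverage = tally[[k]]))
}

#' Decompose paired subpaths into reliable k-subpaths
#'
#' Every contiguous length-k window of every paired subpath is a paired
#' k-subpath; its coverage is the sum of the coverages of all paired
#' subpaths containing it. Windows with coverage at least `min_score`
#' (default 2) are reliable. Windows are produced for every k from `min_k`
#' up to the longest subpath length; within each length class entries are
#' sorted by coverage descending, ties broken lexicographically by node
#' indices.
#'
#' @param subpaths Output of [collect_paired_subpaths()].
#' @param min_score Reliability threshold on summed coverage (default 2).
#' @param min_k Smallest window length produced (default 2; the canonical
#'   decomposition starts at 3, but length-2 windows feed the extension
#'   rule's 2-subpath support test).
#' @return A `reliable_set`: list of entries with `nodes`, `score`,
#'   `provenance = "read"`, sorted by length descending then the per-class
#'   order above.
#' @export
decompose_reliable <- function(subpaths, min_score = 2L, min_k = 2L) {
  tally <- new.env(hash = TRUE, parent = emptyenv())
  store <- new.env(hash = TRUE, parent = emptyenv())
  max_len <- if (length(subpaths)) max(vapply(subpaths, function(s)
    length(s$nodes), integer(1))) else 0L
  for (sp in subpaths) {
    n <- length(sp$nodes)
    for (k in min_k:max(min_k, n)) {
      for (w in path_windows(sp$nodes, k)) {
        key <- path_key(w)
        tally[[key]] <- if (is.null(tally[[key]])) sp$coverage else
          tally[[key]] + sp$coverage
        store[[key]] <- w
      }
    }
  }
  entries <- list()
  for (key in ls(tally)) {
    if (tally[[key]] >= min_score) {
      entries[[length(entries) + 1L]] <- list(
        nodes = store[[key]], score = as.numeric(tally[[key]]),
        provenance = "read"
      )
    }
  }
  sort_reliable(entries)
}

# Canonical reliable-set order: length desc, then (within a length class)
# provenance rank (assembly/merged before read), score desc, lexicographic.
#' @keywords internal
sort_reliable <- function(entries) {
  if (length(entries) == 0L) {
    class(entries) <- "reliable_set"
    return(entries)
  }
  len <- vapply(entries, function(e) length(e$nodes), integer(1))
  prov <- vapply(entries, function(e)
    ifelse(e$provenance == "read", 1L, 0L), integer(1))
  score <- vapply(entries, function(e) e$score, numeric(1))
  keys <- vapply(entries, function(e) path_key(e$nodes), character(1))
  entries <- entries[order(-len, prov, -score, keys)]
  class(entries) <- "reliable_set"
  entries
}

#' @export
print.reliable_set <- function(x, ...) {
  cat(sprintf("reliable_set of %d subpaths\n", length(x)))
  for (e in utils::head(x, 10L)) {
    cat(sprintf("  [%s] score=%g (%s)\n", paste(e$nodes, collapse = ">"),
                e$score, e$provenance))
  }
  if (length(x) > 10L) cat("  ...\n")
  invisible(x)
}

#' Dump a reliable set as TSV (debug aid)
#' @param set A `reliable_set`.
#' @param con Connection or file path.
#' @export
dump_reliable_tsv <- function(set, con) {
  lines <- c("k\tnodes\tscore\tprovenance",
             vapply(set, function(e) sprintf("%d\t%s\t%g\t%s",
                                             length(e$nodes),
                                             paste(e$nodes, collapse = ","),
                                             e$score, e$provenance),
                    character(1)))
  writeLines(lines, con)
  invisible(lines)
}
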