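#' Tally splice junctions in a locus
#'
#' Every gap between consecutive alignment blocks of any fragment in the
#' locus is a candidate intron. A fragment supports an intron once, even if
#' both mates spell it. Candidates supported by fewer than
#' `min_junction_reads` fragments are discarded.
#'
#' @param locus A locus from [cluster_loci()].
#' @param min_junction_reads Minimum fragment support to retain a junction
#'   (default 1).
#' @return A data.frame with columns `donor`, `acceptor` (0-based intron
#'   interval: donor = intron start, acceptor = intron end, exclusive) and
#'   `count`, sorted by coordinate.
#' @export
collect_junctions <- function(locus, min_junction_reads = 1L) {
  tally <- new.env(hash = TRUE, parent = emptyenv())
  for (p in locus$pairs) {
    seen <- character(0)
    for (fr in list(p$left, p$right)) {
      if (is.null(fr)) next
      b <- fr$blocks
      if (nrow(b) < 2L) next
      for (i in seq_len(nrow(b) - 1L)) {
        key <- sprintf("%d:%d", b[i, 2L], b[i + 1L, 1L])
        seen <- union(seen, key)
      }
    }
    for (key in seen) {
      tally[[key]] <- if (is.null(tally[[key]])) 1L else tally[[key]] + 1L
    }
  }
  keys <- ls(tally)
  if (length(keys) == 0L)
    return(data.frame(donor = integer(0), acceptor = integer(0), count = integer(0)))
  parts <- do.call(rbind, strsplit(keys, ":", fixed = TRUE))
  df <- data.frame(
    donor = as.integer(parts[, 1L]),
    acceptor = as.integer(parts[, 2L]),
    count = vapply(keys, function(k) tally[[k]], integer(1)),
    row.names = NULL
  )
  df <- df[df$count >= min_junction_reads, , drop = FALSE]
  df <- df[order(df$donor, df$acceptor), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Segment a locus into exon segments
#'
#' Cuts the locus at every retained donor and acceptor coordinate and keeps
#' maximal runs of non-zero base-level read coverage between cut points as
#' exon segments. Intronic positions with zero coverage produce no segment;
#' reads lying inside a retained intron keep it represented as a covered
#' segment (retained-intron signal).
#'
#' @param locus A locus from [cluster_loci()].
#' @param junctions Junction table from [collect_junctions()].
#' @return A data.frame with columns `start`, `end` (0-based half-open) and
#'   `cov` (mean base coverage of the segment), coordinate-sorted.
#' @export
segment_exons <- function(locus, junctions) {
  blocks <- do.call(rbind, unlist(lapply(locus$pairs, function(p) {
    lapply(Filter(Negate(is.null), list(p$left, p$right)), `[[`, "blocks")
  }), recursive = FALSE))
  if (is.null(blocks) || nrow(blocks) == 0L)
    return(data.frame(start = integer(0), end = integer(0), cov = numeric(0)))
  ir <- IRanges::IRanges(blocks[, 1L] + 1L, blocks[, 2L])  # 1-based
  cov <- IRanges::coverage(ir)
  runs <- IRanges::slice(cov, lower = 1L, rangesOnly = TRUE)
  cuts <- sort(unique(c(junctions$donor, junctions$acceptor)))
  segs <- NULL
  for (i in seq_along(runs)) {
    s <- IRanges::start(runs)[i] - 1L  # back to 0-based
    e <- IRanges::end(runs)[i]
    inner <- cuts[cuts > s & cuts < e]
    bounds <- c(s, inner, e)
    segs <- rbind(segs, cbind(bounds[-length(bounds)], bounds[-1L]))
  }
  mean_cov <- vapply(seq_len(nrow(segs)), function(i) {
    v <- IRanges::Views(cov, IRanges::IRanges(segs[i, 1L] + 1L, segs[i, 2L]))
    IRanges::viewMeans(v)
  }, numeric(1))
  data.frame(start = as.integer(segs[, 1L]), end = as.integer(segs[, 2L]),
             cov = mean_cov)
}

#' Build the weighted splicing graph of a locus
#'
#' Nodes are the exon segments; a junction edge joins the segment ending at
#' a retained intron's donor to the segment starting at its acceptor, with
#' weight equal to the junction's fragment support; an adjacency edge joins
#' two abutting segments when at least one alignment block crosses their
#' shared boundary, with weight equal to the number of crossing fragments.
#' The graph is acyclic by construction: every edge points from a node to a
#' strictly later-starting node, so coordinate order is a topological order.
#'
#' @param locus A locus from [cluster_loci()].
#' @param junctions Junction table from [collect_junctions()].
#' @param segments Segment table from [segment_exons()].
#' @return A `splicing_graph`: a list with `chrom`, `strand`, `nodes`
#'   (the segment data.frame) and `edges` (data.frame with `from`, `to`,
#'   `weight`, `kind` = `"junction"`/`"adjacency"`, `donor`, `acceptor`).
#' @export
build_splicing_graph <- function(locus, junctions, segments) {
  nodes <- segments[order(segments$start, segments$end), , drop = FALSE]
  rownames(nodes) <- NULL
  edges <- data.frame(from = integer(0), to = integer(0), weight = numeric(0),
                      kind = character(0), donor = integer(0), acceptor = integer(0))
  if (nrow(junctions) > 0L) {
    for (i in seq_len(nrow(junctions))) {
      d <- junctions$donor[i]; a <- junctions$acceptor[i]
      u <- which(nodes$end == d)
      v <- which(nodes$start == a)
      if (length(u) != 1L || length(v) != 1L) {
        warning(sprintf("junction %d-%d matches no segment boundary; dropped", d, a))
        next
      }
      edges <- rbind(edges, data.frame(
        from = u, to = v, weight = as.numeric(junctions$count[i]),
        kind = "junction", donor = d, acceptor = a
      ))
    }
  }
  # adjacency edges between abutting segments crossed by >= 1 fragment
  if (nrow(nodes) > 1L) {
    for (i in seq_len(nrow(nodes) - 1L)) {
      if (nodes$end[i] != nodes$start[i + 1L]) next
      b <- nodes$end[i]
      n_cross <- 0L
      for (p in locus$pairs) {
        crossed <- FALSE
        for (fr in list(p$left, p$right)) {
          if (is.null(fr)) next
          if (any(fr$blocks[, 1L] < b & fr$blocks[, 2L] > b)) crossed <- TRUE
        }
        if (crossed) n_cross <- n_cross + 1L
      }
      if (n_cross >= 1L) {
        edges <- rbind(edges, data.frame(
          from = i, to = i + 1L, weight = as.numeric(n_cross),
          kind = "adjacency", donor = NA_integer_, acceptor = NA_integer_
        ))
      }
    }
  }
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  stopifnot(all(edges$from < edges$to))
  g <- list(chrom = locus$chrom, strand = locus$strand,
            nodes = nodes, edges = edges)
  class(g) <- "splicing_graph"
  g
}

#' @export
print.splicing_graph <- function(x, ...) {
  cat(sprintf("splicing_graph %s:%d-%d(%s): %d nodes, %d edges (%d junctions)\n",
              x$chrom, min(x$nodes$start), max(x$nodes$end), x$strand,
              nrow(x$nodes), nrow(x$edges), sum(x$edges$kind == "junction")))
  invisible(x)
}

# Edge lookup key map: "from,to" -> edge row index.
#' @keywords internal
edge_index_map <- function(graph) {
  e <- graph$edges
  stats::setNames(seq_len(nrow(e)), paste(e$from, e$to, sep = ","))
}

#' Write exon segments and junctions of splicing graphs as BED text
#'
#' Debug dump: one BED line per exon segment and one per junction edge
#' (intron interval), score = weight/coverage.
#'
#' @param graphs List of `splicing_graph` objects.
#' @param con Connection or file path.
#' @export
dump_graphs_bed <- function(graphs, con) {
  lines <- character(0)
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    for (i in seq_len(nrow(g$nodes))) {
      lines <- c(lines, sprintf("%s\t%d\t%d\tg%d_seg%d\t%.1f\t%s",
                                g$chrom, g$nodes$start[i], g$nodes$end[i],
                                gi, i, g$nodes$cov[i], g$strand))
    }
    jn <- g$edges[g$edges$kind == "junction", , drop = FALSE]
    for (i in seq_len(nrow(jn))) {
      lines <- c(lines, sprintf("%s\t%d\t%d\tg%d_junc%d\t%.0f\t%s",
                                g$chrom, jn$donor[i], jn$acceptor[i],
                                gi, i, jn$weight[i], g$strand))
    }
  }
  writeLines(lines, con)
  invisible(lines)
}
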