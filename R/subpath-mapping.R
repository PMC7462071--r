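#' Build the junction hash index over all splicing graphs
#'
#' One entry per junction edge of every splicing graph; the key records the
#' junction's chromosome and intron coordinates, the value its graph and
#' edge indices. Adjacency edges are not indexed. Two graphs sharing a
#' junction key is an error (read loci must not share junctions).
#'
#' @param graphs List of `splicing_graph` objects.
#' @return A `junction_index`: environment mapping `"chrom:donor-acceptor"`
#'   to `c(graph, edge)`.
#' @export
build_junction_index <- function(graphs) {
  idx <- new.env(hash = TRUE, parent = emptyenv())
  for (gi in seq_along(graphs)) {
    e <- graphs[[gi]]$edges
    jn <- which(e$kind == "junction")
    for (ei in jn) {
      key <- sprintf("%s:%d-%d", graphs[[gi]]$chrom, e$donor[ei], e$acceptor[ei])
      if (!is.null(idx[[key]]))
        stop("duplicate junction key across graphs: ", key)
      idx[[key]] <- c(graph = gi, edge = ei)
    }
  }
  class(idx) <- c("junction_index", class(idx))
  idx
}

#' Locate a reliable assembly subpath on a splicing graph
#'
#' Looks up every splice junction of the subpath's exon chain in the
#' junction index. All junctions must hit the index and resolve to the same
#' splicing graph, and the induced edge sequence must form a connected path
#' there; intra-exon adjacency edges are filled in where a colored-graph
#' exon spans several splicing-graph segments. Terminal exon ends extend
#' along adjacency edges only through segments contained in the exon. The
#' assembler depth is carried over as the mapped subpath's score.
#'
#' @param entry An assembly `reliable_set` entry (with `exons` and `score`).
#' @param index A `junction_index`.
#' @param graphs The list of `splicing_graph`s the index was built from.
#' @return A list with `graph` (index into `graphs`) and the mapped entry
#'   (`nodes` in splicing-graph indices, `score`, `provenance`), or `NULL`
#'   if unmapped.
#' @export
map_assembly_subpath <- function(entry, index, graphs) {
  ex <- merge_abutting(entry$exons)  # consecutive rows now all spell introns
  nj <- nrow(ex) - 1L
  if (nj < 1L) return(NULL)  # no junction to anchor on
  hits <- matrix(NA_integer_, nrow = nj, ncol = 2L)
  for (j in seq_len(nj)) {
    key <- sprintf("%s:%d-%d", entry$chrom, ex[j, 2L], ex[j + 1L, 1L])
    v <- index[[key]]
    if (is.null(v)) return(NULL)
    hits[j, ] <- v
  }
  if (length(unique(hits[, 1L])) != 1L) {
    warning("assembly subpath junctions span two splicing graphs; unmapped")
    return(NULL)
  }
  gi <- hits[1L, 1L]
  g <- graphs[[gi]]
  emap <- edge_index_map(g)
  # walk: left tail within the first exon, adjacency runs between
  # consecutive junctions, right tail within the last exon
  path <- g$edges$from[hits[1L, 2L]]
  repeat {
    cur <- path[1L]
    prev <- which(g$nodes$end == g$nodes$start[cur])
    if (length(prev) != 1L || is.na(emap[paste(prev, cur, sep = ",")])) break
    if (g$nodes$start[prev] < ex[1L, 1L]) break
    path <- c(prev, path)
  }
  for (j in seq_len(nj)) {
    v <- g$edges$to[hits[j, 2L]]
    path <- c(path, v)
    if (j < nj) {
      target <- g$edges$from[hits[j + 1L, 2L]]
      cur <- v
      while (cur != target) {
        nxt <- which(g$nodes$start == g$nodes$end[cur])
        if (length(nxt) != 1L || is.na(emap[paste(cur, nxt, sep = ",")]))
          return(NULL)
        if (g$nodes$end[nxt] > ex[j + 1L, 2L]) return(NULL)
        path <- c(path, nxt)
        cur <- nxt
      }
    }
  }
  repeat {
    cur <- path[length(path)]
    nxt <- which(g$nodes$start == g$nodes$end[cur])
    if (length(nxt) != 1L || is.na(emap[paste(cur, nxt, sep = ",")])) break
    if (g$nodes$end[nxt] > ex[nrow(ex), 2L]) break
    path <- c(path, nxt)
  }
  list(graph = gi,
       entry = list(nodes = unname(path), score = entry$score,
                    provenance = "assembly"))
}

#' Match mono-exon assembly transcripts to single-node splicing graphs
#'
#' Single-exon transcripts carry no junction and cannot be hash-indexed;
#' they are matched to isolated splicing-graph segments by reciprocal
#' exonic overlap of at least `min_reciprocal`.
#'
#' @param entry An assembly entry with a one-row `exons` matrix.
#' @param graphs List of `splicing_graph`s.
#' @param min_reciprocal Reciprocal-overlap fraction (default 0.5).
#' @return As [map_assembly_subpath()], or `NULL`.
#' @export
map_mono_exon <- function(entry, graphs, min_reciprocal = 0.5) {
  ex <- entry$exons
  if (nrow(ex) != 1L) return(NULL)
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    if (g$chrom != entry$chrom) next
    iso <- setdiff(seq_len(nrow(g$nodes)), c(g$edges$from, g$edges$to))
    for (ni in iso) {
      ov <- min(g$nodes$end[ni], ex[1L, 2L]) - max(g$nodes$start[ni], ex[1L, 1L])
      if (ov <= 0) next
      if (ov / (ex[1L, 2L] - ex[1L, 1L]) >= min_reciprocal &&
          ov / (g$nodes$end[ni] - g$nodes$start[ni]) >= min_reciprocal)
        return(list(graph = gi,
                    entry = list(nodes = ni, score = entry$score,
                                 provenance = "assembly")))
    }
  }
  NULL
}

#' Merge read-derived and assembly-derived reliable subpaths
#'
#' Union keyed by node sequence over one splicing graph. A sequence present
#' in both sets keeps one copy with provenance `"merged"` and both scores
#' retained (`score` = the assembly depth, `score_read` = the read
#' coverage); the canonical reliable-set order is re-applied.
#'
#' @param paired Read-derived `reliable_set` of one graph.
#' @param assembly Assembly-derived `reliable_set` mapped onto the same
#'   graph.
#' @return The merged `reliable_set`.
#' @export
merge_reliable <- function(paired, assembly) {
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (e in assembly) seen[[path_key(e$nodes)]] <- e
  out <- list()
  for (e in paired) {
    key <- path_key(e$nodes)
    other <- seen[[key]]
    if (!is.null(other)) {
      other$provenance <- "merged"
      other$score_read <- e$score
      seen[[key]] <- other
    } else {
      out[[length(out) + 1L]] <- e
    }
  }
  for (key in ls(seen)) out[[length(out) + 1L]] <- seen[[key]]
  sort_reliable(out)
}
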