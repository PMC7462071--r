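#' Parse per-assembler transcript GTFs into colored transcripts
#'
#' Reads one GTF per upstream assembler and emits one colored transcript per
#' `transcript_id` per file, with exon coordinates converted to the internal
#' 0-based half-open convention and exon chains sorted by coordinate. The
#' "color" is the assembler label. Exon records without a `transcript_id`
#' are skipped with a warning; a file without exon features is an error.
#'
#' @param gtf_paths Character vector of at least two GTF paths.
#' @param colors Assembler labels, one per path (defaults to file base
#'   names).
#' @return List of colored transcripts: `color`, `transcript_id`, `chrom`,
#'   `strand`, `exons` (two-column 0-based half-open matrix, sorted).
#' @export
parse_assemblies <- function(gtf_paths, colors = NULL) {
  if (length(gtf_paths) < 2L)
    stop("at least two assembler GTFs are required")
  if (is.null(colors))
    colors <- sub("\\.gtf$", "", basename(gtf_paths), ignore.case = TRUE)
  stopifnot(length(colors) == length(gtf_paths))
  out <- list()
  for (fi in seq_along(gtf_paths)) {
    gr <- rtracklayer::import(gtf_paths[fi], format = "gtf")
    gr <- gr[!is.na(gr$type) & gr$type == "exon"]
    if (length(gr) == 0L)
      stop("no exon features in GTF: ", gtf_paths[fi])
    tid <- gr$transcript_id
    if (any(is.na(tid))) {
      warning(sum(is.na(tid)), " exon record(s) without transcript_id skipped in ",
              basename(gtf_paths[fi]))
      gr <- gr[!is.na(tid)]
      tid <- gr$transcript_id
    }
    for (id in unique(tid)) {
      ex <- gr[tid == id]
      ex <- ex[order(GenomicRanges::start(ex))]
      exons <- cbind(start = GenomicRanges::start(ex) - 1L,
                     end = GenomicRanges::end(ex))
      out[[length(out) + 1L]] <- list(
        color = colors[fi], transcript_id = id,
        chrom = as.character(GenomicRanges::seqnames(ex))[1L],
        strand = as.character(GenomicRanges::strand(ex))[1L],
        exons = exons
      )
    }
  }
  out
}

#' Cluster merged transcripts into gene loci
#'
#' Single-linkage clustering of the pooled transcripts from all assemblers:
#' two transcripts join one locus when any of their exons overlap on the
#' same chromosome and strand.
#'
#' @param transcripts Output of [parse_assemblies()].
#' @return List of clusters, each a list of colored transcripts.
#' @export
cluster_merged_transcripts <- function(transcripts) {
  if (length(transcripts) == 0L) return(list())
  n <- length(transcripts)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }
  key <- vapply(transcripts, function(t) paste(t$chrom, t$strand), character(1))
  for (grp in split(seq_len(n), key)) {
    if (length(grp) < 2L) next
    ex <- lapply(transcripts[grp], function(t)
      IRanges::IRanges(t$exons[, 1L] + 1L, t$exons[, 2L]))
    for (a in seq_len(length(grp) - 1L)) {
      for (b in (a + 1L):length(grp)) {
        if (length(IRanges::findOverlaps(ex[[a]], ex[[b]])) > 0L)
          unite(grp[a], grp[b])
      }
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  lapply(split(seq_len(n), roots), function(idx) transcripts[idx])
}

#' Build a colored graph from one locus of merged transcripts
#'
#' Exons with identical (start, end) collapse to one node; each transcript's
#' exon chain becomes its transcript-representing path (a genuine path in
#' the graph), and the edges are the consecutive-exon links over all paths.
#' With `boundary_slack > 0`, exon boundaries within `boundary_slack` bp of
#' each other are snapped to the most frequent coordinate of their group
#' before node identity is decided (ties to the smallest coordinate).
#'
#' @param transcripts List of colored transcripts of one locus.
#' @param boundary_slack Snap distance in bp (default 0: exact identity).
#' @return A `colored_graph`: list with `chrom`, `strand`, `nodes`
#'   (data.frame `start`, `end`), `edges` (data.frame `from`, `to`) and
#'   `paths` (list of `color`, `transcript_id`, `nodes`).
#' @export
build_colored_graph <- function(transcripts, boundary_slack = 0L) {
  stopifnot(length(transcripts) >= 1L)
  if (boundary_slack > 0L)
    transcripts <- snap_boundaries(transcripts, boundary_slack)
  all_ex <- do.call(rbind, lapply(transcripts, `[[`, "exons"))
  nodes <- unique(data.frame(start = all_ex[, 1L], end = all_ex[, 2L]))
  nodes <- nodes[order(nodes$start, nodes$end), , drop = FALSE]
  rownames(nodes) <- NULL
  nkey <- stats::setNames(seq_len(nrow(nodes)), paste(nodes$start, nodes$end))
  paths <- lapply(transcripts, function(t) {
    idx <- unname(nkey[paste(t$exons[, 1L], t$exons[, 2L])])
    list(color = t$color, transcript_id = t$transcript_id, nodes = idx)
  })
  epairs <- unique(do.call(rbind, lapply(paths, function(p) {
    if (length(p$nodes) < 2L) return(NULL)
    cbind(p$nodes[-length(p$nodes)], p$nodes[-1L])
  })))
  edges <- if (is.null(epairs)) data.frame(from = integer(0), to = integer(0)) else
    data.frame(from = epairs[, 1L], to = epairs[, 2L])
  edges <- edges[order(edges$from, edges$to), , drop = FALSE]
  rownames(edges) <- NULL
  g <- list(chrom = transcripts[[1L]]$chrom, strand = transcripts[[1L]]$strand,
            nodes = nodes, edges = edges, paths = paths)
  class(g) <- "colored_graph"
  g
}

# Majority-vote boundary snapping within `slack` bp.
#' @keywords internal
snap_boundaries <- function(transcripts, slack) {
  coords <- sort(unlist(lapply(transcripts, function(t) as.vector(t$exons))))
  tab <- table(coords)
  vals <- as.integer(names(tab))
  # group coordinates closer than `slack` to the previous one
  grp <- cumsum(c(TRUE, diff(vals) > slack))
  target <- vapply(split(seq_along(vals), grp), function(ix) {
    cnt <- as.integer(tab[ix])
    vals[ix][which.max(cnt)]  # which.max takes the first (smallest) on ties
  }, integer(1))
  remap <- stats::setNames(target[grp], vals)
  lapply(transcripts, function(t) {
    t$exons[] <- remap[as.character(t$exons)]
    t
  })
}

#' Extract reliable assembly subpaths from a colored graph
#'
#' Every contiguous length-k window of every transcript-representing path is
#' an assembly k-subpath; its depth is the number of DISTINCT assemblers
#' (colors) whose paths contain it — two transcripts of the same assembler
#' count once. Windows with depth at least `min_depth` (default 2) are
#' reliable; each length class is sorted by depth descending, ties
#' lexicographic.
#'
#' @param graph A `colored_graph`.
#' @param min_depth Reliability threshold on assembler depth (default 2).
#' @param min_k Smallest window length produced (default 2, as for paired
#'   subpaths).
#' @return A `reliable_set` of entries with `nodes` (colored-graph node
#'   indices), `exons` (genomic exon matrix of the window), `score` (depth)
#'   and `provenance = "assembly"`.
#' @export
extract_reliable_assembly_subpaths <- function(graph, min_depth = 2L,
                                               min_k = 2L) {
  colors_of <- new.env(hash = TRUE, parent = emptyenv())
  store <- new.env(hash = TRUE, parent = emptyenv())
  for (p in graph$paths) {
    n <- length(p$nodes)
    if (n < min_k) next
    for (k in min_k:n) {
      for (w in path_windows(p$nodes, k)) {
        key <- path_key(w)
        colors_of[[key]] <- union(colors_of[[key]], p$color)
        store[[key]] <- w
      }
    }
  }
  entries <- list()
  for (key in ls(colors_of)) {
    depth <- length(colors_of[[key]])
    if (depth >= min_depth) {
      w <- store[[key]]
      entries[[length(entries) + 1L]] <- list(
        nodes = w,
        exons = cbind(start = graph$nodes$start[w], end = graph$nodes$end[w]),
        chrom = graph$chrom, strand = graph$strand,
        score = as.numeric(depth), provenance = "assembly"
      )
    }
  }
  sort_reliable(entries)
}
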