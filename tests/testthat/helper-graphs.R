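# Shared constructors and independent oracles for the test suite.
# Splicing graphs here are built directly (not from reads) so graph-level
# operations can be tested in isolation.

# A splicing_graph from explicit node intervals and edges.
make_graph <- function(nodes, edges, chrom = "chrF", strand = "+") {
  nodes <- data.frame(start = nodes[, 1L], end = nodes[, 2L],
                      cov = if (ncol(nodes) > 2L) nodes[, 3L] else 10)
  if (is.null(edges) || nrow(edges) == 0L) {
    edges <- data.frame(from = integer(0), to = integer(0),
                        weight = numeric(0), kind = character(0),
                        donor = integer(0), acceptor = integer(0))
  } else {
    edges <- data.frame(from = edges$from, to = edges$to,
                        weight = edges$weight,
                        kind = if (!is.null(edges$kind)) edges$kind else
                          ifelse(nodes$end[edges$from] == nodes$start[edges$to],
                                 "adjacency", "junction"))
    edges$donor <- ifelse(edges$kind == "junction",
                          nodes$end[edges$from], NA_integer_)
    edges$acceptor <- ifelse(edges$kind == "junction",
                             nodes$start[edges$to], NA_integer_)
    edges <- edges[order(edges$from, edges$to), ]
    rownames(edges) <- NULL
  }
  g <- list(chrom = chrom, strand = strand, nodes = nodes, edges = edges)
  class(g) <- "splicing_graph"
  g
}

# Nodes laid on a line: node i = [1000*i, 1000*i + 400).
spaced_nodes <- function(n) cbind(1000L * seq_len(n), 1000L * seq_len(n) + 400L)

# The classic exon-skipping diamond: A->B->C plus A->C.
diamond_graph <- function(w_ab = 10, w_bc = 10, w_ac = 5) {
  make_graph(spaced_nodes(3L),
             data.frame(from = c(1L, 2L, 1L), to = c(2L, 3L, 3L),
                        weight = c(w_ab, w_bc, w_ac)))
}

# Random DAG shaped like a splicing graph: forward edges over spaced nodes,
# every non-first node has an in-edge and every non-last an out-edge (so
# the graph is connected enough to exercise extension).
random_graph <- function(seed, min_nodes = 4L, max_nodes = 9L) {
  set.seed(seed)
  n <- sample(min_nodes:max_nodes, 1L)
  from <- integer(0); to <- integer(0)
  for (v in 2L:n) {
    from <- c(from, sample.int(v - 1L, 1L)); to <- c(to, v)
  }
  extra <- sample(0:(n - 1L), 1L)
  for (k in seq_len(extra)) {
    u <- sample.int(n - 1L, 1L)
    v <- if (u + 1L == n) n else sample((u + 1L):n, 1L)
    if (!any(from == u & to == v)) { from <- c(from, u); to <- c(to, v) }
  }
  ed <- unique(data.frame(from = from, to = to))
  ed$weight <- sample(1:30, nrow(ed), replace = TRUE)
  make_graph(spaced_nodes(n), ed)
}

# Random genuine paths in g (random walks along edges), as a reliable_set.
random_reliable <- function(g, n_paths, seed, provenance = "read") {
  set.seed(seed)
  succ <- split(g$edges$to, factor(g$edges$from, levels = seq_len(nrow(g$nodes))))
  entries <- list()
  for (k in seq_len(n_paths)) {
    v <- sample.int(nrow(g$nodes), 1L)
    path <- v
    repeat {
      nxt <- succ[[path[length(path)]]]
      if (length(nxt) == 0L || runif(1) < 0.25) break
      path <- c(path, if (length(nxt) == 1L) nxt else sample(nxt, 1L))
    }
    if (length(path) >= 2L)
      entries[[length(entries) + 1L]] <- list(
        nodes = path, score = sample(2:9, 1L), provenance = provenance)
  }
  # dedupe by node sequence
  keys <- vapply(entries, function(e) paste(e$nodes, collapse = ","), character(1))
  isopath:::sort_reliable(entries[!duplicated(keys)])
}

# Locus construction from raw block matrices (0-based half-open).
make_frag <- function(blocks, qname = "q", strand = "+", mapq = 60L,
                      first = TRUE, chrom = "chrF") {
  list(qname = qname, chrom = chrom, strand = strand, mapq = mapq,
       first = first, blocks = blocks)
}

make_raw_pair <- function(left_blocks, right_blocks = NULL, qname = "q",
                          strand = "+", chrom = "chrF") {
  left <- make_frag(left_blocks, qname, strand, first = TRUE, chrom = chrom)
  right <- if (!is.null(right_blocks))
    make_frag(right_blocks, qname, strand, first = FALSE, chrom = chrom)
  span <- range(c(left_blocks, right_blocks))
  list(left = left, right = right, chrom = chrom, strand = strand,
       span = as.integer(span))
}

make_locus <- function(pairs, chrom = "chrF", strand = "+") {
  span <- range(unlist(lapply(pairs, `[[`, "span")))
  list(chrom = chrom, strand = strand, start = span[1L], end = span[2L],
       pairs = pairs)
}

# Write a minimal coordinate-sorted SAM file from (pos0, cigar, ...) specs.
write_test_sam <- function(records, path, chrom = "chrS", chrom_len = 100000L) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  body <- vapply(records, function(r) {
    rl <- sum(as.integer(
      regmatches(r$cigar, gregexpr("[0-9]+(?=[MIS=X])", r$cigar, perl = TRUE))[[1]]
    ))
    line <- sprintf("%s\t%d\t%s\t%d\t%d\t%s\t%s\t%d\t0\t%s\t*",
                    r$qname, r$flag, if (is.null(r$chrom)) chrom else r$chrom,
                    r$pos0 + 1L, if (is.null(r$mapq)) 60L else r$mapq,
                    r$cigar, if (is.null(r$rnext)) "=" else r$rnext,
                    if (is.null(r$pnext0)) r$pos0 + 1L else r$pnext0 + 1L,
                    strrep("A", rl))
    if (!is.null(r$xs)) line <- paste0(line, "\tXS:A:", r$xs)
    line
  }, character(1))
  writeLines(c(header, body), path)
  path
}

# Oracle: enumerate all simple paths u -> v with igraph.
igraph_paths <- function(g, from, to) {
  ig <- igraph::graph_from_data_frame(
    data.frame(from = as.character(g$edges$from), to = as.character(g$edges$to)),
    vertices = as.character(seq_len(nrow(g$nodes))), directed = TRUE)
  ps <- igraph::all_simple_paths(ig, as.character(from), as.character(to),
                                 mode = "out")
  ps <- lapply(ps, function(p) as.integer(names(p)))
  if (from == to) ps <- c(list(from), ps)
  ps
}

# Independent replay of the extension hierarchy: weight-1 successors (else
# all successors), then witness filtering with subpath lengths 2, 3, ...,
# then largest node weight, then smallest index. Written directly from the
# rule order, separate from the package's implementation.
oracle_step_right <- function(path, line, entries) {
  last <- path[length(path)]
  succ <- line$succ[[last]]
  if (length(succ) == 0L) return(NULL)
  has_w1 <- vapply(succ, function(s)
    any(line$edges$from == last & line$edges$to == s & line$edges$weight == 1),
    logical(1))
  cands <- if (any(has_w1)) succ[has_w1] else succ
  contains_window <- function(l, win) {
    n <- length(win)
    if (length(l) < n) return(FALSE)
    any(vapply(seq_len(length(l) - n + 1L), function(i)
      all(l[i:(i + n - 1L)] == win), logical(1)))
  }
  k <- 2L
  while (length(cands) > 1L && k <= length(path) + 1L) {
    suffix <- path[(length(path) - k + 2L):length(path)]
    sup <- cands[vapply(cands, function(cd)
      any(vapply(entries, function(e)
        contains_window(e$l_nodes, c(suffix, cd)), logical(1))), logical(1))]
    if (length(sup) == 0L) break
    cands <- sup
    k <- k + 1L
  }
  if (length(cands) > 1L) {
    mw <- max(line$node_weight[cands])
    cands <- sort(cands[line$node_weight[cands] == mw])
  }
  cands[1L]
}

# Parse GTF text lines back into per-transcript intron chains via
# rtracklayer (independent of the writer).
read_gtf_chains <- function(lines) {
  if (length(lines) == 0L)
    return(data.frame(tid = character(0), chain = character(0)))
  path <- tempfile(fileext = ".gtf")
  writeLines(lines, path)
  gr <- rtracklayer::import(path, format = "gtf")
  ex <- gr[gr$type == "exon"]
  chains <- vapply(split(ex, ex$transcript_id), function(t) {
    t <- sort(t)
    s <- GenomicRanges::start(t) - 1L
    e <- GenomicRanges::end(t)
    isopath:::intron_chain_string(cbind(s, e))
  }, character(1))
  data.frame(tid = names(chains), chain = unname(chains))
}
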