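# Line graphs come from helper splicing graphs; seeds and extension are
# checked against the independent hierarchy oracle in helper-graphs.R.

entries_for <- function(line, rel) isopath:::project_reliable(rel, line$graph)

test_that("seed selection is longest-first then falls back to the heaviest unused node", {
  g <- make_graph(spaced_nodes(5L),
                  data.frame(from = c(1L, 2L, 3L, 1L, 4L),
                             to = c(2L, 3L, 4L, 3L, 5L), weight = 5))
  line <- build_line_graph(g)
  rel <- isopath:::sort_reliable(list(
    list(nodes = c(1L, 2L, 3L, 4L), score = 2, provenance = "read"),
    list(nodes = c(1L, 3L, 4L), score = 9, provenance = "read")
  ))
  entries <- entries_for(line, rel)
  seed <- select_seed(entries, covered = c(FALSE, FALSE),
                      used = logical(line$n_nodes), line$node_weight)
  expect_identical(seed$type, "subpath")
  expect_length(seed$l_nodes, 3L)  # projection of the length-4 G-path

  # all subpaths covered: unused node with the largest weight
  line$node_weight <- c(5, 3, 8, 2, 6)
  seed2 <- select_seed(entries, covered = c(TRUE, TRUE),
                       used = c(FALSE, FALSE, TRUE, FALSE, FALSE),
                       line$node_weight)
  expect_identical(seed2$type, "node")
  expect_identical(seed2$l_nodes, which.max(c(5, 3, -Inf, 2, 6)))
  # everything used: done
  expect_null(select_seed(entries, c(TRUE, TRUE), rep(TRUE, 5L),
                          line$node_weight))

  # brute-force agreement of the subpath choice under the documented order
  open <- entries
  lens <- vapply(open, function(e) length(e$l_nodes), integer(1))
  best <- open[[order(-lens)[1L]]]
  expect_equal(seed$l_nodes, best$l_nodes)
})

test_that("assembly-derived seeds outrank read-derived seeds of equal length", {
  g <- make_graph(spaced_nodes(4L),
                  data.frame(from = c(1L, 2L, 1L, 3L), to = c(2L, 3L, 3L, 4L),
                             weight = 5))
  rel <- isopath:::sort_reliable(list(
    list(nodes = c(1L, 2L, 3L), score = 99, provenance = "read"),
    list(nodes = c(1L, 3L, 4L), score = 2, provenance = "assembly")
  ))
  line <- build_line_graph(g)
  entries <- entries_for(line, rel)
  seed <- select_seed(entries, logical(2L), logical(line$n_nodes),
                      line$node_weight)
  expect_identical(entries[[seed$index]]$provenance, "assembly")
})

test_that("extension follows the witness hierarchy", {
  # G: 1->2->3 with 3->4 and 3->5; reliable 2-subpath supports edge (2,3)->(3,5)
  g <- make_graph(spaced_nodes(5L),
                  data.frame(from = c(1L, 2L, 3L, 3L), to = c(2L, 3L, 4L, 5L),
                             weight = c(10, 10, 9, 2)))
  rel <- isopath:::sort_reliable(list(
    list(nodes = c(2L, 3L, 5L), score = 3, provenance = "read")
  ))
  line <- weight_line_graph(g, rel)
  entries <- entries_for(line, rel)
  witness <- isopath:::witness_table(entries)
  e12 <- project_subpath(c(1L, 2L), g)
  # without any witness both successors stay; largest node weight wins (3->4)
  path0 <- extend_right(e12, line, isopath:::witness_table(list()))
  expect_equal(line$origin$to[path0[length(path0)]], 4L)
  # the witnessed 2-subpath overrides the heavier neighbor
  path1 <- extend_right(e12, line, witness)
  expect_equal(line$origin$to[path1[length(path1)]], 5L)

  # a longer (3-subpath) witness beats a 2-subpath witness
  rel2 <- isopath:::sort_reliable(list(
    list(nodes = c(3L, 4L), score = 5, provenance = "read"),      # 2-subpath for (3,4)
    list(nodes = c(2L, 3L, 5L), score = 3, provenance = "read")   # 3-subpath for (3,5)
  ))
  line2 <- weight_line_graph(g, rel2)
  entries2 <- entries_for(line2, rel2)
  path2 <- extend_right(e12, line2, isopath:::witness_table(entries2))
  expect_equal(line2$origin$to[path2[length(path2)]], 5L)
})

test_that("left extension mirrors right extension", {
  g <- make_graph(spaced_nodes(5L),
                  data.frame(from = c(1L, 2L, 3L, 4L), to = c(3L, 3L, 4L, 5L),
                             weight = c(2, 10, 10, 10)))
  rel <- isopath:::sort_reliable(list(
    list(nodes = c(1L, 3L, 4L), score = 3, provenance = "read")
  ))
  line <- weight_line_graph(g, rel)
  entries <- entries_for(line, rel)
  e34 <- project_subpath(c(3L, 4L), g)
  # without witnesses the heavier predecessor (2->3) wins
  p0 <- extend_left(e34, line, isopath:::witness_table(list()))
  expect_equal(line$origin$from[p0[1L]], 2L)
  # the prefix witness routes through 1->3
  p1 <- extend_left(e34, line, isopath:::witness_table(entries))
  expect_equal(line$origin$from[p1[1L]], 1L)
})

test_that("extension choices equal the exhaustive hierarchy oracle on random fixtures", {
  n_checked <- 0L
  for (seed in 1:100) {
    g <- random_graph(seed, min_nodes = 5L, max_nodes = 9L)
    rel <- random_reliable(g, 4L, seed + 1000L)
    line <- weight_line_graph(g, rel)
    entries <- entries_for(line, rel)
    witness <- isopath:::witness_table(entries)
    set.seed(seed)
    for (rep in 1:3) {
      start <- sample.int(line$n_nodes, 1L)
      path <- start
      repeat {
        got <- isopath:::step_right(path, line, witness)
        want <- oracle_step_right(path, line, entries)
        expect_identical(got, want)
        if (is.null(got)) break
        n_checked <- n_checked + 1L
        path <- c(path, got)
      }
    }
  }
  expect_gt(n_checked, 200L)  # the loop exercised real branching decisions
})

test_that("committing a path subtracts c_min exactly once per node", {
  g <- make_graph(spaced_nodes(4L),
                  data.frame(from = 1:3, to = 2:4, weight = c(5, 3, 7)))
  line <- build_line_graph(g)
  res <- commit_path(c(1L, 2L, 3L), line)
  expect_equal(res$transcript$c_min, 3)
  expect_equal(res$line$node_weight, c(2, 0, 4))
  expect_equal(res$transcript$g_nodes, 1:4)
  # a second commit over shared nodes uses the updated weights
  res2 <- commit_path(c(1L, 2L), res$line)
  expect_equal(res2$transcript$c_min, 0)  # node 2 is exhausted
  expect_equal(res2$line$node_weight, c(2, 0, 4))
})

test_that("assembly covers every reliable subpath and every node", {
  # linear graph: one path covers everything
  g <- make_graph(spaced_nodes(4L),
                  data.frame(from = 1:3, to = 2:4, weight = 5))
  line <- weight_line_graph(g, list())
  paths <- assemble_graph(line, list())
  expect_length(paths, 1L)
  expect_equal(paths[[1L]]$g_nodes, 1:4)

  # diamond with both isoforms witnessed: exactly the two true chains
  g2 <- diamond_graph(10, 10, 5)
  rel2 <- isopath:::sort_reliable(list(
    list(nodes = c(1L, 2L, 3L), score = 8, provenance = "read"),
    list(nodes = c(1L, 3L), score = 4, provenance = "read")
  ))
  line2 <- weight_line_graph(g2, rel2)
  paths2 <- assemble_graph(line2, rel2)
  chains <- vapply(paths2, function(p) paste(p$g_nodes, collapse = ","),
                   character(1))
  expect_setequal(chains, c("1,2,3", "1,3"))

  # property over random weighted fixtures: full cover, monotone weights
  for (seed in 1:60) {
    g <- random_graph(seed)
    rel <- random_reliable(g, 4L, seed + 31L)
    line <- weight_line_graph(g, rel)
    w0 <- line$node_weight
    paths <- assemble_graph(line, rel)
    lpaths <- lapply(paths, `[[`, "l_nodes")
    for (e in isopath:::project_reliable(rel, g)) {
      expect_true(any(vapply(lpaths, function(p)
        isopath:::is_contiguous_subseq(e$l_nodes, p), logical(1))))
    }
    expect_setequal(unique(unlist(lpaths)), seq_len(line$n_nodes))
    # weights never increase and never go negative across commits
    w <- w0
    for (p in paths) {
      nodes <- unique(p$l_nodes)
      cm <- p$c_min
      expect_lte(cm, min(w[nodes]) + 1e-9)
      w[nodes] <- w[nodes] - cm
      expect_true(all(w >= -1e-9))
    }
  }
})

test_that("single-exon and isolated segments become mono-exon transcripts", {
  g <- make_graph(cbind(c(100L, 5000L, 6000L), c(400L, 5400L, 6400L), c(9, 3, 4)),
                  data.frame(from = 2L, to = 3L, weight = 6, kind = "junction"))
  paths <- assemble_splicing_graph(g, list())
  mono <- Filter(function(p) length(p$g_nodes) == 1L, paths)
  expect_length(mono, 1L)
  expect_equal(mono[[1L]]$g_nodes, 1L)
  expect_equal(mono[[1L]]$c_min, 9)  # mean base coverage of the segment
})

test_that("GTF emission filters on c_min, merges abutting segments and round-trips intron chains", {
  g <- make_graph(cbind(c(100L, 200L, 350L), c(200L, 350L, 500L)),
                  data.frame(from = c(1L, 2L), to = c(2L, 3L), weight = 5,
                             kind = "adjacency"),
                  chrom = "chrZ")
  paths <- list(list(l_nodes = c(1L, 2L), g_nodes = 1:3, c_min = 2.0),
                list(l_nodes = c(1L, 2L), g_nodes = 1:3, c_min = 0.4))
  gtf <- paths_to_gtf(paths, g, min_cov = 1.5, gene_id = "gX")
  expect_length(gtf, 2L)  # 1 transcript + 1 exon; the 0.4 path is dropped
  exon <- strsplit(gtf[2L], "\t")[[1L]]
  expect_equal(exon[3L], "exon")
  expect_equal(as.integer(exon[4L]), 101L)  # 1-based start
  expect_equal(as.integer(exon[5L]), 500L)  # abutting segments merged

  # round trip: emitted intron chain equals the path's junction sequence
  for (seed in 1:20) {
    gr <- random_graph(seed)
    rel <- random_reliable(gr, 3L, seed + 77L)
    line <- weight_line_graph(gr, rel)
    paths <- assemble_graph(line, rel)
    gtf <- paths_to_gtf(paths, gr, min_cov = 0, gene_id = "g")
    tx <- read_gtf_chains(gtf)
    for (p in paths) {
      segs <- cbind(gr$nodes$start[p$g_nodes], gr$nodes$end[p$g_nodes])
      expected <- isopath:::intron_chain_string(isopath:::merge_abutting(segs))
      expect_true(expected %in% c(tx$chain, if (expected == "") ""))
    }
  }
})
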