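# Graphs come from helper constructors; connect_pair is validated against
# an igraph-based exhaustive path enumeration oracle.

test_that("fragments map to node paths through junctions and adjacencies", {
  g <- make_graph(cbind(c(1000L, 1150L), c(1050L, 1200L)),
                  data.frame(from = 1L, to = 2L, weight = 3))
  expect_equal(fragment_to_node_path(cbind(c(1020L, 1150L), c(1050L, 1180L)), g),
               c(1L, 2L))
  # gap that is not a known junction
  expect_null(fragment_to_node_path(cbind(c(1020L, 1160L), c(1045L, 1180L)), g))
  # single block across two abutting segments joined by an adjacency edge
  g2 <- make_graph(cbind(c(100L, 200L), c(200L, 300L)),
                   data.frame(from = 1L, to = 2L, weight = 2, kind = "adjacency"))
  expect_equal(fragment_to_node_path(cbind(150L, 250L), g2), c(1L, 2L))
  # same block fails if the adjacency edge is absent
  g3 <- make_graph(cbind(c(100L, 200L), c(200L, 300L)), NULL)
  expect_null(fragment_to_node_path(cbind(150L, 250L), g3))
})

test_that("connect_pair applies the unique-connector and p+s+q rules", {
  # chain A->B->C: p1=[A,B], p2=[C]; unique connector, p+s+q = 3
  chain <- make_graph(spaced_nodes(3L),
                      data.frame(from = c(1L, 2L), to = c(2L, 3L), weight = 5))
  expect_equal(connect_pair(c(1L, 2L), 3L, chain), c(1L, 2L, 3L))
  # p1=[A], p2=[B]: p+s+q = 2 < 3
  expect_null(connect_pair(1L, 2L, chain))
  # diamond: two connectors A->B1->C / A->B2->C -> ambiguous
  dia <- make_graph(spaced_nodes(4L),
                    data.frame(from = c(1L, 1L, 2L, 3L), to = c(2L, 3L, 4L, 4L),
                               weight = 5))
  expect_null(connect_pair(1L, 4L, dia))
  # overlapping mates: shared node, p+q >= 3
  expect_equal(connect_pair(c(1L, 2L), c(2L, 4L), dia), c(1L, 2L, 4L))
  # single shared node with p+q = 2 is too short
  expect_null(connect_pair(2L, 2L, dia))
  # inconsistent overlap warns and drops
  expect_warning(res <- connect_pair(c(1L, 2L, 4L), c(3L, 4L), dia),
                 "inconsistent|disagree")
  expect_null(res)
})

test_that("connect_pair agrees with exhaustive enumeration on random graphs", {
  skip_if_not_installed("igraph")
  for (seed in 1:25) {
    g <- random_graph(seed, min_nodes = 5L, max_nodes = 12L)
    set.seed(seed + 500L)
    for (rep in 1:8) {
      u <- sample.int(nrow(g$nodes), 1L)
      v <- u + sample.int(nrow(g$nodes) - u + 1L, 1L) - 1L
      p1 <- u; p2 <- v
      got <- connect_pair(p1, p2, g)
      conns <- Filter(function(p) length(p) >= 0, igraph_paths(g, u, v))
      if (u == v) {
        expected <- NULL  # p + q = 2 < 3
      } else if (length(conns) == 1L) {
        s <- length(conns[[1L]]) - 2L
        expected <- if (1L + s + 1L >= 3L) conns[[1L]] else NULL
      } else {
        expected <- NULL
      }
      expect_equal(got, expected,
                   info = sprintf("seed %d u=%d v=%d", seed, u, v))
    }
  }
})

test_that("identical paired subpaths aggregate their coverage", {
  chain <- make_graph(spaced_nodes(3L),
                      data.frame(from = c(1L, 2L), to = c(2L, 3L), weight = 5))
  mk <- function(q) make_raw_pair(
    cbind(c(1000L, 2000L), c(1400L, 2100L)),  # p1 = [1,2]
    cbind(3000L, 3200L),                      # p2 = [3]
    qname = q
  )
  sp <- collect_paired_subpaths(lapply(paste0("q", 1:4), mk), chain)
  expect_length(sp, 1L)
  expect_equal(sp[[1L]]$nodes, c(1L, 2L, 3L))
  expect_equal(sp[[1L]]$coverage, 4L)
  expect_length(collect_paired_subpaths(list(), chain), 0L)
})

test_that("the canonical 4-path decomposes into exactly two 3-subpaths", {
  sp <- list(list(nodes = 1:4, coverage = 2L))
  rel <- decompose_reliable(sp, min_score = 2L, min_k = 3L)
  got <- lapply(rel, `[[`, "nodes")
  expect_length(got, 3L)  # the two 3-windows plus the full path
  threes <- got[vapply(got, length, integer(1)) == 3L]
  expect_setequal(vapply(threes, paste, character(1), collapse = ","),
                  c("1,2,3", "2,3,4"))
})

test_that("window coverage sums and the reliability threshold match a brute-force tally", {
  sp <- list(list(nodes = c(1L, 2L, 3L), coverage = 1L),
             list(nodes = c(1L, 2L, 3L, 4L), coverage = 1L))
  rel <- decompose_reliable(sp, min_score = 2L, min_k = 3L)
  keys <- vapply(rel, function(e) paste(e$nodes, collapse = ","), character(1))
  expect_identical(keys, "1,2,3")  # coverage 1 + 1 = 2; all others below 2
  expect_equal(rel[[1L]]$score, 2)

  # single low-coverage subpath yields nothing
  expect_length(decompose_reliable(list(list(nodes = 1:3, coverage = 1L))), 0L)

  # randomized agreement with an independent window tally
  set.seed(7)
  for (rep in 1:10) {
    sps <- lapply(1:6, function(i) {
      len <- sample(2:6, 1L)
      start <- sample(1:3, 1L)
      list(nodes = start:(start + len - 1L), coverage = sample(1:4, 1L))
    })
    rel <- decompose_reliable(sps, min_score = 2L, min_k = 2L)
    oracle <- new.env()
    for (s in sps) {
      n <- length(s$nodes)
      for (k in 2:n) for (i in seq_len(n - k + 1L)) {
        key <- paste(s$nodes[i:(i + k - 1L)], collapse = ",")
        oracle[[key]] <- (if (is.null(oracle[[key]])) 0L else oracle[[key]]) +
          s$coverage
      }
    }
    exp_keys <- Filter(function(k) oracle[[k]] >= 2L, ls(oracle))
    got_keys <- vapply(rel, function(e) paste(e$nodes, collapse = ","), character(1))
    expect_setequal(got_keys, exp_keys)
    for (e in rel)
      expect_equal(e$score, oracle[[paste(e$nodes, collapse = ",")]])
  }
})

test_that("window counts and coverage monotonicity hold", {
  # a length-n path yields n-k+1 k-windows
  for (n in 3:8) {
    for (k in 2:n) {
      expect_length(isopath:::path_windows(seq_len(n), k), n - k + 1L)
    }
  }
  # coverage of a k-subpath >= coverage of any (k+1)-subpath containing it
  set.seed(11)
  sps <- lapply(1:8, function(i) {
    len <- sample(3:7, 1L)
    list(nodes = seq(sample(1:4, 1L), length.out = len), coverage = sample(1:5, 1L))
  })
  rel <- decompose_reliable(sps, min_score = 1L, min_k = 2L)
  scores <- new.env()
  for (e in rel) scores[[paste(e$nodes, collapse = ",")]] <- e$score
  for (e in rel) {
    n <- length(e$nodes)
    if (n < 3L) next
    for (w in isopath:::path_windows(e$nodes, n - 1L)) {
      sub <- scores[[paste(w, collapse = ",")]]
      expect_gte(sub, e$score)
    }
  }
})

test_that("sorting within a length class is by score then lexicographic order", {
  sps <- list(list(nodes = c(2L, 3L), coverage = 5L),
              list(nodes = c(1L, 2L), coverage = 5L),
              list(nodes = c(3L, 4L), coverage = 9L))
  rel <- decompose_reliable(sps, min_score = 2L, min_k = 2L)
  expect_equal(lapply(rel, `[[`, "nodes"),
               list(c(3L, 4L), c(1L, 2L), c(2L, 3L)))
})
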