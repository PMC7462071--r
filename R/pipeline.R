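#' Assemble transcripts from alignments plus upstream assemblies
#'
#' End-to-end pipeline: reads coordinate-sorted spliced paired-end
#' alignments, clusters them into loci and builds a weighted splicing graph
#' per locus; extracts reliable paired subpaths from the read pairs;
#' merges the transcript sets of the upstream assemblers into per-locus
#' colored graphs and extracts reliable assembly subpaths (assembler depth
#' at least 2); maps those onto the splicing graphs through the junction
#' index and merges them with the paired subpaths; then recovers
#' transcripts as a path cover of each weighted line graph by seeded path
#' extension, and applies the post-assembly expression filter `min_cov`.
#'
#' @param bam Coordinate-sorted SAM/BAM path.
#' @param assemblies Character vector of at least two assembler GTF paths.
#' @param colors Assembler labels (default: file base names).
#' @param out Optional output GTF path.
#' @param min_mapq,max_gap,fasta See [load_alignments()] and
#'   [cluster_loci()].
#' @param min_junction_reads See [collect_junctions()].
#' @param min_score Paired-subpath reliability threshold (default 2).
#' @param min_depth Assembly-subpath reliability threshold (default 2).
#' @param boundary_slack See [build_colored_graph()].
#' @param eps_support,theta See [weight_line_graph()].
#' @param min_cov Post-assembly expression filter on `c_min` (default 1.5).
#' @param strict_binary See [extend_right()].
#' @param verbose Print per-locus counters.
#' @return List with `transcripts` (data.frame: gene_id, transcript_id,
#'   chrom, strand, start, end, n_exons, intron_chain, cov), `gtf`
#'   (character lines, also written to `out` if given) and `stats`
#'   (counters: loci, graphs, subpath and mapping tallies).
#' @export
assemble_transcripts <- function(bam, assemblies, colors = NULL, out = NULL,
                                 min_mapq = 1L, max_gap = 50L, fasta = NULL,
                                 min_junction_reads = 1L, min_score = 2L,
                                 min_depth = 2L, boundary_slack = 0L,
                                 eps_support = 0.05, theta = 0.1,
                                 min_cov = 1.5, strict_binary = FALSE,
                                 verbose = FALSE) {
  frags <- load_alignments(bam, min_mapq = min_mapq, fasta = fasta)
  pairs <- pair_mates(frags)
  loci <- cluster_loci(pairs, max_gap = max_gap)

  graphs <- list()
  paired_sets <- list()
  stats <- list(fragments = length(frags), pairs = length(pairs),
                loci = length(loci), graphs = 0L,
                paired_subpaths = 0L, assembly_subpaths = 0L,
                assembly_mapped = 0L, assembly_unmapped = 0L,
                transcripts = 0L, filtered = 0L)
  for (locus in loci) {
    jn <- collect_junctions(locus, min_junction_reads)
    segs <- segment_exons(locus, jn)
    if (nrow(segs) == 0L) next
    g <- build_splicing_graph(locus, jn, segs)
    graphs[[length(graphs) + 1L]] <- g
    sp <- collect_paired_subpaths(locus$pairs, g)
    paired_sets[[length(graphs)]] <- decompose_reliable(sp, min_score)
    stats$paired_subpaths <- stats$paired_subpaths + length(paired_sets[[length(graphs)]])
  }
  stats$graphs <- length(graphs)

  transcripts <- parse_assemblies(assemblies, colors)
  clusters <- cluster_merged_transcripts(transcripts)
  index <- build_junction_index(graphs)
  assembly_sets <- rep(list(list()), length(graphs))
  for (cl in clusters) {
    cg <- build_colored_graph(cl, boundary_slack)
    rel <- extract_reliable_assembly_subpaths(cg, min_depth)
    stats$assembly_subpaths <- stats$assembly_subpaths + length(rel)
    for (entry in rel) {
      m <- map_assembly_subpath(entry, index, graphs)
      if (is.null(m)) {
        stats$assembly_unmapped <- stats$assembly_unmapped + 1L
      } else {
        stats$assembly_mapped <- stats$assembly_mapped + 1L
        assembly_sets[[m$graph]] <- c(assembly_sets[[m$graph]], list(m$entry))
      }
    }
    # mono-exon transcripts reported by >= min_depth assemblers
    mono <- Filter(function(p) length(p$nodes) == 1L, cg$paths)
    if (length(mono)) {
      keys <- vapply(mono, function(p) path_key(p$nodes), character(1))
      for (key in unique(keys)) {
        grp <- mono[keys == key]
        depth <- length(unique(vapply(grp, `[[`, character(1), "color")))
        if (depth < min_depth) next
        ni <- grp[[1L]]$nodes
        m <- map_mono_exon(
          list(exons = cbind(cg$nodes$start[ni], cg$nodes$end[ni]),
               chrom = cg$chrom, score = depth),
          graphs)
        if (!is.null(m))
          assembly_sets[[m$graph]] <- c(assembly_sets[[m$graph]],
                                        list(m$entry))
      }
    }
  }

  all_rows <- NULL
  gtf <- character(0)
  for (gi in seq_along(graphs)) {
    g <- graphs[[gi]]
    merged <- merge_reliable(paired_sets[[gi]], sort_reliable(assembly_sets[[gi]]))
    paths <- assemble_splicing_graph(g, merged, eps_support, theta,
                                     strict_binary)
    gene_id <- sprintf("ISOPATH.%d", gi)
    kept <- Filter(function(p) p$c_min >= min_cov, paths)
    stats$filtered <- stats$filtered + (length(paths) - length(kept))
    stats$transcripts <- stats$transcripts + length(kept)
    gtf <- c(gtf, paths_to_gtf(paths, g, min_cov, gene_id))
    ti <- 0L
    for (p in kept) {
      ti <- ti + 1L
      exons <- merge_abutting(cbind(g$nodes$start[p$g_nodes],
                                    g$nodes$end[p$g_nodes]))
      all_rows <- rbind(all_rows, data.frame(
        gene_id = gene_id, transcript_id = sprintf("%s.%d", gene_id, ti),
        chrom = g$chrom, strand = g$strand,
        start = min(exons[, 1L]), end = max(exons[, 2L]),
        n_exons = nrow(exons), intron_chain = intron_chain_string(exons),
        cov = p$c_min
      ))
    }
    if (verbose)
      message(sprintf("%s: %d nodes, %d edges, %d reliable, %d transcripts",
                      gene_id, nrow(g$nodes), nrow(g$edges), length(merged),
                      length(kept)))
  }
  if (is.null(all_rows))
    all_rows <- data.frame(gene_id = character(0), transcript_id = character(0),
                           chrom = character(0), strand = character(0),
                           start = integer(0), end = integer(0),
                           n_exons = integer(0), intron_chain = character(0),
                           cov = numeric(0))
  if (!is.null(out)) writeLines(gtf, out)
  list(transcripts = all_rows, gtf = gtf, stats = stats, graphs = graphs)
}

#' Score an assembly against a truth table by intron-chain matching
#'
#' A truth transcript is correctly detected when an assembled transcript on
#' the same chromosome has exactly its intron chain (the standard
#' correctness criterion); a gene is detected when at least one of its
#' isoforms is. Mono-exon entries match by identical chromosome and
#' >= 50% reciprocal span overlap.
#'
#' @param predicted `transcripts` data.frame from [assemble_transcripts()].
#' @param truth Truth data.frame with `chrom`, `intron_chain`, `transcript`,
#'   `gene` columns (as written by [generate_alignments()]).
#' @return List with `recall`, `precision`, `gene_recall`,
#'   `gene_precision` (fractions), and the matched counts.
#' @export
score_assembly <- function(predicted, truth) {
  tkey <- paste(truth$chrom, truth$intron_chain)
  pkey <- paste(predicted$chrom, predicted$intron_chain)
  multi_t <- truth$intron_chain != ""
  multi_p <- predicted$intron_chain != ""
  t_matched <- tkey %in% pkey
  p_matched <- pkey %in% tkey
  # mono-exon: reciprocal span overlap
  if (any(!multi_t) && any(!multi_p)) {
    for (i in which(!multi_t)) {
      for (j in which(!multi_p)) {
        if (truth$chrom[i] != predicted$chrom[j]) next
        ov <- min(truth$end[i], predicted$end[j]) -
          max(truth$start[i], predicted$start[j])
        if (ov > 0 &&
            ov / (truth$end[i] - truth$start[i]) >= 0.5 &&
            ov / (predicted$end[j] - predicted$start[j]) >= 0.5) {
          t_matched[i] <- TRUE; p_matched[j] <- TRUE
        }
      }
    }
  }
  genes_detected <- unique(truth$gene[t_matched])
  pred_genes <- unique(predicted$gene_id)
  pred_genes_ok <- unique(predicted$gene_id[p_matched])
  list(
    recall = mean(t_matched),
    precision = if (nrow(predicted)) mean(p_matched) else NA_real_,
    gene_recall = length(genes_detected) / length(unique(truth$gene)),
    gene_precision = if (length(pred_genes))
      length(pred_genes_ok) / length(pred_genes) else NA_real_,
    n_truth = nrow(truth), n_predicted = nrow(predicted),
    n_matched_truth = sum(t_matched), n_matched_predicted = sum(p_matched)
  )
}
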