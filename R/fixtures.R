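# Deterministic synthetic-data generator: toy multi-isoform genes, spliced
# paired-end reads in SAM, and mock per-assembler GTFs with controlled
# error modes (missed transcripts, spurious recombined chains, boundary
# jitter). Emulates the shape of data the assembler sees in practice —
# several isoforms per locus sharing exons, uneven abundances, paired-end
# fragments spelling introns — without base-level sequencing error.

#' Default toy gene set
#'
#' Three multi-isoform genes whose isoforms are pairwise distinguishable by
#' paired-end fragments: an exon-skipping gene (2 isoforms), a gene with
#' both a skipped exon and an alternative last exon (3 isoforms), and a
#' minus-strand mutually-exclusive-exon gene (2 isoforms). Exon coordinates
#' are 0-based half-open; abundances are fragment counts per isoform.
#'
#' @return List of gene descriptions (`chrom`, `strand`, `exons`,
#'   `isoforms`, `abundance`).
#' @export
toy_genes <- function() {
  list(
    list(
      chrom = "chrT", strand = "+",
      exons = list(c(1000L, 1400L), c(2000L, 2250L), c(3000L, 3500L)),
      isoforms = list(c(1L, 2L, 3L), c(1L, 3L)),
      abundance = c(60L, 40L)
    ),
    list(
      chrom = "chrT", strand = "+",
      exons = list(c(10000L, 10500L), c(11000L, 11300L), c(12000L, 12400L),
                   c(13000L, 13600L), c(14000L, 14450L)),
      isoforms = list(c(1L, 2L, 3L, 4L), c(1L, 3L, 4L), c(1L, 2L, 3L, 5L)),
      abundance = c(50L, 35L, 45L)
    ),
    list(
      chrom = "chrU", strand = "-",
      exons = list(c(5000L, 5450L), c(6000L, 6350L), c(7000L, 7300L),
                   c(8000L, 8500L)),
      isoforms = list(c(1L, 2L, 4L), c(1L, 3L, 4L)),
      abundance = c(55L, 40L)
    )
  )
}

#' Describe a synthetic data set
#'
#' Bundles the study conditions of the generator: the gene models, the read
#' and fragment geometry, and the per-assembler error profiles. Defaults
#' are 150 bp reads (fragment mean 300 bp, sd 25) and three concordant
#' assembler profiles (every true isoform reported, no spurious chains, no
#' boundary jitter); the error rates are the dials for the degraded
#' scenarios exercised in tests.
#'
#' @param seed Integer seed; the single source of randomness.
#' @param genes Gene list as in [toy_genes()]; all abundances must be > 0.
#' @param read_length,frag_mean,frag_sd Read/fragment geometry in bp.
#' @param assembler_profiles List of profiles: `name`, `tp_rate` (chance a
#'   true isoform is reported), `false_rate` (expected spurious recombined
#'   chains per gene), `jitter` (max internal-boundary shift, bp).
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, genes = toy_genes(), read_length = 150L,
                         frag_mean = 300L, frag_sd = 25L,
                         assembler_profiles = list(
                           list(name = "asmA", tp_rate = 1, false_rate = 0, jitter = 0L),
                           list(name = "asmB", tp_rate = 1, false_rate = 0, jitter = 0L),
                           list(name = "asmC", tp_rate = 1, false_rate = 0, jitter = 0L)
                         )) {
  for (g in genes) {
    stopifnot(all(g$abundance > 0))
    for (iso in g$isoforms) {
      ex <- do.call(rbind, g$exons[iso])
      stopifnot(all(diff(ex[, 1L]) > 0), all(ex[, 2L] > ex[, 1L]))
    }
  }
  spec <- list(seed = as.integer(seed), genes = genes,
               read_length = as.integer(read_length),
               frag_mean = as.integer(frag_mean), frag_sd = as.integer(frag_sd),
               assembler_profiles = assembler_profiles)
  class(spec) <- "fixture_spec"
  spec
}

# Exon matrix (0-based half-open) of one isoform.
#' @keywords internal
isoform_exons <- function(gene, iso) {
  do.call(rbind, gene$exons[gene$isoforms[[iso]]])
}

# Transcript-coordinate interval [s, e) -> genomic blocks over exon chain.
#' @keywords internal
tx_to_blocks <- function(exons, s, e) {
  lens <- exons[, 2L] - exons[, 1L]
  offs <- cumsum(c(0L, lens))
  blocks <- NULL
  for (i in seq_len(nrow(exons))) {
    a <- max(s, offs[i]); b <- min(e, offs[i + 1L])
    if (a < b) {
      blocks <- rbind(blocks, c(exons[i, 1L] + (a - offs[i]),
                                exons[i, 1L] + (b - offs[i])))
    }
  }
  blocks
}

#' @keywords internal
blocks_to_cigar <- function(blocks) {
  parts <- character(0)
  for (i in seq_len(nrow(blocks))) {
    if (i > 1L)
      parts <- c(parts, sprintf("%dN", blocks[i, 1L] - blocks[i - 1L, 2L]))
    parts <- c(parts, sprintf("%dM", blocks[i, 2L] - blocks[i, 1L]))
  }
  paste(parts, collapse = "")
}

#' Generate synthetic spliced paired-end alignments
#'
#' Samples paired-end fragments per isoform (count = its abundance),
#' fragment lengths normal around `frag_mean` truncated to
#' [read_length, isoform length], start positions uniform; mates of
#' `read_length` bp each are placed at the fragment ends and mapped to
#' genomic blocks, so their CIGARs spell the true introns through N
#' operations. Records are emitted coordinate-sorted with `XS` strand tags
#' on spliced reads. Isoforms shorter than the read length are skipped with
#' a warning. Output is byte-identical for a fixed spec.
#'
#' @param spec A `fixture_spec`.
#' @param dir Output directory (created if needed).
#' @return List with `sam` (path), `truth` (path to a TSV listing gene,
#'   transcript, chrom, strand, intron chain and fragment count) and
#'   `truth_df` (the same as a data.frame).
#' @export
generate_alignments <- function(spec, dir = tempfile("fixture")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed)

  rl <- spec$read_length
  recs <- list()   # (chrom, pos0, qname, flag, cigar, mpos0, tlen, xs, len)
  truth <- NULL
  fid <- 0L
  for (gi in seq_along(spec$genes)) {
    gene <- spec$genes[[gi]]
    for (ii in seq_along(gene$isoforms)) {
      exons <- isoform_exons(gene, ii)
      iso_len <- sum(exons[, 2L] - exons[, 1L])
      n <- gene$abundance[ii]
      if (iso_len < rl) {
        warning(sprintf("isoform g%d.i%d shorter than read length; skipped", gi, ii))
        next
      }
      truth <- rbind(truth, data.frame(
        gene = sprintf("g%d", gi), transcript = sprintf("g%d.i%d", gi, ii),
        chrom = gene$chrom, strand = gene$strand,
        start = min(exons[, 1L]), end = max(exons[, 2L]),
        intron_chain = intron_chain_string(exons), n_fragments = n
      ))
      for (f in seq_len(n)) {
        fid <- fid + 1L
        flen <- round(stats::rnorm(1L, spec$frag_mean, spec$frag_sd))
        flen <- max(rl, min(iso_len, flen))
        s <- if (iso_len == flen) 0L else
          sample.int(iso_len - flen + 1L, 1L) - 1L
        b1 <- tx_to_blocks(exons, s, s + rl)
        b2 <- tx_to_blocks(exons, s + flen - rl, s + flen)
        qname <- sprintf("frag%06d", fid)
        xs <- gene$strand
        spliced1 <- nrow(b1) > 1L; spliced2 <- nrow(b2) > 1L
        tlen <- max(b2[, 2L]) - min(b1[, 1L])
        recs[[length(recs) + 1L]] <- list(
          chrom = gene$chrom, pos = b1[1L, 1L], qname = qname,
          flag = 99L, cigar = blocks_to_cigar(b1), mpos = b2[1L, 1L],
          tlen = tlen, xs = if (spliced1) xs else NA_character_
        )
        recs[[length(recs) + 1L]] <- list(
          chrom = gene$chrom, pos = b2[1L, 1L], qname = qname,
          flag = 147L, cigar = blocks_to_cigar(b2), mpos = b1[1L, 1L],
          tlen = -tlen, xs = if (spliced2) xs else NA_character_
        )
      }
    }
  }
  chrom_len <- stats::aggregate(
    end ~ chrom,
    data.frame(chrom = vapply(spec$genes, `[[`, character(1), "chrom"),
               end = vapply(spec$genes, function(g)
                 max(vapply(g$exons, max, integer(1))), integer(1))),
    max
  )
  chroms <- sort(chrom_len$chrom)
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", chroms,
                      chrom_len$end[match(chroms, chrom_len$chrom)] + 1000L))
  ord <- order(vapply(recs, `[[`, character(1), "chrom"),
               vapply(recs, function(r) r$pos, numeric(1)),
               vapply(recs, `[[`, character(1), "qname"))
  body <- vapply(recs[ord], function(r) {
    seq <- strrep("A", rl)
    line <- sprintf("%s\t%d\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t*",
                    r$qname, r$flag, r$chrom, r$pos + 1L, r$cigar,
                    r$mpos + 1L, r$tlen, seq)
    if (!is.na(r$xs)) line <- paste0(line, "\tXS:A:", r$xs)
    line
  }, character(1))
  sam <- file.path(dir, "reads.sam")
  writeLines(c(header, body), sam)
  truth_path <- file.path(dir, "truth.tsv")
  utils::write.table(truth, truth_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  list(sam = sam, truth = truth_path, truth_df = truth)
}

#' Generate mock per-assembler transcript GTFs
#'
#' Each assembler profile reports every true isoform with probability
#' `tp_rate`, adds spurious chains (a recombination of two isoforms of the
#' same gene at a shared exon, or a one-exon-dropped variant) at an
#' expected `false_rate` per gene, and shifts internal exon boundaries by
#' up to `jitter` bp. Truth labels are written so depth-based reliability
#' is checkable: shared truths appear in concordant files, while
#' independent errors essentially never coincide.
#'
#' @param spec A `fixture_spec` (needs at least two assembler profiles).
#' @param dir Output directory.
#' @return List with `gtfs` (paths, one per profile), `colors` (profile
#'   names) and `labels` (data.frame: color, transcript_id, true).
#' @export
generate_assembler_gtfs <- function(spec, dir = tempfile("fixture")) {
  stopifnot(length(spec$assembler_profiles) >= 2L)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv))
  set.seed(spec$seed + 1000003L)

  gtfs <- character(0); colors <- character(0); labels <- NULL
  for (prof in spec$assembler_profiles) {
    lines <- character(0)
    for (gi in seq_along(spec$genes)) {
      gene <- spec$genes[[gi]]
      for (ii in seq_along(gene$isoforms)) {
        if (stats::runif(1L) > prof$tp_rate) next
        exons <- jitter_exons(isoform_exons(gene, ii), prof$jitter)
        tid <- sprintf("%s.g%d.i%d", prof$name, gi, ii)
        lines <- c(lines, exon_gtf_lines(gene, exons, gi, tid, prof$name))
        labels <- rbind(labels, data.frame(color = prof$name,
                                           transcript_id = tid, true = TRUE))
      }
      n_false <- stats::rpois(1L, prof$false_rate)
      for (k in seq_len(n_false)) {
        exons <- spurious_chain(gene)
        if (is.null(exons)) next
        exons <- jitter_exons(exons, prof$jitter)
        tid <- sprintf("%s.g%d.f%d", prof$name, gi, k)
        lines <- c(lines, exon_gtf_lines(gene, exons, gi, tid, prof$name))
        labels <- rbind(labels, data.frame(color = prof$name,
                                           transcript_id = tid, true = FALSE))
      }
    }
    path <- file.path(dir, paste0(prof$name, ".gtf"))
    writeLines(lines, path)
    gtfs <- c(gtfs, path); colors <- c(colors, prof$name)
  }
  list(gtfs = gtfs, colors = colors, labels = labels)
}

#' @keywords internal
exon_gtf_lines <- function(gene, exons, gi, tid, source) {
  vapply(seq_len(nrow(exons)), function(i) {
    sprintf('%s\t%s\texon\t%d\t%d\t.\t%s\t.\tgene_id "g%d"; transcript_id "%s";',
            gene$chrom, source, exons[i, 1L] + 1L, exons[i, 2L],
            gene$strand, gi, tid)
  }, character(1))
}

# A spurious chain: recombine two isoforms of the gene at a shared exon, or
# drop one internal exon; NULL when the gene offers no such variant.
#' @keywords internal
spurious_chain <- function(gene) {
  isos <- gene$isoforms
  cands <- list()
  if (length(isos) >= 2L) {
    for (a in seq_along(isos)) for (b in seq_along(isos)) {
      if (a == b) next
      shared <- intersect(isos[[a]], isos[[b]])
      for (x in shared) {
        ia <- match(x, isos[[a]]); ib <- match(x, isos[[b]])
        chain <- c(isos[[a]][seq_len(ia)], isos[[b]][-seq_len(ib)])
        if (!any(vapply(isos, identical, logical(1), chain)) &&
            all(diff(chain) > 0)) {
          cands[[length(cands) + 1L]] <- chain
        }
      }
    }
  }
  for (a in seq_along(isos)) {
    iso <- isos[[a]]
    if (length(iso) >= 3L) {
      for (drop_i in 2L:(length(iso) - 1L)) {
        chain <- iso[-drop_i]
        if (!any(vapply(isos, identical, logical(1), chain)))
          cands[[length(cands) + 1L]] <- chain
      }
    }
  }
  cands <- unique(cands)
  if (length(cands) == 0L) return(NULL)
  do.call(rbind, gene$exons[cands[[sample.int(length(cands), 1L)]]])
}

# Shift internal boundaries by up to +/- jitter bp (terminal ends kept).
#' @keywords internal
jitter_exons <- function(exons, jitter) {
  if (jitter <= 0L || nrow(exons) < 2L) return(exons)
  for (i in seq_len(nrow(exons))) {
    if (i < nrow(exons)) {
      exons[i, 2L] <- exons[i, 2L] + sample(seq(-jitter, jitter), 1L)
    }
    if (i > 1L) {
      exons[i, 1L] <- exons[i, 1L] + sample(seq(-jitter, jitter), 1L)
    }
  }
  exons
}
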