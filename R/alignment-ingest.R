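#' Read spliced paired-end alignments as block chains
#'
#' Loads a coordinate-sorted SAM/BAM file and converts each primary aligned
#' record to a chain of genomic blocks (0-based, half-open). CIGAR `M`/`=`/`X`
#' and `D` operations extend the current block, `N` splits blocks at introns,
#' and `I`/`S`/`H` do not consume reference. Unmapped, secondary,
#' supplementary and sub-`min_mapq` records are dropped. Records with invalid
#' CIGAR strings are rejected when the file is parsed by Rsamtools.
#'
#' Strand is taken from the aligner's splice-strand tag (`XS`) when present;
#' otherwise, for spliced records with a reference FASTA supplied, from the
#' GT-AG / CT-AC intron dinucleotide motifs; otherwise it is `"*"` (unknown).
#'
#' @param path Path to a coordinate-sorted SAM or BAM file with a header.
#' @param min_mapq Minimum mapping quality to retain a record (default 1;
#'   records with missing MAPQ, stored as 255, are kept).
#' @param fasta Optional reference FASTA used for intron-motif strand
#'   inference of spliced records that carry no `XS` tag.
#' @return A list of fragments; each fragment is a list with elements
#'   `qname`, `chrom`, `strand` (`"+"`, `"-"` or `"*"`), `mapq`, `first`
#'   (logical, first-of-pair flag) and `blocks` (two-column integer matrix of
#'   0-based half-open intervals, sorted and strictly increasing).
#' @export
load_alignments <- function(path, min_mapq = 1L, fasta = NULL) {
  bam <- as_sorted_bam(path)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag", "mapq"),
    tag = "XS",
    flag = Rsamtools::scanBamFlag(
      isUnmappedQuery = FALSE,
      isSecondaryAlignment = FALSE,
      isSupplementaryAlignment = FALSE
    )
  )
  gal <- GenomicAlignments::readGAlignments(bam, param = param)
  mc <- S4Vectors::mcols(gal)
  keep <- is.na(mc$mapq) | mc$mapq >= min_mapq
  gal <- gal[keep]
  mc <- S4Vectors::mcols(gal)
  if (length(gal) == 0L) return(list())

  blocks1 <- GenomicAlignments::extractAlignmentRangesOnReference(
    GenomicAlignments::cigar(gal), GenomicAlignments::start(gal)
  )
  chroms <- as.character(GenomicAlignments::seqnames(gal))
  xs <- mc$XS
  if (is.null(xs)) xs <- rep(NA_character_, length(gal))
  genome <- if (!is.null(fasta)) Biostrings::readDNAStringSet(fasta) else NULL
  if (!is.null(genome)) names(genome) <- sub("\\s.*$", "", names(genome))

  frags <- vector("list", length(gal))
  for (i in seq_along(gal)) {
    ir <- blocks1[[i]]
    blocks <- cbind(start = IRanges::start(ir) - 1L, end = IRanges::end(ir))
    strand <- xs[i]
    if (is.na(strand) || !strand %in% c("+", "-")) {
      strand <- if (nrow(blocks) > 1L && !is.null(genome)) {
        infer_motif_strand(genome, chroms[i], blocks)
      } else "*"
    }
    frags[[i]] <- list(
      qname = mc$qname[i], chrom = chroms[i], strand = strand,
      mapq = if (is.na(mc$mapq[i])) 255L else mc$mapq[i],
      first = bitwAnd(mc$flag[i], 64L) > 0L,
      blocks = blocks
    )
  }
  frags
}

# Validate sortedness/header; convert SAM to a temporary BAM if needed.
#' @keywords internal
as_sorted_bam <- function(path) {
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    hdr <- grep("^@", readLines(path, n = 1000L), value = TRUE)
    if (!any(grepl("^@SQ", hdr))) stop("SAM file has no @SQ header lines: ", path)
    hd <- grep("^@HD", hdr, value = TRUE)
    if (length(hd) == 0L || !grepl("SO:coordinate", hd[1L]))
      stop("alignment file is not coordinate-sorted: ", path)
    dest <- tempfile(fileext = "")
    return(Rsamtools::asBam(path, dest, overwrite = TRUE, indexDestination = FALSE))
  }
  hdr <- Rsamtools::scanBamHeader(path)[[1L]]
  if (length(hdr$targets) == 0L) stop("BAM file has an empty header: ", path)
  hd <- hdr$text[["@HD"]]
  if (is.null(hd) || !any(grepl("SO:coordinate", hd)))
    stop("alignment file is not coordinate-sorted: ", path)
  path
}

# GT-AG on the forward strand => '+', CT-AC => '-', anything else unknown.
#' @keywords internal
infer_motif_strand <- function(genome, chrom, blocks) {
  if (!chrom %in% names(genome)) return("*")
  seq <- genome[[chrom]]
  votes <- character(0)
  for (i in seq_len(nrow(blocks) - 1L)) {
    d <- blocks[i, 2L]       # 0-based intron start
    a <- blocks[i + 1L, 1L]  # 0-based intron end (exclusive)
    if (a - d < 4L || a > length(seq)) next
    left <- as.character(Biostrings::subseq(seq, d + 1L, d + 2L))
    right <- as.character(Biostrings::subseq(seq, a - 1L, a))
    if (left == "GT" && right == "AG") votes <- c(votes, "+")
    if (left == "CT" && right == "AC") votes <- c(votes, "-")
  }
  if (length(unique(votes)) == 1L) votes[1L] else "*"
}

#' Pair mates by query name
#'
#' Groups fragments by query name and chromosome and emits mate pairs, the
#' left mate being the one whose first block starts first. Fragments without
#' a usable mate (mate missing, or on another chromosome) are emitted as
#' singletons; they still contribute to graph building but not to paired
#' subpaths. If more than two records share a name on one chromosome
#' (duplicate mappings that survived upstream filters), the first/second-mate
#' pairing with the highest summed MAPQ is kept, with a warning.
#'
#' @param fragments List of fragments from [load_alignments()].
#' @return A list of pairs; each pair is a list with `left`, `right`
#'   (`right` is `NULL` for singletons), `chrom` and `strand` (the known
#'   strand of either mate, else `"*"`).
#' @export
pair_mates <- function(fragments) {
  if (length(fragments) == 0L) return(list())
  keys <- vapply(fragments, function(f) paste0(f$qname, "\r", f$chrom), character(1))
  groups <- split(seq_along(fragments), keys)
  pairs <- list()
  n_dup <- 0L
  for (idx in groups) {
    fs <- fragments[idx]
    firsts <- which(vapply(fs, function(f) f$first, logical(1)))
    seconds <- setdiff(seq_along(fs), firsts)
    if (length(firsts) >= 1L && length(seconds) >= 1L) {
      if (length(fs) > 2L) n_dup <- n_dup + 1L
      best <- c(NA_integer_, NA_integer_); best_q <- -1L
      for (a in firsts) for (b in seconds) {
        q <- fs[[a]]$mapq + fs[[b]]$mapq
        if (q > best_q) { best <- c(a, b); best_q <- q }
      }
      fs <- fs[best]
    } else {
      # all mates on one side: singletons
      for (f in fs) pairs[[length(pairs) + 1L]] <- make_pair(f, NULL)
      next
    }
    if (length(fs) == 1L) {
      pairs[[length(pairs) + 1L]] <- make_pair(fs[[1L]], NULL)
    } else {
      o <- order(vapply(fs, function(f) f$blocks[1L, 1L], integer(1)))
      pairs[[length(pairs) + 1L]] <- make_pair(fs[[o[1L]]], fs[[o[2L]]])
    }
  }
  if (n_dup > 0L)
    warning(n_dup, " query name(s) had >2 alignments; kept highest-MAPQ pairing")
  pairs
}

#' @keywords internal
make_pair <- function(left, right) {
  strand <- left$strand
  if (strand == "*" && !is.null(right)) strand <- right$strand
  span <- range(c(left$blocks, if (!is.null(right)) right$blocks))
  list(left = left, right = right, chrom = left$chrom, strand = strand,
       span = as.integer(span))
}

#' Cluster mate pairs into gene loci
#'
#' Single-linkage clustering of fragment pairs into loci by genomic
#' proximity: two pairs belong to one locus when their intron-spanning hulls
#' (leftmost block start to rightmost block end across both mates) are within
#' `max_gap` of each other on the same chromosome. Known strands are kept
#' separate; unknown-strand pairs join the overlapping known-strand locus
#' with the larger overlap (ties resolved to `"+"`), and the remainder form
#' their own loci. A final pass re-merges same-strand loci brought within
#' `max_gap` of each other by unknown-strand assignment.
#'
#' @param pairs List of pairs from [pair_mates()].
#' @param max_gap Maximum gap (bp) bridged within one locus (default 50).
#' @return A list of loci; each locus is a list with `chrom`, `strand`,
#'   `start`, `end` (0-based half-open span) and `pairs`.
#' @export
cluster_loci <- function(pairs, max_gap = 50L) {
  if (length(pairs) == 0L) return(list())
  out <- list()
  for (chrom in unique(vapply(pairs, `[[`, character(1), "chrom"))) {
    on_chrom <- pairs[vapply(pairs, function(p) p$chrom == chrom, logical(1))]
    strands <- vapply(on_chrom, `[[`, character(1), "strand")
    known <- list(); # strand -> list(ranges IRanges, members list of idx)
    for (s in c("+", "-")) {
      idx <- which(strands == s)
      if (length(idx)) known[[s]] <- cluster_hulls(on_chrom[idx], idx, max_gap)
    }
    unk_idx <- which(strands == "*")
    assigned <- rep(NA_character_, length(unk_idx))
    if (length(unk_idx)) {
      hull <- t(vapply(on_chrom[unk_idx], `[[`, integer(2), "span"))
      for (j in seq_along(unk_idx)) {
        best_s <- NA_character_; best_ov <- -Inf
        for (s in c("+", "-")) {
          cl <- known[[s]]
          if (is.null(cl)) next
          ov <- pmin(IRanges::end(cl$ranges), hull[j, 2L] + max_gap) -
            pmax(IRanges::start(cl$ranges), hull[j, 1L] + 1L - max_gap)
          if (length(ov) && max(ov) >= 0 && max(ov) > best_ov) {
            best_ov <- max(ov); best_s <- s
          }
        }
        assigned[j] <- best_s
      }
      for (s in c("+", "-")) {
        take <- unk_idx[!is.na(assigned) & assigned == s]
        if (length(take)) {
          merged <- cluster_hulls(c(on_chrom[known[[s]]$idx], on_chrom[take]),
                                  c(known[[s]]$idx, take), max_gap)
          known[[s]] <- merged
        }
      }
      left <- unk_idx[is.na(assigned)]
      if (length(left)) known[["*"]] <- cluster_hulls(on_chrom[left], left, max_gap)
    }
    for (s in names(known)) {
      cl <- known[[s]]
      for (g in unique(cl$group)) {
        members <- cl$idx[cl$group == g]
        lp <- on_chrom[members]
        hull <- t(vapply(lp, `[[`, integer(2), "span"))
        out[[length(out) + 1L]] <- list(
          chrom = chrom, strand = s,
          start = min(hull[, 1L]), end = max(hull[, 2L]),
          pairs = lp
        )
      }
    }
  }
  out[order(vapply(out, `[[`, character(1), "chrom"),
            vapply(out, `[[`, numeric(1), "start"))]
}

# Single-linkage merge of pair hulls; returns group labels per pair.
#' @keywords internal
cluster_hulls <- function(pairs, idx, max_gap) {
  hull <- t(vapply(pairs, `[[`, integer(2), "span"))
  ir <- IRanges::IRanges(hull[, 1L] + 1L, hull[, 2L])  # 1-based for IRanges
  red <- IRanges::reduce(ir, min.gapwidth = max_gap + 1L)
  # each hull is contained in exactly one reduced range
  grp <- IRanges::findOverlaps(ir, red, select = "first")
  list(idx = idx, group = grp, ranges = red)
}
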