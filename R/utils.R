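# Internal coordinate convention: 0-based half-open [start, end).
# GTF and SAM are 1-based inclusive; conversion happens only at I/O.

#' @keywords internal
to_internal <- function(start1, end1) cbind(start = start1 - 1L, end = end1)

#' @keywords internal
to_gtf <- function(start0, end0) cbind(start = start0 + 1L, end = end0)

# Key for a node-index path; fixed width so string order == lexicographic
# order on the integer vector.
#' @keywords internal
path_key <- function(nodes) paste(sprintf("%06d", nodes), collapse = ",")

# Lexicographic order of a list of integer vectors.
#' @keywords internal
path_order <- function(paths) order(vapply(paths, path_key, character(1)))

# All contiguous length-k windows of an integer vector, as a list.
#' @keywords internal
path_windows <- function(nodes, k) {
  n <- length(nodes)
  if (k > n) return(list())
  lapply(seq_len(n - k + 1L), function(i) nodes[i:(i + k - 1L)])
}

#' @keywords internal
is_contiguous_subseq <- function(sub, full) {
  ns <- length(sub); nf <- length(full)
  if (ns > nf) return(FALSE)
  for (i in seq_len(nf - ns + 1L)) {
    if (all(full[i:(i + ns - 1L)] == sub)) return(TRUE)
  }
  FALSE
}

# Intron chain of an exon matrix (0-based half-open rows) as "d-a;d-a;...".
#' @keywords internal
intron_chain_string <- function(exons) {
  if (nrow(exons) < 2L) return("")
  d <- exons[-nrow(exons), 2L]
  a <- exons[-1L, 1L]
  paste(sprintf("%d-%d", d, a), collapse = ";")
}

# Merge abutting rows of a sorted exon-segment matrix into maximal exons.
#' @keywords internal
merge_abutting <- function(segs) {
  if (nrow(segs) <= 1L) return(segs)
  out <- segs[1L, , drop = FALSE]
  for (i in 2L:nrow(segs)) {
    if (segs[i, 1L] == out[nrow(out), 2L]) {
      out[nrow(out), 2L] <- segs[i, 2L]
    } else {
      out <- rbind(out, segs[i, , drop = FALSE])
    }
  }
  out
}
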