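# Crystal-contig assembly: candidate small-RNA loci built only from genomic
# reads that contain a perfect match to some small-RNA read. Anchored reads
# are greedily merged by exact suffix-prefix overlap (longest overlap first,
# lexicographic tie-breaking), after removing reads contained in another.

#' Assemble crystal contigs from anchored genomic reads
#'
#' Only genomic reads containing a perfect match (on either strand) to at
#' least one small read are used. Contained reads are absorbed; remaining
#' reads are merged greedily by exact suffix-prefix overlaps of at least
#' `min_overlap` nt, longest overlap first with deterministic lexicographic
#' tie-breaking. Every emitted contig contains at least one anchoring small
#' read as an exact substring (either strand).
#'
#' @param genomic_reads character vector (or DNAStringSet) of genomic reads.
#' @param small_reads collapsed-read data.frame or character vector of
#'   small-RNA sequences.
#' @param min_overlap minimum exact suffix-prefix overlap for merging.
#' @return data.frame with columns `contig_id`, `seq`, `length`,
#'   `n_support` (genomic reads merged in) and list-columns `support`
#'   (their ids) and `anchors` (small reads contained).
#' @export
assemble_crystal_contigs <- function(genomic_reads, small_reads,
                                     min_overlap = 20L) {
  if (inherits(genomic_reads, "DNAStringSet"))
    genomic_reads <- setNames(as.character(genomic_reads),
                              names(genomic_reads))
  greads <- normalize_seq(genomic_reads)
  if (is.null(names(greads)) || any(names(greads) == ""))
    names(greads) <- sprintf("gread%05d", seq_along(greads))
  smalls <- if (is.data.frame(small_reads)) small_reads$seq else
    normalize_seq(small_reads)
  if (length(greads) == 0 || length(smalls) == 0)
    stop("both read sets must be non-empty")

  anchored <- anchor_reads(greads, smalls)
  if (!any(anchored)) return(empty_contigs())
  seqs <- greads[anchored]

  # absorb contained reads (substring of another, same orientation)
  keep <- rep(TRUE, length(seqs))
  support <- as.list(names(seqs))
  ord <- order(nchar(seqs))
  for (a in ord) {
    for (b in seq_along(seqs)) {
      if (a == b || !keep[a] || !keep[b]) next
      if (nchar(seqs[a]) <= nchar(seqs[b]) &&
          grepl(seqs[a], seqs[b], fixed = TRUE) &&
          !(nchar(seqs[a]) == nchar(seqs[b]) && b > a)) {
        support[[b]] <- c(support[[b]], support[[a]])
        keep[a] <- FALSE
        break
      }
    }
  }
  seqs <- seqs[keep]; support <- support[keep]

  repeat {
    n <- length(seqs)
    if (n < 2) break
    best <- NULL; best_ov <- min_overlap - 1L
    for (a in seq_len(n)) for (b in seq_len(n)) {
      if (a == b) next
      ov <- suffix_prefix_overlap(seqs[a], seqs[b], best_ov + 0L)
      if (ov > best_ov ||
          (ov == best_ov && ov >= min_overlap && !is.null(best) &&
           lex_before(seqs[a], seqs[b], seqs[best[1]], seqs[best[2]]))) {
        best <- c(a, b); best_ov <- max(best_ov, ov)
      }
    }
    if (is.null(best) || best_ov < min_overlap) break
    a <- best[1]; b <- best[2]
    merged <- paste0(seqs[a], substr(seqs[b], best_ov + 1L, nchar(seqs[b])))
    msupport <- c(support[[a]], support[[b]])
    seqs <- seqs[-c(a, b)]; support <- support[-c(a, b)]
    seqs <- c(seqs, setNames(merged, ""))
    support[[length(support) + 1L]] <- msupport
  }

  anchors <- lapply(seqs, function(s) contained_smalls(s, smalls))
  has_anchor <- vapply(anchors, length, integer(1)) > 0
  seqs <- seqs[has_anchor]; support <- support[has_anchor]
  anchors <- anchors[has_anchor]
  o <- order(-nchar(seqs), seqs)
  data.frame(contig_id = sprintf("crystal%04d", seq_along(o)),
             seq = unname(seqs[o]), length = nchar(unname(seqs[o])),
             n_support = vapply(support[o], length, integer(1)),
             support = I(lapply(support[o], sort)),
             anchors = I(anchors[o]),
             stringsAsFactors = FALSE)
}

empty_contigs <- function() {
  data.frame(contig_id = character(0), seq = character(0),
             length = integer(0), n_support = integer(0),
             support = I(list()), anchors = I(list()),
             stringsAsFactors = FALSE)
}

anchor_reads <- function(greads, smalls) {
  rc <- revcomp(greads)
  anchored <- rep(FALSE, length(greads))
  for (s in unique(smalls)) {
    todo <- !anchored
    if (!any(todo)) break
    anchored[todo] <- grepl(s, greads[todo], fixed = TRUE) |
      grepl(s, rc[todo], fixed = TRUE)
  }
  anchored
}

contained_smalls <- function(contig, smalls) {
  rc <- revcomp(contig)
  smalls[vapply(smalls, function(s)
    grepl(s, contig, fixed = TRUE) || grepl(s, rc, fixed = TRUE),
    logical(1))]
}

# longest k with suffix(a, k) == prefix(b, k); k < min(len) (containment is
# handled separately). Returns 0 if none above `floor`.
suffix_prefix_overlap <- function(a, b, floor = 0L) {
  la <- nchar(a); lb <- nchar(b)
  for (k in seq(min(la, lb) - 1L, max(1L, floor), by = -1L)) {
    if (k < 1) break
    if (substr(a, la - k + 1L, la) == substr(b, 1L, k)) return(k)
  }
  0L
}

lex_before <- function(a1, b1, a2, b2) {
  if (a1 != a2) a1 < a2 else b1 < b2
}
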