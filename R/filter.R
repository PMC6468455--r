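# Contaminant subtraction: remove reads that align end-to-end (ungapped) to
# any reference sequence with a small substitution allowance, on either
# strand. Mirrors the specificity-first filtering done before piRNA cluster
# detection, where reads matching tRNA, rRNA or miRNA precursor references
# within three mismatches are discarded.

#' Remove reads matching annotated contaminant references
#'
#' A read is removed if and only if it matches a substring of any reference
#' end-to-end, without gaps, on either strand, with at most `max_mismatch`
#' substitutions. The removal report names the reference class that claimed
#' each removed read (classes are tried in the order given; the first hit
#' wins).
#'
#' @param collapsed collapsed-read data.frame from [collapse_reads()].
#' @param references named list of reference sets (e.g.
#'   `list(tRNA = ..., rRNA = ..., mirna_precursor = ...)`), each a character
#'   vector or [Biostrings::DNAStringSet].
#' @param max_mismatch substitution allowance (default 3).
#' @return list with `retained` (collapsed-read data.frame), `removed`
#'   (same columns plus `class`), partitioning the input.
#' @export
filter_annotated <- function(collapsed, references, max_mismatch = 3L) {
  if (length(references) == 0 || is.null(names(references)))
    stop("references must be a non-empty named list")
  refs <- lapply(references, function(r) {
    if (inherits(r, "DNAStringSet")) r
    else Biostrings::DNAStringSet(normalize_seq(r))
  })
  refs <- refs[vapply(refs, length, integer(1)) > 0]
  n <- nrow(collapsed)
  cls <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    read <- collapsed$seq[i]
    rc <- revcomp(read)
    for (nm in names(refs)) {
      hit <- any(Biostrings::vcountPattern(read, refs[[nm]],
                                           max.mismatch = max_mismatch) > 0) ||
        any(Biostrings::vcountPattern(rc, refs[[nm]],
                                      max.mismatch = max_mismatch) > 0)
      if (hit) { cls[i] <- nm; break }
    }
  }
  removed <- collapsed[!is.na(cls), , drop = FALSE]
  removed$class <- cls[!is.na(cls)]
  retained <- collapsed[is.na(cls), , drop = FALSE]
  rownames(removed) <- rownames(retained) <- NULL
  list(retained = retained, removed = removed)
}
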