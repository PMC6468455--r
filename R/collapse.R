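# Read collapsing and length profiles.

#' Collapse raw reads to distinct sequences with copy counts
#'
#' Normalises to the uppercase T-alphabet (U becomes T) and tallies one
#' entry per distinct sequence. Reads containing characters outside
#' A/C/G/T (including N) are dropped with a warning, since downstream bias
#' statistics and ungapped mapping assume a 4-letter alphabet. The sum of
#' counts equals the number of surviving input reads.
#'
#' @param reads character vector (or [Biostrings::DNAStringSet]) of reads.
#' @return data.frame with columns `seq`, `count`, `length`, ordered by
#'   decreasing count then sequence.
#' @export
collapse_reads <- function(reads) {
  reads <- normalize_seq(reads)
  bad <- grepl("[^ACGT]", reads)
  if (any(bad))
    warning(sum(bad), " read(s) with non-ACGT characters dropped")
  reads <- reads[!bad]
  if (length(reads) == 0)
    return(data.frame(seq = character(0), count = integer(0),
                      length = integer(0), stringsAsFactors = FALSE))
  tab <- table(reads)
  out <- data.frame(seq = names(tab), count = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$length <- nchar(out$seq)
  out <- out[order(-out$count, out$seq), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read-length histogram
#'
#' @param collapsed collapsed-read data.frame from [collapse_reads()].
#' @param weighting `"by_copy"` counts read copies, `"by_unique"` counts
#'   distinct sequences.
#' @return data.frame with columns `length` and `n`; totals equal total
#'   copies or distinct sequences respectively.
#' @export
length_profile <- function(collapsed, weighting = c("by_copy", "by_unique")) {
  weighting <- match.arg(weighting)
  if (nrow(collapsed) == 0)
    return(data.frame(length = integer(0), n = integer(0)))
  w <- if (weighting == "by_copy") collapsed$count else rep(1L,
                                                            nrow(collapsed))
  agg <- tapply(w, collapsed$length, sum)
  data.frame(length = as.integer(names(agg)), n = as.integer(agg),
             row.names = NULL)
}
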