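# Ungapped end-to-end genome mapping with a substitution allowance.
# All placements on both strands are reported (no random single placement);
# n_loci carries the total number of genomic placements of each read so that
# downstream statistics can weight multi-mappers as count / n_loci.

#' Map collapsed reads to a genome
#'
#' Reports every ungapped end-to-end placement of each read on either strand
#' with at most `max_mismatch` substitutions. Coordinates are 0-based
#' half-open; `five_prime`/`three_prime` are the genomic positions of the
#' read's 5' and 3' ends (`start` and `end - 1` on `+`, swapped on `-`).
#'
#' @param collapsed collapsed-read data.frame from [collapse_reads()] (or any
#'   data.frame with `seq` and `count`).
#' @param genome [Biostrings::DNAStringSet] or named character vector.
#' @param max_mismatch substitution allowance (default 0; locus-level work
#'   uses exact placements, only contaminant subtraction uses a looser one).
#' @return mapping data.frame with columns `seq`, `count`, `contig`,
#'   `start`, `end`, `strand`, `mismatches`, `five_prime`, `three_prime`,
#'   `n_loci`.
#' @export
map_reads <- function(collapsed, genome, max_mismatch = 0L) {
  if (!inherits(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  if (length(genome) == 0 || sum(Biostrings::width(genome)) == 0)
    stop("genome must be non-empty")
  if (is.null(names(genome)))
    names(genome) <- sprintf("contig%d", seq_along(genome))
  if (!"count" %in% names(collapsed)) collapsed$count <- 1L
  rows <- list(); nr <- 0L
  add <- function(df) {
    nr <<- nr + 1L
    rows[[nr]] <<- df
  }
  for (i in seq_len(nrow(collapsed))) {
    read <- collapsed$seq[i]
    cnt <- collapsed$count[i]
    pats <- c(`+` = read, `-` = revcomp(read))
    for (ci in seq_along(genome)) {
      subj <- genome[[ci]]
      for (str in c("+", "-")) {
        m <- Biostrings::matchPattern(pats[[str]], subj,
                                      max.mismatch = max_mismatch)
        if (length(m) == 0) next
        st1 <- Biostrings::start(m); en1 <- Biostrings::end(m)
        mm <- if (max_mismatch == 0) rep(0L, length(m)) else
          count_mismatches(pats[[str]], as.character(m))
        add(data.frame(seq = read, count = cnt,
                       contig = names(genome)[ci],
                       start = st1 - 1L, end = en1, strand = str,
                       mismatches = mm, stringsAsFactors = FALSE))
      }
    }
  }
  if (nr == 0L)
    return(data.frame(seq = character(0), count = integer(0),
                      contig = character(0), start = integer(0),
                      end = integer(0), strand = character(0),
                      mismatches = integer(0), five_prime = integer(0),
                      three_prime = integer(0), n_loci = integer(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows[seq_len(nr)])
  out$five_prime <- ifelse(out$strand == "+", out$start, out$end - 1L)
  out$three_prime <- ifelse(out$strand == "+", out$end - 1L, out$start)
  out$n_loci <- as.integer(ave(rep(1L, nrow(out)), out$seq, FUN = sum))
  out <- out[order(out$contig, out$start, out$end, out$strand, out$seq), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

count_mismatches <- function(pattern, hits) {
  p <- strsplit(pattern, "")[[1]]
  vapply(strsplit(hits, ""), function(h) sum(h != p), integer(1))
}
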