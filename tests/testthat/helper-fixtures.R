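# Small fixtures built in code.

# A reduced simulation: one unistrand cluster, one canonical miRNA locus,
# one tRNA locus -- fast enough for unit tests.
small_config <- function(seed = 11L, ...) {
  simulation_config(
    seed = seed,
    genome_length = 8000L,
    features = list(
      feature_spec("unistrand_pirna_cluster", length = 600, strand = "+",
                   n_reads = 25),
      feature_spec("mirna_locus", family = "MIR-1"),
      feature_spec("trna", n_fragments = 10)),
    n_background_reads = 20L,
    ...)
}

# Hand-built mapping records (0-based half-open), one contig.
make_mappings <- function(starts, lens, strand = "+", counts = 1L,
                          seqs = NULL, contig = "chrT", n_loci = 1L) {
  n <- length(starts)
  lens <- rep_len(lens, n); counts <- rep_len(counts, n)
  strand <- rep_len(strand, n)
  if (is.null(seqs)) {
    # distinct sequences starting with T (1T-biased piRNA-like stacks)
    repeat {
      seqs <- vapply(seq_len(n), function(i) {
        paste0("T", paste(sample(c("A", "C", "G", "T"), lens[i] - 1L,
                                 replace = TRUE), collapse = ""))
      }, character(1))
      if (!anyDuplicated(seqs)) break
    }
  }
  end <- starts + lens
  data.frame(seq = seqs, count = as.integer(counts), contig = contig,
             start = as.integer(starts), end = as.integer(end),
             strand = strand, mismatches = 0L,
             five_prime = ifelse(strand == "+", starts, end - 1L),
             three_prime = ifelse(strand == "+", end - 1L, starts),
             n_loci = as.integer(rep_len(n_loci, n)),
             stringsAsFactors = FALSE)
}

random_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}
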