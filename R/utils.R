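# Internal helpers shared across modules. Sequences are handled in the
# T-alphabet (DNA space): U is normalised to T on input, so the "1U" bias of
# the literature is "1T" here, as in genome-space small-RNA data.

BASES <- c("A", "C", "G", "T")

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

#' Reverse complement of character sequences
#'
#' Thin character-vector wrapper around [Biostrings::reverseComplement()].
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Single-base complement on a character vector of bases.
comp_base <- function(b) unname(COMPLEMENT[b])

# Can bases a and b form a pair (Watson-Crick or G:U wobble)?
base_pairable <- function(a, b) {
  (a == "A" & b == "T") | (a == "T" & b == "A") |
    (a == "C" & b == "G") | (a == "G" & b == "C") |
    (a == "G" & b == "T") | (a == "T" & b == "G")
}

# Normalise reads: uppercase, U -> T. Returns character vector.
normalize_seq <- function(x) {
  x <- toupper(as.character(x))
  gsub("U", "T", x, fixed = TRUE)
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a sub-seed from a base seed, kept within 32-bit integer range.
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 31 + k) %% 2147483647L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Random DNA string(s) with a given GC fraction.
random_dna <- function(n, length, gc = 0.5) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  vapply(seq_len(n), function(i) {
    paste(sample(BASES, length, replace = TRUE, prob = p), collapse = "")
  }, character(1))
}

# Mapping weight: copy count spread over the read's genomic placements.
mapping_weight <- function(mappings, weighting = c("weighted", "unweighted")) {
  weighting <- match.arg(weighting)
  if (weighting == "weighted") mappings$count / mappings$n_loci
  else as.numeric(mappings$count)
}
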