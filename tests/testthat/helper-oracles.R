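# Independent brute-force oracles, deliberately structured differently from
# the implementations they check.

# All ungapped end-to-end placements of `read` on a single-contig genome
# string, by scanning every offset on both strands.
naive_map_scan <- function(read, genome_chr, max_mismatch = 0L) {
  L <- nchar(genome_chr)
  l <- nchar(read)
  gb <- strsplit(genome_chr, "")[[1]]
  hits <- list()
  for (strand in c("+", "-")) {
    pat <- if (strand == "+") read else srnaloci::revcomp(read)
    pb <- strsplit(pat, "")[[1]]
    for (s in seq_len(L - l + 1L)) {
      mm <- sum(gb[s:(s + l - 1L)] != pb)
      if (mm <= max_mismatch)
        hits[[length(hits) + 1L]] <- data.frame(
          start = s - 1L, end = s + l - 1L, strand = strand,
          mismatches = mm, stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), mismatches = integer(0)))
  out <- do.call(rbind, hits)
  out[order(out$start, out$strand), , drop = FALSE]
}

# Ping-pong histogram by an explicit double loop over all opposite-strand
# mapping pairs.
brute_pingpong <- function(mappings, max_overlap) {
  w <- mappings$count / mappings$n_loci
  hist <- setNames(rep(0, max_overlap), seq_len(max_overlap))
  for (i in seq_len(nrow(mappings))) {
    for (j in seq_len(nrow(mappings))) {
      if (mappings$strand[i] != "+" || mappings$strand[j] != "-") next
      if (mappings$contig[i] != mappings$contig[j]) next
      ov <- mappings$five_prime[j] - mappings$five_prime[i] + 1L
      if (ov >= 1 && ov <= max_overlap)
        hist[ov] <- hist[ov] + w[i] * w[j]
    }
  }
  unname(hist)
}

# Maximum base-pair count by memoized top-down recursion, decomposing on
# whether the LAST base is paired (the DP decomposes on the first).
fold_oracle_count <- function(seq, min_loop = 3L) {
  b <- strsplit(toupper(gsub("U", "T", seq)), "")[[1]]
  n <- length(b)
  can <- function(x, y) {
    (x == "A" && y == "T") || (x == "T" && y == "A") ||
      (x == "C" && y == "G") || (x == "G" && y == "C") ||
      (x == "G" && y == "T") || (x == "T" && y == "G")
  }
  memo <- new.env(parent = emptyenv())
  rec <- function(i, j) {
    if (j - i < min_loop + 1L) return(0L)
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    best <- rec(i, j - 1L)
    for (k in i:(j - min_loop - 1L)) {
      if (!can(b[k], b[j])) next
      left <- if (k > i) rec(i, k - 1L) else 0L
      best <- max(best, left + 1L + rec(k + 1L, j - 1L))
    }
    memo[[key]] <- best
    best
  }
  if (n < 2) 0L else rec(1L, n)
}

# Connected components of the anchored-read overlap graph (edges: exact
# suffix-prefix overlap >= min_overlap in either direction, or containment).
crystal_component_count <- function(genomic_reads, small_reads,
                                    min_overlap) {
  rc <- srnaloci::revcomp(genomic_reads)
  anchored <- vapply(seq_along(genomic_reads), function(i)
    any(vapply(small_reads, function(s)
      grepl(s, genomic_reads[i], fixed = TRUE) ||
        grepl(s, rc[i], fixed = TRUE), logical(1))), logical(1))
  reads <- genomic_reads[anchored]
  n <- length(reads)
  if (n == 0) return(0L)
  ov <- function(a, b) {
    la <- nchar(a); lb <- nchar(b)
    for (k in seq(min(la, lb) - 1L, 1L)) {
      if (substr(a, la - k + 1L, la) == substr(b, 1L, k)) return(k)
    }
    0L
  }
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    linked <- ov(reads[i], reads[j]) >= min_overlap ||
      grepl(reads[i], reads[j], fixed = TRUE) ||
      grepl(reads[j], reads[i], fixed = TRUE)
    if (linked) adj[i, j] <- adj[j, i] <- TRUE
  }
  comp <- rep(0L, n); nc <- 0L
  for (i in seq_len(n)) {
    if (comp[i] > 0) next
    nc <- nc + 1L
    stack <- i
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (comp[v] > 0) next
      comp[v] <- nc
      stack <- c(stack, which(adj[v, ] & comp == 0L))
    }
  }
  nc
}
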