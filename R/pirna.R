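# piRNA cluster detection and analytics: proTRAC-style acceptance criteria,
# strand-resolved length distributions, 1T/10A bias, entropy logos,
# ping-pong 5'-5' overlap signature and next-uridine phasing.

#' piRNA cluster acceptance parameters
#'
#' The printed criteria: clusters of at least 500 bp with at least 20 hits,
#' more than 75\% of sequences in the 24--32 nt piRNA size range, more than
#' 75\% of sequences with 1T and/or 10A, and an even abundance distribution
#' (the top 10\% of sequences must carry less than 75\% of the reads).
#' Strict inequalities are honoured exactly as printed at the boundaries.
#'
#' @param min_length minimum cluster length in bp.
#' @param min_hits minimum (weighted) hit count.
#' @param size_range inclusive piRNA-like size range in nt.
#' @param min_size_fraction fraction of sequences inside `size_range`
#'   (strict >).
#' @param min_bias_fraction fraction of sequences carrying 1T and/or 10A
#'   (strict >); per-sequence OR, as in proTRAC. The global 1T and 10A
#'   fractions are reported alongside.
#' @param evenness_top_fraction top share of distinct sequences inspected by
#'   the evenness filter.
#' @param evenness_max_share maximum read share those sequences may carry
#'   (strict <).
#' @param max_gap single-linkage merge distance for candidate formation.
#' @param dual_strand_minority minority-strand weight share above which a
#'   cluster is called dual-strand.
#' @param weighting `"weighted"` spreads copy counts over a read's
#'   placements (count / n_loci); `"unweighted"` uses raw copy counts.
#' @return list of class `cluster_params`.
#' @export
cluster_params <- function(min_length = 500L,
                           min_hits = 20,
                           size_range = c(24L, 32L),
                           min_size_fraction = 0.75,
                           min_bias_fraction = 0.75,
                           evenness_top_fraction = 0.10,
                           evenness_max_share = 0.75,
                           max_gap = 500L,
                           dual_strand_minority = 0.10,
                           weighting = c("weighted", "unweighted")) {
  weighting <- match.arg(weighting)
  stopifnot(min_length > 0, min_hits > 0,
            min_size_fraction > 0, min_size_fraction < 1,
            min_bias_fraction > 0, min_bias_fraction < 1,
            evenness_top_fraction > 0, evenness_top_fraction < 1,
            evenness_max_share > 0, evenness_max_share < 1)
  structure(list(min_length = as.integer(min_length), min_hits = min_hits,
                 size_range = as.integer(size_range),
                 min_size_fraction = min_size_fraction,
                 min_bias_fraction = min_bias_fraction,
                 evenness_top_fraction = evenness_top_fraction,
                 evenness_max_share = evenness_max_share,
                 max_gap = as.integer(max_gap),
                 dual_strand_minority = dual_strand_minority,
                 weighting = weighting),
            class = "cluster_params")
}

base_at <- function(seqs, position) {
  ifelse(nchar(seqs) >= position, substr(seqs, position, position),
         NA_character_)
}

#' Detect piRNA clusters
#'
#' Candidates are maximal runs of mappings whose inter-mapping gap is at
#' most `max_gap` per contig (single linkage, both strands pooled).
#' Acceptance requires all of: span `>= min_length`; weighted hits
#' `>= min_hits`; fraction of sequences with length inside `size_range`
#' `> min_size_fraction`; fraction of sequences with 5' T and/or
#' position-10 A `> min_bias_fraction`; and the top
#' `evenness_top_fraction` of distinct sequences carrying
#' `< evenness_max_share` of the weighted reads. The per-candidate report
#' names every violated criterion.
#'
#' @param mappings mapping data.frame from [map_reads()], contaminant-
#'   filtered upstream.
#' @param genome genome the mappings refer to (kept for interface symmetry
#'   and TE overlap; sequence content is not needed for the filters).
#' @param params a [cluster_params()].
#' @param te_annotation optional TE intervals (data.frame with `contig`,
#'   `start`, `end`, 0-based half-open) for overlap reporting.
#' @return list with `clusters` (accepted clusters; data.frame with a
#'   `members` list-column of mapping subsets) and `report` (per-candidate
#'   filter report).
#' @export
detect_clusters <- function(mappings, genome = NULL,
                            params = cluster_params(),
                            te_annotation = NULL) {
  empty_cl <- data.frame(cluster_id = character(0), contig = character(0),
                         start = integer(0), end = integer(0),
                         strand_mode = character(0), hits = numeric(0),
                         n_sequences = integer(0), bias_or = numeric(0),
                         bias_1t = numeric(0), bias_10a = numeric(0),
                         size_fraction = numeric(0),
                         evenness_share = numeric(0),
                         te_overlap = numeric(0),
                         stringsAsFactors = FALSE)
  if (nrow(mappings) == 0)
    return(list(clusters = cbind(empty_cl,
                                 data.frame(members = I(list()))),
                report = data.frame()))
  w_all <- mapping_weight(mappings, params$weighting)
  clusters <- list(); report <- list(); cid <- 0L
  for (contig in unique(mappings$contig)) {
    sel <- which(mappings$contig == contig)
    o <- sel[order(mappings$start[sel])]
    grp <- cumsum(c(1L, as.integer(
      mappings$start[o][-1] > cummax(mappings$end[o])[-length(o)] +
        params$max_gap)))
    for (gi in unique(grp)) {
      idx <- o[grp == gi]
      m <- mappings[idx, , drop = FALSE]
      w <- w_all[idx]
      cid <- cid + 1L
      stats <- cluster_stats(m, w, params)
      fails <- character(0)
      if (stats$span < params$min_length) fails <- c(fails, "min_length")
      if (stats$hits < params$min_hits) fails <- c(fails, "min_hits")
      if (!(stats$size_fraction > params$min_size_fraction))
        fails <- c(fails, "size_range")
      if (!(stats$bias_or > params$min_bias_fraction))
        fails <- c(fails, "bias")
      if (!(stats$evenness_share < params$evenness_max_share))
        fails <- c(fails, "evenness")
      report[[cid]] <- data.frame(
        candidate_id = sprintf("cand%04d", cid), contig = contig,
        start = stats$start, end = stats$end, span = stats$span,
        hits = stats$hits, n_sequences = stats$n_sequences,
        size_fraction = stats$size_fraction, bias_or = stats$bias_or,
        bias_1t = stats$bias_1t, bias_10a = stats$bias_10a,
        evenness_share = stats$evenness_share,
        accepted = length(fails) == 0,
        failed = paste(fails, collapse = ","),
        stringsAsFactors = FALSE)
      if (length(fails) == 0) {
        te_ov <- te_overlap_fraction(contig, stats$start, stats$end,
                                     te_annotation)
        clusters[[length(clusters) + 1L]] <- cbind(
          data.frame(cluster_id = sprintf("cluster%03d",
                                          length(clusters) + 1L),
                     contig = contig, start = stats$start,
                     end = stats$end, strand_mode = stats$strand_mode,
                     hits = stats$hits, n_sequences = stats$n_sequences,
                     bias_or = stats$bias_or, bias_1t = stats$bias_1t,
                     bias_10a = stats$bias_10a,
                     size_fraction = stats$size_fraction,
                     evenness_share = stats$evenness_share,
                     te_overlap = te_ov, stringsAsFactors = FALSE),
          data.frame(members = I(list(m))))
      }
    }
  }
  clusters <- if (length(clusters)) do.call(rbind, clusters) else
    cbind(empty_cl, data.frame(members = I(list())))
  rownames(clusters) <- NULL
  list(clusters = clusters, report = do.call(rbind, report))
}

cluster_stats <- function(m, w, params) {
  start <- min(m$start); end <- max(m$end)
  total <- sum(w)
  lens <- m$end - m$start
  in_range <- lens >= params$size_range[1] & lens <= params$size_range[2]
  b1 <- base_at(m$seq, 1L); b10 <- base_at(m$seq, 10L)
  has_bias <- (!is.na(b1) & b1 == "T") | (!is.na(b10) & b10 == "A")
  # evenness over distinct sequences
  seq_w <- tapply(w, m$seq, sum)
  seq_w <- sort(as.numeric(seq_w), decreasing = TRUE)
  n_top <- ceiling(params$evenness_top_fraction * length(seq_w))
  evenness <- sum(seq_w[seq_len(n_top)]) / total
  w_plus <- sum(w[m$strand == "+"]); w_minus <- sum(w[m$strand == "-"])
  minority <- min(w_plus, w_minus) / total
  strand_mode <- if (minority > params$dual_strand_minority) "dual"
  else if (w_plus >= w_minus) "plus" else "minus"
  list(start = start, end = end, span = end - start, hits = total,
       n_sequences = length(unique(m$seq)),
       size_fraction = sum(w[in_range]) / total,
       bias_or = sum(w[has_bias]) / total,
       bias_1t = sum(w[!is.na(b1) & b1 == "T"]) / total,
       bias_10a = if (any(!is.na(b10)))
         sum(w[!is.na(b10) & b10 == "A"]) / sum(w[!is.na(b10)]) else NA_real_,
       evenness_share = evenness, strand_mode = strand_mode)
}

te_overlap_fraction <- function(contig, start, end, te_annotation) {
  if (is.null(te_annotation)) return(NA_real_)
  te <- te_annotation[te_annotation$contig == contig, , drop = FALSE]
  if (nrow(te) == 0) return(0)
  iv <- IRanges::IRanges(start + 1L, end)
  tiv <- IRanges::reduce(IRanges::IRanges(te$start + 1L, te$end))
  ov <- IRanges::intersect(iv, tiv)
  sum(IRanges::width(ov)) / (end - start)
}

#' Positional base bias
#'
#' Weighted fraction of sequences whose base at a 1-based position equals
#' `base`. Sequences shorter than `position` are excluded from the
#' denominator; if none contribute the result is `NA` (flagged undefined).
#'
#' @param reads collapsed-read or mapping data.frame (columns `seq` and
#'   optionally `count`, `n_loci`), or a character vector.
#' @param position 1-based position within the read.
#' @param base the base to count (T-alphabet; "U" is normalised).
#' @return the fraction, or `NA_real_` when no read reaches `position`.
#' @export
base_bias <- function(reads, position, base) {
  rd <- as_read_table(reads)
  base <- normalize_seq(base)
  b <- base_at(rd$seq, position)
  ok <- !is.na(b)
  if (!any(ok)) return(NA_real_)
  sum(rd$weight[ok & b == base]) / sum(rd$weight[ok])
}

as_read_table <- function(reads) {
  if (is.character(reads)) {
    return(data.frame(seq = normalize_seq(reads),
                      weight = rep(1, length(reads)),
                      stringsAsFactors = FALSE))
  }
  w <- if (!is.null(reads$count)) {
    if (!is.null(reads$n_loci)) reads$count / reads$n_loci
    else as.numeric(reads$count)
  } else rep(1, nrow(reads))
  data.frame(seq = normalize_seq(reads$seq), weight = w,
             stringsAsFactors = FALSE)
}

#' Entropy-based sequence logo table
#'
#' Per position, the information content is `2 - H` bits, where `H` is the
#' Shannon entropy (log base 2) of the weighted base frequencies; letter
#' heights are frequency times information. Reads shorter than a position
#' do not contribute to it.
#'
#' @param reads as in [base_bias()].
#' @param positions 1-based positions (default: 1 to the longest read).
#' @return data.frame with columns `position`, `base`, `freq`, `info`,
#'   `height`.
#' @export
entropy_logo <- function(reads, positions = NULL) {
  rd <- as_read_table(reads)
  if (is.null(positions)) positions <- seq_len(max(nchar(rd$seq)))
  out <- list()
  for (p in positions) {
    b <- base_at(rd$seq, p)
    ok <- !is.na(b)
    if (!any(ok)) next
    freq <- vapply(BASES, function(x)
      sum(rd$weight[ok & b == x]), numeric(1)) / sum(rd$weight[ok])
    nz <- freq[freq > 0]
    info <- 2 + sum(nz * log2(nz))
    out[[length(out) + 1L]] <- data.frame(
      position = p, base = BASES, freq = as.numeric(freq), info = info,
      height = as.numeric(freq) * info, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Ping-pong 5'-5' overlap signature
#'
#' For every pair of opposite-strand mappings on the same contig the
#' overlap is `minus.five_prime - plus.five_prime + 1`; overlaps between 1
#' and the maximum read length are accumulated, each pair weighted by the
#' product of the two mappings' weights. A 10-nt modal overlap is the
#' hallmark of ping-pong amplification. Ties for the mode break towards the
#' smallest overlap.
#'
#' @param mappings mapping data.frame (typically one cluster's members).
#' @param max_overlap histogram ceiling; default the longest read.
#' @param weighting see [cluster_params()].
#' @return list of class `pingpong_profile` with `histogram` (data.frame
#'   `overlap`, `weight`, `n_pairs`), `modal_overlap` (NA when no pairs)
#'   and `n_pairs`.
#' @export
ping_pong_profile <- function(mappings, max_overlap = NULL,
                              weighting = "weighted") {
  w <- mapping_weight(mappings, weighting)
  if (is.null(max_overlap)) {
    max_overlap <- if (nrow(mappings) > 0)
      max(mappings$end - mappings$start) else 32L
  }
  hist <- data.frame(overlap = seq_len(max_overlap),
                     weight = 0, n_pairs = 0L)
  n_pairs <- 0L
  for (contig in unique(mappings$contig)) {
    p <- which(mappings$contig == contig & mappings$strand == "+")
    m <- which(mappings$contig == contig & mappings$strand == "-")
    if (length(p) == 0 || length(m) == 0) next
    ov <- outer(mappings$five_prime[m], mappings$five_prime[p], `-`) + 1L
    wt <- outer(w[m], w[p])
    keep <- ov >= 1L & ov <= max_overlap
    if (!any(keep)) next
    agg_w <- tapply(wt[keep], ov[keep], sum)
    agg_n <- table(ov[keep])
    ix <- as.integer(names(agg_w))
    hist$weight[ix] <- hist$weight[ix] + as.numeric(agg_w)
    hist$n_pairs[ix] <- hist$n_pairs[ix] + as.integer(agg_n)
    n_pairs <- n_pairs + sum(keep)
  }
  modal <- if (n_pairs == 0) NA_integer_ else
    hist$overlap[which.max(hist$weight)]
  structure(list(histogram = hist, modal_overlap = modal,
                 n_pairs = n_pairs, weighting = weighting),
            class = "pingpong_profile")
}

#' Phasing profile along one strand
#'
#' Sorts a cluster's mappings on one strand by 5' position along the
#' transcription direction and, for each consecutive pair, records the gap
#' `next 5' - current 3' - 1` (in transcription orientation), whether the
#' downstream read's 5' base is a uridine, and whether that base is the
#' first uridine past the current 3' end (the next-uridine rule of phased
#' trailing piRNA production). Negative gaps (overlapping reads) are kept
#' in `gaps` but excluded from the histogram.
#'
#' @param mappings mapping data.frame.
#' @param genome genome sequences (needed to inspect gap bases).
#' @param strand `"+"` or `"-"`.
#' @return list of class `phasing_profile` with `gaps` (per consecutive
#'   pair), `histogram`, `u_fraction`, `rule_fraction` and `n_pairs`
#'   (empty when fewer than two mappings lie on the strand).
#' @export
phasing_profile <- function(mappings, genome, strand) {
  if (!inherits(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  m <- mappings[mappings$strand == strand, , drop = FALSE]
  empty <- structure(list(gaps = data.frame(), histogram = data.frame(),
                          u_fraction = NA_real_, rule_fraction = NA_real_,
                          n_pairs = 0L),
                     class = "phasing_profile")
  if (nrow(m) < 2) return(empty)
  rows <- list()
  for (contig in unique(m$contig)) {
    mc <- m[m$contig == contig, , drop = FALSE]
    if (nrow(mc) < 2) next
    gseq <- as.character(genome[[match(contig, names(genome))]])
    # transcription order: increasing 5' on +, decreasing on -
    o <- if (strand == "+") order(mc$five_prime, mc$three_prime)
    else order(-mc$five_prime, -mc$three_prime)
    mc <- mc[o, , drop = FALSE]
    for (k in seq_len(nrow(mc) - 1L)) {
      cur3 <- mc$three_prime[k]; nxt5 <- mc$five_prime[k + 1L]
      gap <- if (strand == "+") nxt5 - cur3 - 1L else cur3 - nxt5 - 1L
      nxt_base <- strand_base(gseq, nxt5, strand)
      gap_pos <- if (gap > 0) {
        if (strand == "+") (cur3 + 1L):(nxt5 - 1L) else
          (nxt5 + 1L):(cur3 - 1L)
      } else integer(0)
      gap_has_u <- any(vapply(gap_pos, function(pp)
        strand_base(gseq, pp, strand) == "T", logical(1)))
      rows[[length(rows) + 1L]] <- data.frame(
        contig = contig, gap = gap,
        next5_is_u = nxt_base == "T",
        rule_ok = gap >= 0 && nxt_base == "T" && !gap_has_u,
        overlapping = gap < 0, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0) return(empty)
  gaps <- do.call(rbind, rows)
  nonneg <- gaps$gap[gaps$gap >= 0]
  histogram <- if (length(nonneg)) {
    tb <- table(nonneg)
    data.frame(gap = as.integer(names(tb)), n = as.integer(tb))
  } else data.frame(gap = integer(0), n = integer(0))
  structure(list(gaps = gaps, histogram = histogram,
                 u_fraction = mean(gaps$next5_is_u),
                 rule_fraction = mean(gaps$rule_ok),
                 n_pairs = nrow(gaps)),
            class = "phasing_profile")
}

# base at 0-based genomic position, read on the given strand
strand_base <- function(gseq, pos0, strand) {
  b <- substr(gseq, pos0 + 1L, pos0 + 1L)
  if (strand == "+") b else comp_base(b)
}

#' Strand-resolved length distributions of a cluster
#'
#' Weighted read-length histogram per strand, with a bimodality flag: a
#' strand is flagged bimodal when two local modes at least 3 nt apart each
#' carry more than 20\% of the strand's weight -- the signature of
#' responder piRNA production by two PIWI proteins of different footprints.
#'
#' @param members a cluster's mapping data.frame.
#' @param weighting see [cluster_params()].
#' @return list with `histograms` (data.frame `strand`, `length`,
#'   `weight`) and `bimodal` (named logical per strand).
#' @export
strand_length_stats <- function(members, weighting = "weighted") {
  w <- mapping_weight(members, weighting)
  out <- list(); bi <- c(`+` = FALSE, `-` = FALSE)
  for (str in c("+", "-")) {
    sel <- members$strand == str
    if (!any(sel)) next
    lens <- members$end[sel] - members$start[sel]
    agg <- tapply(w[sel], lens, sum)
    df <- data.frame(strand = str, length = as.integer(names(agg)),
                     weight = as.numeric(agg), stringsAsFactors = FALSE)
    out[[str]] <- df
    bi[str] <- is_bimodal(df$length, df$weight)
  }
  list(histograms = do.call(rbind, c(out, list(make.row.names = FALSE))),
       bimodal = bi)
}

# Two local modes at least min_sep nt apart, each holding (with its +/-1 nt
# neighbourhood) more than min_share of the strand's weight.
is_bimodal <- function(lengths, weights, min_sep = 3L, min_share = 0.20) {
  if (length(lengths) < 2) return(FALSE)
  full <- rep(0, max(lengths) - min(lengths) + 1L)
  names(full) <- seq(min(lengths), max(lengths))
  full[as.character(lengths)] <- weights
  n <- length(full)
  pad <- c(0, full, 0)
  modes <- which(full >= pad[seq_len(n)] & full >= pad[seq_len(n) + 2L] &
                   full > 0)
  if (length(modes) < 2) return(FALSE)
  share <- vapply(modes, function(k)
    sum(full[max(1, k - 1):min(n, k + 1)]), numeric(1)) / sum(full)
  big <- modes[share > min_share]
  if (length(big) < 2) return(FALSE)
  pos <- as.integer(names(full)[big])
  max(pos) - min(pos) >= min_sep
}
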