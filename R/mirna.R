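# miRNA locus annotation from read stacks, following MirGeneDB-style
# structural and expression criteria: two read-supported arms forming a
# duplex within one hairpin, homogeneous mature 5' ends, 2-nt 3' overhangs
# at both duplex ends, a well-paired duplex, and a bounded precursor length.
# The criteria thresholds are explicit, configurable stand-ins for the
# conventional annotation values.

#' Criteria for miRNA locus acceptance
#'
#' @param min_mature_reads minimum weighted mature-arm read count.
#' @param min_homogeneity minimum weighted fraction of mature-arm reads
#'   sharing the modal 5' end.
#' @param overhang expected duplex 3' overhang (nt) at both ends.
#' @param overhang_tolerance admissible deviation from `overhang` (0 =
#'   strict; set 1 to allow 1--3 nt).
#' @param min_duplex_pairs minimum paired positions between the two arms.
#' @param min_loop minimum hairpin loop between the duplex arms.
#' @param max_precursor maximum precursor length (400 admits the long
#'   precursors, up to 386 nt, seen in flatworm-like complements).
#' @param fold_min_loop loop minimum used by the folding primitive.
#' @param max_bulge largest bulge skipped while extending the lower stem.
#' @return list of class `mirna_criteria`.
#' @export
mirna_criteria <- function(min_mature_reads = 10,
                           min_homogeneity = 0.9,
                           overhang = 2L,
                           overhang_tolerance = 0L,
                           min_duplex_pairs = 16L,
                           min_loop = 8L,
                           max_precursor = 400L,
                           fold_min_loop = 3L,
                           max_bulge = 2L) {
  structure(list(min_mature_reads = min_mature_reads,
                 min_homogeneity = min_homogeneity,
                 overhang = as.integer(overhang),
                 overhang_tolerance = as.integer(overhang_tolerance),
                 min_duplex_pairs = as.integer(min_duplex_pairs),
                 min_loop = as.integer(min_loop),
                 max_precursor = as.integer(max_precursor),
                 fold_min_loop = as.integer(fold_min_loop),
                 max_bulge = as.integer(max_bulge)),
            class = "mirna_criteria")
}

reject <- function(reason, detail = NULL) {
  structure(list(accepted = FALSE, reason = reason, detail = detail),
            class = "mirna_evaluation")
}

#' Evaluate a candidate window as a miRNA locus
#'
#' Applies the acceptance criteria in order and reports the first violated
#' one on rejection: (i) two read-supported arms forming a duplex within one
#' hairpin (with the loop between them at least `min_loop`); (ii) mature-arm
#' 5' homogeneity; (iii) duplex 3' overhangs at both ends; (iv) paired
#' positions within the duplex; (v) precursor length. The mature arm is the
#' higher-expressed arm. The precursor extent is found by extending the stem
#' outwards from the outermost duplex pair, skipping bulges up to
#' `max_bulge` nt.
#'
#' @param mappings mapping data.frame (one candidate window; single contig).
#' @param genome [Biostrings::DNAStringSet] or named character vector.
#' @param criteria a [mirna_criteria()].
#' @param family_table optional seed-family table for family assignment.
#' @return on acceptance, a list of class `mirna_evaluation` with
#'   `accepted = TRUE` and a one-row `locus` data.frame; on rejection,
#'   `accepted = FALSE` plus the `reason` (`"low_expression"`, `"no_star"`,
#'   `"truncated"`, `"no_duplex"`, `"five_prime_heterogeneity"`,
#'   `"overhang"`, `"insufficient_pairing"`, `"precursor_too_long"`).
#' @export
evaluate_locus <- function(mappings, genome, criteria = mirna_criteria(),
                           family_table = NULL) {
  if (!inherits(genome, "DNAStringSet"))
    genome <- Biostrings::DNAStringSet(genome)
  if (nrow(mappings) == 0) return(reject("no_reads"))
  if (length(unique(mappings$contig)) != 1)
    stop("evaluate_locus expects mappings on a single contig")
  contig <- mappings$contig[1]
  clen <- Biostrings::width(genome)[match(contig, names(genome))]
  w <- mapping_weight(mappings)

  # arms: merged overlapping same-strand read stacks
  arms <- arm_table(mappings, w)
  mature_arm <- arms[which.max(arms$weight), ]
  if (mature_arm$weight < criteria$min_mature_reads)
    return(reject("low_expression"))
  partners <- arms[arms$strand == mature_arm$strand &
                     !(arms$start == mature_arm$start &
                         arms$end == mature_arm$end), , drop = FALSE]
  if (nrow(partners) > 0) {
    gap <- pmax(partners$start - mature_arm$end,
                mature_arm$start - partners$end)
    partners <- partners[gap > 0 & gap <= criteria$max_precursor, ,
                         drop = FALSE]
  }
  if (nrow(partners) == 0) return(reject("no_star"))
  star_arm <- partners[which.max(partners$weight), ]
  strand <- mature_arm$strand

  span_start <- min(mature_arm$start, star_arm$start)
  span_end <- max(mature_arm$end, star_arm$end)
  ext <- criteria$max_precursor
  win_start <- span_start - ext
  win_end <- span_end + ext
  if (span_start < 3 || span_end > clen - 3)
    return(reject("truncated"))
  win_start <- max(0L, win_start)
  win_end <- min(clen, win_end)

  axis <- make_axis(genome, contig, win_start, win_end, strand)

  # modal reads of each arm
  modal_m <- modal_mapping(mappings, w, mature_arm)
  modal_s <- modal_mapping(mappings, w, star_arm)
  m_iv <- sort(c(axis$to(modal_m$five_prime), axis$to(modal_m$three_prime)))
  s_iv <- sort(c(axis$to(modal_s$five_prime), axis$to(modal_s$three_prime)))
  left <- if (m_iv[1] < s_iv[1]) m_iv else s_iv
  right <- if (m_iv[1] < s_iv[1]) s_iv else m_iv

  # (i) duplex within one hairpin
  span_axis <- sort(c(axis$to_span(span_start, span_end)))
  fold <- fold_hairpin(substr(axis$seq, span_axis[1], span_axis[2]),
                       min_loop = criteria$fold_min_loop, min_length = 10L)
  if (!fold$ok) return(reject("no_duplex"))
  pr <- fold$pairs
  pr[, 1] <- pr[, 1] + span_axis[1] - 1L
  pr[, 2] <- pr[, 2] + span_axis[1] - 1L
  dup <- pr[pr[, 1] >= left[1] & pr[, 1] <= left[2] &
              pr[, 2] >= right[1] & pr[, 2] <= right[2], , drop = FALSE]
  if (nrow(dup) == 0) return(reject("no_duplex"))
  if (min(dup[, 2]) - max(dup[, 1]) - 1L < criteria$min_loop)
    return(reject("no_duplex", detail = "loop below minimum"))

  # duplex register: best antiparallel alignment of the two arms
  # (robust to equal-score folding alternatives near the loop)
  reg <- duplex_register(axis$seq, left, right, criteria$overhang)

  # (ii) mature 5' homogeneity
  in_m <- mappings$strand == strand &
    mappings$start < mature_arm$end & mappings$end > mature_arm$start
  hom <- sum(w[in_m & mappings$five_prime == modal_m$five_prime]) /
    sum(w[in_m])
  if (hom < criteria$min_homogeneity)
    return(reject("five_prime_heterogeneity", detail = hom))

  # (iii) duplex 3' overhangs at both ends
  over_outer <- reg$outer
  over_inner <- reg$inner
  tol <- criteria$overhang_tolerance
  if (abs(over_outer - criteria$overhang) > tol ||
      abs(over_inner - criteria$overhang) > tol)
    return(reject("overhang", detail = c(outer = over_outer,
                                         inner = over_inner)))

  # (iv) paired positions within the duplex
  if (reg$n_pairs < criteria$min_duplex_pairs)
    return(reject("insufficient_pairing", detail = reg$n_pairs))

  # (v) precursor extent and length
  stem <- extend_stem(axis$seq, reg$i_out, reg$j_out, criteria$max_bulge,
                      criteria$max_precursor + 10L)
  stem <- c(min(stem[1], left[1]), max(stem[2], right[2]))
  prec_len <- stem[2] - stem[1] + 1L
  if (prec_len > criteria$max_precursor)
    return(reject("precursor_too_long", detail = prec_len))

  prec_g <- sort(c(axis$from(stem[1]), axis$from(stem[2])))
  mature_seq <- modal_m$seq
  fam <- if (!is.null(family_table))
    assign_family(mature_seq, family_table) else NULL
  locus <- data.frame(
    contig = contig, start = prec_g[1], end = prec_g[2] + 1L,
    strand = strand,
    mature_start = min(modal_m$start), mature_end = max(modal_m$end),
    star_start = min(modal_s$start), star_end = max(modal_s$end),
    mature_seq = mature_seq, star_seq = modal_s$seq,
    seed = substr(mature_seq, 2, 8),
    family = if (is.null(fam)) NA_character_ else
      paste(fam$families, collapse = ","),
    ambiguous = if (is.null(fam)) NA else fam$ambiguous,
    precursor_length = prec_len,
    mature_count = sum(w[in_m]),
    star_count = star_arm$weight,
    homogeneity = hom,
    overhang_outer = over_outer, overhang_inner = over_inner,
    duplex_pairs = reg$n_pairs,
    stringsAsFactors = FALSE)
  structure(list(accepted = TRUE, locus = locus),
            class = "mirna_evaluation")
}

# merged same-strand arms with weights
arm_table <- function(mappings, w) {
  out <- list()
  for (str in unique(mappings$strand)) {
    sel <- mappings$strand == str
    ir <- IRanges::IRanges(start = mappings$start[sel] + 1L,
                           end = mappings$end[sel])
    red <- IRanges::reduce(ir)
    hits <- IRanges::findOverlaps(ir, red)
    wt <- tapply(w[sel][S4Vectors::queryHits(hits)],
                 S4Vectors::subjectHits(hits), sum)
    out[[str]] <- data.frame(start = IRanges::start(red) - 1L,
                             end = IRanges::end(red),
                             strand = str,
                             weight = as.numeric(wt),
                             stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

modal_mapping <- function(mappings, w, arm) {
  sel <- which(mappings$strand == arm$strand &
                 mappings$start < arm$end & mappings$end > arm$start)
  sel <- sel[order(-w[sel], mappings$start[sel], mappings$seq[sel])]
  mappings[sel[1], ]
}

# Best antiparallel pairing register between the two arm intervals on the
# axis: positions i (left arm) and j (right arm) pair when i + j equals a
# constant; the register d is the number of right-arm 3' bases past the
# partner of the left arm's 5' base (d = 2 for a canonical Dicer duplex of
# equal-length arms). The register maximising the number of pairable
# positions wins; ties prefer the expected overhang, then the smaller d.
duplex_register <- function(seq, left, right, expected = 2L) {
  b <- strsplit(seq, "")[[1]]
  len_l <- left[2] - left[1] + 1L
  len_r <- right[2] - right[1] + 1L
  best <- NULL
  for (d in -8:12) {
    const <- left[1] + right[2] - d
    i <- left[1]:left[2]
    j <- const - i
    ok <- j >= right[1] & j <= right[2]
    if (!any(ok)) next
    n <- sum(base_pairable(b[i[ok]], b[j[ok]]))
    better <- is.null(best) || n > best$n_pairs ||
      (n == best$n_pairs &&
         (abs(d - expected) < abs(best$d - expected) ||
            (abs(d - expected) == abs(best$d - expected) && d < best$d)))
    if (better) {
      pi <- i[ok][base_pairable(b[i[ok]], b[j[ok]])]
      pj <- const - pi
      best <- list(d = d, n_pairs = n,
                   outer = d,
                   inner = d + len_l - len_r,
                   i_out = if (n > 0) min(pi) else left[1],
                   j_out = if (n > 0) max(pj) else right[2])
    }
  }
  best
}

# strand-oriented coordinate axis over a genomic window
make_axis <- function(genome, contig, win_start, win_end, strand) {
  seq <- substr(as.character(genome[[match(contig, names(genome))]]),
                win_start + 1L, win_end)
  if (strand == "-") seq <- revcomp(seq)
  to <- if (strand == "+") function(pos0) pos0 - win_start + 1L
  else function(pos0) win_end - pos0
  from <- if (strand == "+") function(q) q - 1L + win_start
  else function(q) win_end - q
  to_span <- if (strand == "+") function(s0, e0) c(to(s0), to(e0 - 1L))
  else function(s0, e0) c(to(e0 - 1L), to(s0))
  list(seq = seq, to = to, from = from, to_span = to_span)
}

# Walk outwards from the outermost duplex pair, pairing stacked bases and
# skipping bulges of at most `max_bulge` nt on either side. Returns the
# axis interval of the precursor.
extend_stem <- function(seq, lp, rp, max_bulge, max_len) {
  b <- strsplit(seq, "")[[1]]
  n <- length(b)
  combos <- expand.grid(a = 0:max_bulge, d = 0:max_bulge)
  combos <- combos[order(combos$a + combos$d, combos$a), , drop = FALSE]
  repeat {
    if (rp - lp + 1L > max_len) break
    advanced <- FALSE
    for (k in seq_len(nrow(combos))) {
      l2 <- lp - 1L - combos$a[k]
      r2 <- rp + 1L + combos$d[k]
      if (l2 < 1L || r2 > n) next
      if (base_pairable(b[l2], b[r2])) {
        lp <- l2; rp <- r2; advanced <- TRUE; break
      }
    }
    if (!advanced) break
  }
  c(lp, rp)
}

#' Discover miRNA loci across a genome
#'
#' Forms candidate windows from pairs of same-strand read arms lying within
#' one precursor length of each other, where at least one arm passes the
#' mature expression threshold, and evaluates each window with
#' [evaluate_locus()]. Overlapping accepted loci are deduplicated keeping
#' the higher-expressed one.
#'
#' @param mappings mapping data.frame from [map_reads()].
#' @param genome the genome the mappings refer to.
#' @param criteria a [mirna_criteria()].
#' @param family_table optional seed-family table.
#' @return list with `loci` (data.frame of accepted loci) and `rejections`
#'   (data.frame of evaluated-but-rejected windows and reasons).
#' @export
discover_mirna_loci <- function(mappings, genome,
                                criteria = mirna_criteria(),
                                family_table = NULL) {
  loci <- list(); rej <- list()
  if (nrow(mappings) > 0) {
    w <- mapping_weight(mappings)
    for (contig in unique(mappings$contig)) {
      csel <- mappings$contig == contig
      arms <- arm_table(mappings[csel, , drop = FALSE], w[csel])
      arms <- arms[order(arms$strand, arms$start), , drop = FALSE]
      for (str in unique(arms$strand)) {
        sa <- arms[arms$strand == str, , drop = FALSE]
        if (nrow(sa) < 2) next
        for (i in seq_len(nrow(sa) - 1L)) {
          for (j in (i + 1L):nrow(sa)) {
            gap <- sa$start[j] - sa$end[i]
            if (gap <= 0) next
            if (gap > criteria$max_precursor) break
            if (max(sa$weight[i], sa$weight[j]) < criteria$min_mature_reads)
              next
            lo <- sa$start[i]; hi <- sa$end[j]
            msel <- csel & mappings$strand == str &
              mappings$start >= lo & mappings$end <= hi
            ev <- evaluate_locus(mappings[msel, , drop = FALSE], genome,
                                 criteria, family_table)
            if (ev$accepted) {
              loci[[length(loci) + 1L]] <- ev$locus
            } else {
              rej[[length(rej) + 1L]] <-
                data.frame(contig = contig, start = lo, end = hi,
                           strand = str, reason = ev$reason,
                           stringsAsFactors = FALSE)
            }
          }
        }
      }
    }
  }
  loci <- if (length(loci)) do.call(rbind, loci) else NULL
  if (!is.null(loci)) {
    loci <- dedup_loci(loci)
    rownames(loci) <- NULL
  }
  rej <- if (length(rej)) do.call(rbind, rej) else
    data.frame(contig = character(0), start = integer(0),
               end = integer(0), strand = character(0),
               reason = character(0), stringsAsFactors = FALSE)
  list(loci = loci, rejections = rej)
}

dedup_loci <- function(loci) {
  o <- order(-loci$mature_count, loci$contig, loci$start)
  loci <- loci[o, , drop = FALSE]
  keep <- rep(TRUE, nrow(loci))
  for (i in seq_len(nrow(loci))) {
    if (!keep[i]) next
    for (j in seq_len(nrow(loci))) {
      if (i == j || !keep[j]) next
      same <- loci$contig[i] == loci$contig[j] &&
        loci$strand[i] == loci$strand[j] &&
        loci$start[j] < loci$end[i] && loci$end[j] > loci$start[i]
      if (same) keep[j] <- FALSE
    }
  }
  loci <- loci[keep, , drop = FALSE]
  loci[order(loci$contig, loci$start), , drop = FALSE]
}
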