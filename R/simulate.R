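# Synthetic small-RNA study generator: toy genomes with planted miRNA
# hairpins, unistrand and dual-strand (ping-pong + phased) piRNA clusters and
# tRNA/rRNA contaminant loci, plus simulated redundant read sets and a
# machine-readable truth set used as the recovery oracle.
#
# Internally the genome is a character vector of single bases (1-based); all
# public coordinates are 0-based half-open, strand "+"/"-".

#' Describe one planted feature
#'
#' Builds a feature specification for [simulation_config()]. Class-specific
#' parameters are passed via `...` and filled with defaults:
#' \describe{
#'   \item{unistrand_pirna_cluster}{`n_reads` (distinct piRNAs, default 40)}
#'   \item{dualstrand_pirna_cluster}{`responder_prob` (default 0.8),
#'     `phased` (default TRUE), `max_phase_gap` (default 4)}
#'   \item{mirna_locus / long_mirna_locus}{`family` (name in the seed table or
#'     NULL for a novel seed), `mature_length` (22), `loop_length` (8),
#'     `mature_copies` (100), `star_copies` (10), `homogeneity` (1.0),
#'     `precursor_length` (long loci only, default 386)}
#'   \item{trna / rrna}{`n_fragments` (default 25 / 35)}
#'   \item{te_copy / neutral}{no parameters}
#' }
#'
#' @param class feature class, one of `"unistrand_pirna_cluster"`,
#'   `"dualstrand_pirna_cluster"`, `"mirna_locus"`, `"long_mirna_locus"`,
#'   `"trna"`, `"rrna"`, `"te_copy"`, `"neutral"`.
#' @param length feature length in nt (for hairpin loci derived from the
#'   precursor geometry when omitted).
#' @param strand `"+"` or `"-"`; the main (precursor) strand. Dual-strand
#'   clusters transcribe their precursor from the minus strand and produce
#'   responders on the plus strand.
#' @param start optional fixed 0-based start; `NA` lays features out
#'   automatically with non-overlapping gaps.
#' @param ... class-specific parameters, see Details.
#' @return a list of class `feature_spec`.
#' @export
feature_spec <- function(class, length = NULL, strand = "+", start = NA, ...) {
  classes <- c("unistrand_pirna_cluster", "dualstrand_pirna_cluster",
               "mirna_locus", "long_mirna_locus", "trna", "rrna",
               "te_copy", "neutral")
  class <- match.arg(class, classes)
  p <- list(...)
  defaults <- switch(class,
    unistrand_pirna_cluster = list(n_reads = 40),
    dualstrand_pirna_cluster = list(responder_prob = 0.8, phased = TRUE,
                                    max_phase_gap = 4),
    mirna_locus = list(family = NULL, mature_length = 22, loop_length = 8,
                       mature_copies = 100, star_copies = 10,
                       homogeneity = 1.0),
    long_mirna_locus = list(family = NULL, mature_length = 22,
                            loop_length = 8, mature_copies = 100,
                            star_copies = 10, homogeneity = 1.0,
                            precursor_length = 386),
    trna = list(n_fragments = 25),
    rrna = list(n_fragments = 35),
    te_copy = list(),
    neutral = list())
  unknown <- setdiff(names(p), names(defaults))
  if (length(unknown) > 0)
    stop("unknown parameter(s) for class ", class, ": ",
         paste(unknown, collapse = ", "))
  p <- utils::modifyList(defaults, p)
  if (is.null(length)) {
    length <- switch(class,
      mirna_locus = 2 * p$mature_length + p$loop_length,
      long_mirna_locus = p$precursor_length,
      unistrand_pirna_cluster = 1200,
      dualstrand_pirna_cluster = 2200,
      trna = 75, rrna = 500, te_copy = 300, neutral = 1000)
  }
  if (class == "long_mirna_locus") {
    stem <- p$precursor_length - 2 * p$mature_length - p$loop_length
    if (stem <= 0 || stem %% 2 != 0)
      stop("long_mirna_locus precursor_length must leave a positive, ",
           "even lower-stem length")
    length <- p$precursor_length
  }
  if (class == "mirna_locus")
    length <- 2 * p$mature_length + p$loop_length
  if (class == "dualstrand_pirna_cluster") strand <- "-"
  structure(list(class = class, length = as.integer(length),
                 strand = strand, start = start, params = p),
            class = "feature_spec")
}

#' Default planted feature set
#'
#' Three unistrand piRNA clusters, one dual-strand ping-pong/phased cluster,
#' three canonical miRNA loci, one 386-nt long-precursor miRNA locus, two
#' tRNA and one rRNA contaminant locus, and one TE copy -- the locus
#' architecture the analysis modules are designed to recover.
#'
#' @return list of [feature_spec()] objects.
#' @export
default_features <- function() {
  list(
    feature_spec("unistrand_pirna_cluster", length = 1200, strand = "-",
                 n_reads = 45),
    feature_spec("unistrand_pirna_cluster", length = 800, strand = "-",
                 n_reads = 30),
    feature_spec("unistrand_pirna_cluster", length = 1600, strand = "+",
                 n_reads = 60),
    feature_spec("dualstrand_pirna_cluster", length = 2200),
    feature_spec("mirna_locus", family = "MIR-1"),
    feature_spec("mirna_locus", family = "MIR-1992"),
    feature_spec("mirna_locus", family = "BANTAM"),
    feature_spec("long_mirna_locus", family = "MIR-750",
                 precursor_length = 386),
    feature_spec("trna"),
    feature_spec("trna"),
    feature_spec("rrna"),
    feature_spec("te_copy")
  )
}

#' Simulation configuration
#'
#' All knobs of the synthetic-data generator. Defaults encode the study
#' conditions the analysis assumes: initiator piRNAs of 30--32 nt with a
#' strong (0.95) 5' uridine bias, responder piRNAs anchored 10 nt into an
#' initiator (so the 10A bias is inherited from the initiator 1U bias through
#' complementarity), a 50/50 responder length mix of 24--26 and 30--32 nt,
#' phased trailing piRNA production obeying the next-uridine rule, and
#' noise-free reads.
#'
#' @param seed integer RNG seed; fixed seed implies byte-identical outputs.
#' @param genome_length total genome length in nt.
#' @param gc_fraction background GC content in \[0,1\].
#' @param features list of [feature_spec()]; `default_features()` by default.
#' @param noise per-base substitution probability applied to read copies.
#' @param prob_5prime_U probability that an initiator (main-strand) piRNA 5'
#'   base is forced to U.
#' @param prob_10A probability that a responder position-10 base is A. In
#'   ping-pong geometry this base is the complement of the paired initiator's
#'   5' base, so the two biases share one genomic position; `NULL` (default)
#'   inherits `prob_5prime_U` at responder-anchored sites, a numeric value
#'   overrides it there.
#' @param initiator_lengths integer lengths sampled for initiator piRNAs.
#' @param responder_short_lengths,responder_long_lengths the two responder
#'   length modes.
#' @param responder_short_fraction mixing weight of the short responder mode.
#' @param copies_lambda Poisson rate for per-read copy counts
#'   (copies = 1 + Poisson(lambda)).
#' @param n_background_reads number of uniform-random background reads
#'   (18--35 nt) added to the library.
#' @param contig_name name of the single simulated contig.
#' @param family_table seed-family table used to give planted miRNA matures
#'   their family seed; defaults to the packaged table.
#' @return list of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              genome_length = 30000L,
                              gc_fraction = 0.5,
                              features = default_features(),
                              noise = 0,
                              prob_5prime_U = 0.95,
                              prob_10A = NULL,
                              initiator_lengths = 30:32,
                              responder_short_lengths = 24:26,
                              responder_long_lengths = 30:32,
                              responder_short_fraction = 0.5,
                              copies_lambda = 3,
                              n_background_reads = 200L,
                              contig_name = "chrS1",
                              family_table = NULL) {
  stopifnot(is.numeric(seed), length(seed) == 1,
            genome_length >= 100)
  for (f in list(gc_fraction, noise, prob_5prime_U,
                 responder_short_fraction)) {
    if (!is.numeric(f) || f < 0 || f > 1)
      stop("fractions must lie in [0, 1]")
  }
  if (!is.null(prob_10A) && (prob_10A < 0 || prob_10A > 1))
    stop("prob_10A must lie in [0, 1]")
  if (!all(vapply(features, inherits, logical(1), "feature_spec")))
    stop("features must be a list of feature_spec objects")
  structure(list(seed = as.integer(seed),
                 genome_length = as.integer(genome_length),
                 gc_fraction = gc_fraction, features = features,
                 noise = noise, prob_5prime_U = prob_5prime_U,
                 prob_10A = prob_10A,
                 initiator_lengths = as.integer(initiator_lengths),
                 responder_short_lengths = as.integer(responder_short_lengths),
                 responder_long_lengths = as.integer(responder_long_lengths),
                 responder_short_fraction = responder_short_fraction,
                 copies_lambda = copies_lambda,
                 n_background_reads = as.integer(n_background_reads),
                 contig_name = contig_name,
                 family_table = family_table),
            class = "simulation_config")
}

# One row of the read plan.
plan_row <- function(feature_id, contig, start0, end0, strand, copies) {
  data.frame(feature_id = feature_id, contig = contig,
             start = as.integer(start0), end = as.integer(end0),
             strand = strand, copies = as.integer(copies),
             stringsAsFactors = FALSE)
}

#' Simulate a genome with planted small-RNA features
#'
#' Draws an i.i.d. background genome at the configured GC content, lays the
#' planted features out with non-overlapping spacing (or at their fixed
#' starts), engineers each feature's sequence (hairpins whose arms are
#' reverse-complementary around a loop; cluster positions with biased 5'
#' bases; phased chains obeying the next-uridine rule) and records the full
#' read plan in the truth set.
#'
#' @param config a [simulation_config()].
#' @return list with elements `genome` (a [Biostrings::DNAStringSet]) and
#'   `truth` (class `srna_truth`: `$features`, `$read_plan`, `$references`,
#'   `$params`).
#' @export
simulate_genome <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, simulate_genome_impl(config))
}

simulate_genome_impl <- function(config) {
  L <- config$genome_length
  gc <- config$gc_fraction
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  g <- sample(BASES, L, replace = TRUE, prob = p)
  contig <- config$contig_name

  fam_tab <- config$family_table %||% read_seed_families()

  # Layout: honour fixed starts, then place the rest left to right.
  feats <- config$features
  n <- length(feats)
  starts1 <- ends1 <- integer(n)
  fixed <- which(!vapply(feats, function(f) is.na(f$start), logical(1)))
  occupied <- NULL
  for (i in fixed) {
    starts1[i] <- feats[[i]]$start + 1L
    ends1[i] <- starts1[i] + feats[[i]]$length - 1L
    if (starts1[i] < 5 || ends1[i] > L - 4)
      stop("feature ", i, " does not fit in the genome")
  }
  if (length(fixed) > 1) {
    o <- order(starts1[fixed])
    s <- starts1[fixed][o]; e <- ends1[fixed][o]
    if (any(s[-1] <= e[-length(e)]))
      stop("planted feature intervals overlap")
  }
  pos <- 1L
  for (i in setdiff(seq_len(n), fixed)) {
    gap <- sample(700:1200, 1)
    s1 <- pos + gap
    e1 <- s1 + feats[[i]]$length - 1L
    # skip over fixed features already occupying the range
    repeat {
      clash <- FALSE
      for (j in fixed) {
        if (s1 <= ends1[j] + 700L && e1 >= starts1[j] - 700L) {
          s1 <- ends1[j] + 700L + 1L
          e1 <- s1 + feats[[i]]$length - 1L
          clash <- TRUE
        }
      }
      if (!clash) break
    }
    if (e1 > L - 50L)
      stop("genome too short for the requested features (need > ", e1,
           " nt, have ", L, ")")
    starts1[i] <- s1; ends1[i] <- e1
    pos <- e1
  }

  plan <- list()
  features_df <- data.frame(
    feature_id = sprintf("feat%02d", seq_len(n)),
    class = vapply(feats, `[[`, character(1), "class"),
    contig = rep(contig, n),
    start = starts1 - 1L, end = ends1,
    strand = vapply(feats, `[[`, character(1), "strand"),
    stringsAsFactors = FALSE)
  references <- list(tRNA = character(0), rRNA = character(0),
                     mirna_precursor = character(0))
  mirna_truth <- list()

  for (i in seq_len(n)) {
    f <- feats[[i]]
    fid <- features_df$feature_id[i]
    s1 <- starts1[i]; e1 <- ends1[i]
    eng <- switch(f$class,
      unistrand_pirna_cluster =
        engineer_unistrand(g, s1, e1, f, config, fid, contig),
      dualstrand_pirna_cluster =
        engineer_dualstrand(g, s1, e1, f, config, fid, contig),
      mirna_locus = ,
      long_mirna_locus =
        engineer_mirna(g, s1, e1, f, config, fid, contig, fam_tab),
      trna = ,
      rrna = engineer_fragments(g, s1, e1, f, config, fid, contig),
      te_copy = list(g = g, plan = NULL),
      neutral = list(g = g, plan = NULL))
    g <- eng$g
    if (!is.null(eng$plan)) plan[[length(plan) + 1L]] <- eng$plan
    if (!is.null(eng$mirna)) mirna_truth[[fid]] <- eng$mirna
  }

  # contaminant reference sequences are the planted loci as finally written
  for (i in seq_len(n)) {
    cls <- feats[[i]]$class
    if (cls %in% c("trna", "rrna")) {
      key <- if (cls == "trna") "tRNA" else "rRNA"
      references[[key]] <- c(references[[key]],
                             paste(g[starts1[i]:ends1[i]], collapse = ""))
    }
    if (cls %in% c("mirna_locus", "long_mirna_locus")) {
      seq <- paste(g[starts1[i]:ends1[i]], collapse = "")
      if (feats[[i]]$strand == "-") seq <- revcomp(seq)
      references$mirna_precursor <- c(references$mirna_precursor, seq)
    }
  }

  plan <- if (length(plan)) do.call(rbind, plan) else
    plan_row(character(0), character(0), integer(0), integer(0),
             character(0), integer(0))[0, ]
  if (nrow(plan) > 0)
    plan$read_id <- sprintf("r%06d", seq_len(nrow(plan)))
  else plan$read_id <- character(0)
  plan <- plan[, c("read_id", "feature_id", "contig", "start", "end",
                   "strand", "copies")]

  genome <- Biostrings::DNAStringSet(setNames(paste(g, collapse = ""),
                                              contig))
  truth <- structure(list(features = features_df, read_plan = plan,
                          references = references,
                          mirna_loci = mirna_truth,
                          params = config),
                     class = "srna_truth")
  list(genome = genome, truth = truth)
}

# Unistrand cluster: stratified distinct read starts across the span, biased
# 5' bases forced into the genome so reads are exact genomic substrings.
engineer_unistrand <- function(g, s1, e1, f, config, fid, contig) {
  nr <- f$params$n_reads
  span <- e1 - s1 + 1L
  maxlen <- max(config$initiator_lengths)
  lens <- sample(config$initiator_lengths, nr, replace = TRUE)
  # one start per bin keeps inter-read gaps far below the cluster-merge gap
  bins <- floor(seq(s1, e1 - maxlen + 1L, length.out = nr + 1L))
  starts <- integer(nr)
  for (k in seq_len(nr)) {
    lo <- bins[k]; hi <- max(lo, bins[k + 1L] - 1L)
    starts[k] <- if (hi > lo) sample(lo:hi, 1) else lo
  }
  starts[1] <- s1
  starts[nr] <- e1 - lens[nr] + 1L
  forced <- stats::runif(nr) < config$prob_5prime_U
  for (k in seq_len(nr)) {
    if (!forced[k]) next
    if (f$strand == "+") g[starts[k]] <- "T"
    else g[starts[k] + lens[k] - 1L] <- "A" # minus-strand T
  }
  copies <- stats::rpois(nr, config$copies_lambda) + 1L
  list(g = g,
       plan = plan_row(fid, contig, starts - 1L, starts + lens - 1L,
                       f$strand, copies))
}

# Dual-strand cluster: a single phased chain of initiator piRNAs on the minus
# strand (each trailing read starting at the first uridine past the previous
# read's 3' end), with responder piRNAs planted antisense so that the
# 5'-5' overlap with their initiator is exactly 10 nt.
engineer_dualstrand <- function(g, s1, e1, f, config, fid, contig) {
  len <- e1 - s1 + 1L
  p <- f$params
  # transcript position t (1-based, minus strand 5'->3') <-> genome e1 - t + 1
  t2g <- function(t) e1 - t + 1L
  cur <- 1L + sample(0:3, 1)
  plans <- list()
  while (cur + max(config$initiator_lengths) <= len - 40L) {
    l <- sample(config$initiator_lengths, 1)
    gi5 <- t2g(cur)               # genomic index of the 5' base (1-based)
    gi3 <- t2g(cur + l - 1L)
    want_resp <- stats::runif(1) < p$responder_prob
    resp_len <- if (stats::runif(1) < config$responder_short_fraction)
      sample(config$responder_short_lengths, 1)
    else sample(config$responder_long_lengths, 1)
    resp_s <- gi5 - 9L            # plus-strand 5'
    resp_fits <- resp_s >= s1 && (resp_s + resp_len - 1L) <= e1
    p_force <- if (want_resp && resp_fits && !is.null(config$prob_10A))
      config$prob_10A else config$prob_5prime_U
    if (stats::runif(1) < p_force) g[gi5] <- "A" # minus-strand T / plus A
    plans[[length(plans) + 1L]] <-
      plan_row(fid, contig, gi3 - 1L, gi5, "-",
               stats::rpois(1, config$copies_lambda) + 1L)
    if (want_resp && resp_fits) {
      plans[[length(plans) + 1L]] <-
        plan_row(fid, contig, resp_s - 1L, resp_s + resp_len - 1L, "+",
                 stats::rpois(1, config$copies_lambda) + 1L)
    }
    if (p$phased) {
      gap <- sample(0:p$max_phase_gap, 1)
      if (gap > 0) {
        gpos <- t2g(cur + l + 0:(gap - 1L)) # gap bases: no minus-strand T
        hit <- g[gpos] == "A"
        if (any(hit)) g[gpos[hit]] <- sample(c("C", "G", "T"), sum(hit),
                                             replace = TRUE)
      }
      cur <- cur + l + gap
    } else {
      cur <- cur + l + sample(0:30, 1)
    }
  }
  list(g = g, plan = do.call(rbind, plans))
}

# Hairpin locus: precursor = [lower stem +] mature + loop + star [+ stem'],
# with the mature/star duplex showing 2-nt 3' overhangs at both ends.
# Non-pairable insulator bases flank the precursor so its structural extent
# is exactly the planted interval.
engineer_mirna <- function(g, s1, e1, f, config, fid, contig, fam_tab) {
  p <- f$params
  ml <- p$mature_length
  family <- p$family
  seed7 <- NULL
  if (!is.null(family)) {
    hit <- fam_tab$seed[match(family, fam_tab$family)]
    if (is.na(hit)) stop("family ", family, " not in the seed table")
    seed7 <- hit
  }
  mature <- if (is.null(seed7))
    random_dna(1, ml)
  else paste0(sample(BASES, 1), seed7,
              random_dna(1, ml - 8L))
  star20 <- revcomp(substr(mature, 1, ml - 2L))
  loop <- paste(rep_len(strsplit("ACCAACCA", "")[[1]], p$loop_length),
                collapse = "")
  long <- f$class == "long_mirna_locus"
  if (long) {
    stem_len <- (p$precursor_length - 2L * ml - p$loop_length) / 2L
    E <- strsplit(random_dna(1, stem_len), "")[[1]]
    E[1] <- "C"; E[stem_len] <- "C"; E[stem_len - 1L] <- "C"
    E <- paste(E, collapse = "")
    over <- "AA"  # cannot pair the forced C's at the stem top
    precursor <- paste0(E, mature, loop, star20, over, revcomp(E))
    off_m <- stem_len
  } else {
    over <- "CC"  # cannot pair the A insulators
    precursor <- paste0(mature, loop, star20, over)
    off_m <- 0L
  }
  stopifnot(nchar(precursor) == f$length)
  prec <- if (f$strand == "+") precursor else revcomp(precursor)
  g[s1:e1] <- strsplit(prec, "")[[1]]
  g[(s1 - 3L):(s1 - 1L)] <- "A"
  g[(e1 + 1L):(e1 + 3L)] <- "A"

  # genomic intervals of the mature and star reads (0-based half-open)
  prec_iv <- function(a, b) { # precursor positions [a,b] 1-based
    if (f$strand == "+") c(s1 + a - 2L, s1 + b - 1L)
    else c(e1 - b, e1 - a + 1L)
  }
  m_iv <- prec_iv(off_m + 1L, off_m + ml)
  s_iv <- prec_iv(off_m + ml + p$loop_length + 1L,
                  off_m + 2L * ml + p$loop_length)
  h <- p$homogeneity
  modal <- max(1L, round(h * p$mature_copies))
  rows <- list(plan_row(fid, contig, m_iv[1], m_iv[2], f$strand, modal))
  if (modal < p$mature_copies) {
    # 5'-heterogeneous matures: shifted one nt towards the loop
    shift <- if (f$strand == "+") 1L else -1L
    rows[[2]] <- plan_row(fid, contig, m_iv[1] + shift, m_iv[2] + shift,
                          f$strand, p$mature_copies - modal)
  }
  rows[[length(rows) + 1L]] <-
    plan_row(fid, contig, s_iv[1], s_iv[2], f$strand, p$star_copies)
  list(g = g, plan = do.call(rbind, rows),
       mirna = list(feature_id = fid, family = family,
                    mature = mature, precursor = precursor,
                    mature_interval = m_iv, star_interval = s_iv,
                    precursor_length = nchar(precursor)))
}

# tRNA/rRNA locus: background sequence; reads are random fragments.
engineer_fragments <- function(g, s1, e1, f, config, fid, contig) {
  nf <- f$params$n_fragments
  lens <- sample(26:35, nf, replace = TRUE)
  starts <- sample(s1:(e1 - 35L), nf, replace = TRUE)
  copies <- stats::rpois(nf, config$copies_lambda) + 1L
  list(g = g, plan = plan_row(fid, contig, starts - 1L, starts + lens - 1L,
                              "+", copies))
}

#' Simulate reads from a planted genome
#'
#' Emits the redundant (pre-collapsing) read multiset of the truth set's read
#' plan: every planned read is expanded to its copy count, sequences are
#' taken from the genome (reverse-complemented for minus-strand reads),
#' uniform substitution noise is applied per copy, and uniform-random
#' background reads are appended. Read-level truth attributes every read to
#' exactly one feature or to `"background"`.
#'
#' @param genome,truth output of [simulate_genome()].
#' @param config the same [simulation_config()] used for the genome.
#' @return list of class `srna_reads` with `reads` (named character vector)
#'   and `read_truth` (data.frame: read_id, source_read, feature_id).
#' @export
simulate_reads <- function(genome, truth, config) {
  stopifnot(inherits(truth, "srna_truth"),
            inherits(config, "simulation_config"))
  if (!identical(config$seed, truth$params$seed) ||
      !identical(length(config$features), length(truth$params$features)))
    stop("truth/config mismatch: the truth set was generated under a ",
         "different configuration")
  with_seed(derive_seed(config$seed, 1L), {
    gseq <- as.character(genome[[1]])
    plan <- truth$read_plan
    out_ids <- character(0); out_seqs <- character(0)
    out_src <- character(0); out_feat <- character(0)
    if (nrow(plan) > 0) {
      base_seq <- substring(gseq, plan$start + 1L, plan$end)
      minus <- plan$strand == "-"
      base_seq[minus] <- revcomp(base_seq[minus])
      for (k in seq_len(nrow(plan))) {
        cp <- plan$copies[k]
        seqs <- rep(base_seq[k], cp)
        if (config$noise > 0) seqs <- vapply(seqs, mutate_seq,
                                             character(1), config$noise)
        out_ids <- c(out_ids, sprintf("%s_c%d", plan$read_id[k],
                                      seq_len(cp)))
        out_seqs <- c(out_seqs, seqs)
        out_src <- c(out_src, rep(plan$read_id[k], cp))
        out_feat <- c(out_feat, rep(plan$feature_id[k], cp))
      }
    }
    nb <- config$n_background_reads
    if (nb > 0) {
      blens <- sample(18:35, nb, replace = TRUE)
      bseqs <- vapply(blens, function(l)
        paste(sample(BASES, l, replace = TRUE), collapse = ""), character(1))
      out_ids <- c(out_ids, sprintf("bg%05d_c1", seq_len(nb)))
      out_seqs <- c(out_seqs, bseqs)
      out_src <- c(out_src, sprintf("bg%05d", seq_len(nb)))
      out_feat <- c(out_feat, rep("background", nb))
    }
    structure(list(reads = setNames(out_seqs, out_ids),
                   read_truth = data.frame(read_id = out_ids,
                                           source_read = out_src,
                                           feature_id = out_feat,
                                           stringsAsFactors = FALSE)),
              class = "srna_reads")
  })
}

mutate_seq <- function(seq, noise) {
  b <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(b)) < noise)
  for (i in hit) b[i] <- sample(setdiff(BASES, b[i]), 1)
  paste(b, collapse = "")
}

#' Uniform-random reads
#'
#' Reads with independent, uniformly distributed bases -- the null model
#' under which the 5' uridine fraction is 25\% in expectation.
#'
#' @param n number of reads.
#' @param length read length in nt.
#' @param seed optional seed; `NULL` uses the current RNG state.
#' @return character vector of reads.
#' @export
simulate_uniform_reads <- function(n, length = 30L, seed = NULL) {
  gen <- function() {
    m <- matrix(sample(BASES, n * length, replace = TRUE), nrow = n)
    apply(m, 1, paste, collapse = "")
  }
  if (is.null(seed)) gen() else with_seed(seed, gen())
}

#' Genomic shotgun-style reads by tiling
#'
#' Deterministic tiling reads over a genome, used to exercise crystal-contig
#' assembly from genomic reads.
#'
#' @param genome a [Biostrings::DNAStringSet] or named character vector.
#' @param read_length read length in nt.
#' @param step distance between consecutive read starts.
#' @return named character vector of reads.
#' @export
simulate_genomic_reads <- function(genome, read_length = 100L, step = 40L) {
  if (inherits(genome, "DNAStringSet")) {
    seqs <- as.character(genome)
  } else seqs <- genome
  out <- character(0)
  for (nm in names(seqs)) {
    s <- seqs[[nm]]
    starts <- seq(1L, max(1L, nchar(s) - read_length + 1L), by = step)
    reads <- substring(s, starts, pmin(nchar(s), starts + read_length - 1L))
    names(reads) <- sprintf("%s_g%06d", nm, starts)
    out <- c(out, reads)
  }
  out
}
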