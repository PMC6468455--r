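# Configuration-driven end-to-end runs: simulate -> collapse -> filter ->
# map -> miRNA annotation -> piRNA detection -> report, with planted-truth
# recovery scoring when a truth set is available. Stage outputs are written
# in standard formats; the summary JSON contains only reproducible tallies
# (timings go to the log), so identical config + seed gives a byte-identical
# summary.

#' Pipeline configuration
#'
#' @param seed global seed, propagated to every stochastic stage.
#' @param outdir run directory (created if missing).
#' @param simulation a [simulation_config()]; its seed is overridden by
#'   `seed`.
#' @param cluster_params a [cluster_params()].
#' @param mirna_criteria a [mirna_criteria()].
#' @param stages named logical vector toggling `collapse`, `filter`, `map`,
#'   `mirna`, `pirna`, `score`.
#' @param max_mismatch_filter contaminant-subtraction mismatch allowance.
#' @param max_mismatch_map genome-mapping mismatch allowance.
#' @param log_level `"info"` or `"quiet"`.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            outdir = tempfile("srnaloci_run_"),
                            simulation = simulation_config(seed = seed),
                            cluster_params = srnaloci::cluster_params(),
                            mirna_criteria = srnaloci::mirna_criteria(),
                            stages = c(collapse = TRUE, filter = TRUE,
                                       map = TRUE, mirna = TRUE,
                                       pirna = TRUE, score = TRUE),
                            max_mismatch_filter = 3L,
                            max_mismatch_map = 0L,
                            log_level = "info") {
  simulation$seed <- as.integer(seed)
  structure(list(seed = as.integer(seed), outdir = outdir,
                 simulation = simulation, cluster_params = cluster_params,
                 mirna_criteria = mirna_criteria, stages = stages,
                 max_mismatch_filter = max_mismatch_filter,
                 max_mismatch_map = max_mismatch_map,
                 log_level = log_level),
            class = "pipeline_config")
}

#' Run the full pipeline
#'
#' Executes the enabled stages in order, writing each stage's outputs into
#' `config$outdir` (genome FASTA, reads FASTQ, truth GFF3/JSON, collapsed
#' FASTA, removal report TSV, mappings BED+TSV, miRNA locus GFF3/TSV,
#' cluster BED+TSV, profile TSVs) plus `summary.json` with per-stage
#' tallies. A stage failure raises a condition carrying the stage name;
#' outputs of completed stages are retained.
#'
#' @param config a [pipeline_config()].
#' @return the summary list, invisibly.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, recursive = TRUE, showWarnings = FALSE)
  logfile <- file.path(config$outdir, "run.log")
  log <- function(...) {
    msg <- paste0(format(Sys.time(), "%H:%M:%S"), " ", ...)
    cat(msg, "\n", file = logfile, append = TRUE)
    if (config$log_level != "quiet") message(msg)
  }
  summary <- list(seed = config$seed)
  stage <- function(name, enabled, fun) {
    if (!isTRUE(enabled)) { log("stage ", name, ": skipped"); return(NULL) }
    log("stage ", name, ": start")
    out <- tryCatch(fun(), error = function(e)
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE))
    log("stage ", name, ": done")
    out
  }

  sim <- stage("simulate", TRUE, function() {
    gt <- simulate_genome(config$simulation)
    reads <- simulate_reads(gt$genome, gt$truth, config$simulation)
    write_genome_fasta(gt$genome, file.path(config$outdir, "genome.fasta"))
    write_reads(reads$reads, file.path(config$outdir, "reads.fastq"))
    write_truth_gff3(gt$truth, file.path(config$outdir, "truth.gff3"))
    write_truth_json(gt$truth, file.path(config$outdir, "truth.json"))
    list(genome = gt$genome, truth = gt$truth, reads = reads)
  })
  summary$simulate <- list(
    genome_length = sum(Biostrings::width(sim$genome)),
    n_features = nrow(sim$truth$features),
    n_reads = length(sim$reads$reads))

  collapsed <- stage("collapse", config$stages[["collapse"]], function() {
    cr <- collapse_reads(sim$reads$reads)
    write_collapsed_fasta(cr, file.path(config$outdir, "collapsed.fasta"))
    cr
  })
  if (!is.null(collapsed))
    summary$collapse <- list(n_unique = nrow(collapsed),
                             total_copies = sum(collapsed$count))

  retained <- collapsed
  if (!is.null(collapsed) && isTRUE(config$stages[["filter"]])) {
    filt <- stage("filter", TRUE, function() {
      refs <- sim$truth$references
      refs <- refs[c("tRNA", "rRNA")]
      fl <- filter_annotated(collapsed, refs,
                             max_mismatch = config$max_mismatch_filter)
      write_collapsed_fasta(fl$retained,
                            file.path(config$outdir, "retained.fasta"))
      write.table(fl$removed[, c("seq", "count", "class")],
                  file.path(config$outdir, "removal_report.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      fl
    })
    retained <- filt$retained
    summary$filter <- list(n_retained = nrow(filt$retained),
                           n_removed = nrow(filt$removed))
  }

  mappings <- NULL
  if (!is.null(retained) && isTRUE(config$stages[["map"]])) {
    mappings <- stage("map", TRUE, function() {
      mp <- map_reads(retained, sim$genome,
                      max_mismatch = config$max_mismatch_map)
      write_mappings_bed(mp, file.path(config$outdir, "mappings.bed"))
      mp
    })
    summary$map <- list(n_mappings = nrow(mappings),
                        n_mapped_reads = length(unique(mappings$seq)))
  }

  mirna <- NULL
  if (!is.null(mappings) && isTRUE(config$stages[["mirna"]])) {
    mirna <- stage("mirna", TRUE, function() {
      res <- discover_mirna_loci(mappings, sim$genome,
                                 config$mirna_criteria,
                                 family_table = read_seed_families())
      write_mirna_outputs(res, config$outdir)
      res
    })
    summary$mirna <- list(
      n_loci = if (is.null(mirna$loci)) 0L else nrow(mirna$loci),
      n_rejected_windows = nrow(mirna$rejections))
  }

  pirna <- NULL
  if (!is.null(mappings) && isTRUE(config$stages[["pirna"]])) {
    pirna <- stage("pirna", TRUE, function() {
      mp <- mappings
      if (!is.null(mirna$loci) && nrow(mirna$loci) > 0) {
        # subtract reads arising from annotated miRNA precursors
        fl <- filter_annotated(
          unique(mp[, c("seq", "count")]),
          list(mirna_precursor = precursor_seqs(mirna$loci, sim$genome)),
          max_mismatch = config$max_mismatch_filter)
        mp <- mp[mp$seq %in% fl$retained$seq, , drop = FALSE]
      }
      te <- truth_te_annotation(sim$truth)
      det <- detect_clusters(mp, sim$genome, config$cluster_params,
                             te_annotation = te)
      write_cluster_outputs(det, config$outdir)
      write_profiles(det$clusters, sim$genome, config$outdir)
      det
    })
    summary$pirna <- list(n_clusters = nrow(pirna$clusters),
                          n_candidates = nrow(pirna$report))
  }

  if (isTRUE(config$stages[["score"]])) {
    calls <- call_table(mirna, pirna)
    rec <- stage("score", TRUE, function() {
      r <- score_recovery(calls, sim$truth)
      jsonlite::write_json(r["per_class"],
                           file.path(config$outdir, "recovery.json"),
                           auto_unbox = TRUE, digits = NA, na = "null")
      r
    })
    summary$score <- lapply(seq_len(nrow(rec$per_class)), function(i)
      as.list(rec$per_class[i, c("class", "n_truth", "n_calls",
                                 "matched", "precision", "recall")]))
  }

  jsonlite::write_json(summary, file.path(config$outdir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  log("pipeline complete")
  invisible(summary)
}

precursor_seqs <- function(loci, genome) {
  vapply(seq_len(nrow(loci)), function(i) {
    s <- substr(as.character(genome[[match(loci$contig[i],
                                           names(genome))]]),
                loci$start[i] + 1L, loci$end[i])
    if (loci$strand[i] == "-") revcomp(s) else s
  }, character(1))
}

truth_te_annotation <- function(truth) {
  te <- truth$features[truth$features$class == "te_copy", , drop = FALSE]
  if (nrow(te) == 0) return(NULL)
  te[, c("contig", "start", "end")]
}

write_mirna_outputs <- function(res, outdir) {
  loci <- res$loci
  tsv <- file.path(outdir, "mirna_loci.tsv")
  gff <- file.path(outdir, "mirna_loci.gff3")
  if (is.null(loci) || nrow(loci) == 0) {
    write.table(data.frame(), tsv, sep = "\t", quote = FALSE,
                row.names = FALSE)
    writeLines("##gff-version 3", gff)
    return(invisible(NULL))
  }
  write.table(loci, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  rows <- list()
  for (i in seq_len(nrow(loci))) {
    id <- sprintf("mir%03d", i)
    rows[[length(rows) + 1L]] <- data.frame(
      seqnames = loci$contig[i],
      start = c(loci$start[i], loci$mature_start[i],
                loci$star_start[i]) + 1L,
      end = c(loci$end[i], loci$mature_end[i], loci$star_end[i]),
      strand = loci$strand[i],
      type = c("pre_miRNA", "miRNA", "miRNA_star"),
      ID = c(id, paste0(id, ".mature"), paste0(id, ".star")),
      Parent = c(NA, id, id), stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, rows)
  gr <- GenomicRanges::GRanges(df$seqnames,
                               IRanges::IRanges(df$start, df$end),
                               strand = df$strand)
  S4Vectors::mcols(gr)$type <- df$type
  S4Vectors::mcols(gr)$ID <- df$ID
  S4Vectors::mcols(gr)$Parent <- df$Parent
  rtracklayer::export(gr, gff, format = "GFF3")
  invisible(NULL)
}

write_cluster_outputs <- function(det, outdir) {
  cl <- det$clusters
  write.table(det$report, file.path(outdir, "cluster_report.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  stats <- cl[, setdiff(names(cl), "members"), drop = FALSE]
  write.table(stats, file.path(outdir, "clusters.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  bed <- file.path(outdir, "clusters.bed")
  if (nrow(cl) == 0) { file.create(bed); return(invisible(NULL)) }
  gr <- GenomicRanges::GRanges(cl$contig,
                               IRanges::IRanges(cl$start + 1L, cl$end))
  S4Vectors::mcols(gr)$name <- cl$cluster_id
  S4Vectors::mcols(gr)$score <- round(cl$hits)
  rtracklayer::export(gr, bed, format = "BED")
  invisible(NULL)
}

write_profiles <- function(clusters, genome, outdir) {
  for (i in seq_len(nrow(clusters))) {
    id <- clusters$cluster_id[i]
    mem <- clusters$members[[i]]
    pp <- ping_pong_profile(mem)
    write.table(pp$histogram,
                file.path(outdir, sprintf("%s_pingpong.tsv", id)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    logo <- entropy_logo(mem)
    write.table(logo, file.path(outdir, sprintf("%s_logo.tsv", id)),
                sep = "\t", quote = FALSE, row.names = FALSE)
    lens <- strand_length_stats(mem)
    write.table(lens$histograms,
                file.path(outdir, sprintf("%s_lengths.tsv", id)),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(NULL)
}

call_table <- function(mirna, pirna) {
  rows <- list()
  if (!is.null(mirna$loci) && nrow(mirna$loci) > 0)
    rows[[1]] <- data.frame(class = "mirna_locus",
                            contig = mirna$loci$contig,
                            start = mirna$loci$start,
                            end = mirna$loci$end, stringsAsFactors = FALSE)
  if (!is.null(pirna) && nrow(pirna$clusters) > 0)
    rows[[length(rows) + 1L]] <-
      data.frame(class = "pirna_cluster", contig = pirna$clusters$contig,
                 start = pirna$clusters$start, end = pirna$clusters$end,
                 stringsAsFactors = FALSE)
  if (length(rows) == 0)
    return(data.frame(class = character(0), contig = character(0),
                      start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

# truth feature class -> call class
call_class <- function(truth_class) {
  c(unistrand_pirna_cluster = "pirna_cluster",
    dualstrand_pirna_cluster = "pirna_cluster",
    mirna_locus = "mirna_locus",
    long_mirna_locus = "mirna_locus")[truth_class]
}

#' Score feature calls against a planted truth set
#'
#' A call matches a planted feature of the same class when their interval
#' Jaccard index is at least `min_jaccard`; matching is one-to-one and
#' greedy by decreasing Jaccard (ties broken by truth feature order). The
#' report is invariant to the order of the calls.
#'
#' @param calls data.frame with columns `class` (`"mirna_locus"` /
#'   `"pirna_cluster"`), `contig`, `start`, `end` (0-based half-open).
#' @param truth an `srna_truth` (or its `$features` data.frame).
#' @param min_jaccard matching threshold.
#' @return list of class `recovery_report`: `per_class` (precision/recall
#'   per class; precision is `NA` for classes with no calls), `matched`,
#'   `missed`, `spurious`.
#' @export
score_recovery <- function(calls, truth, min_jaccard = 0.5) {
  feats <- if (inherits(truth, "srna_truth")) truth$features else truth
  feats$call_class <- call_class(feats$class)
  feats <- feats[!is.na(feats$call_class), , drop = FALSE]
  classes <- sort(unique(c(feats$call_class, calls$class)))
  per_class <- list(); matched <- list(); missed <- list(); spur <- list()
  for (cl in classes) {
    tr <- feats[feats$call_class == cl, , drop = FALSE]
    ca <- calls[calls$class == cl, , drop = FALSE]
    ca <- ca[order(ca$contig, ca$start, ca$end), , drop = FALSE]
    jac <- matrix(0, nrow(tr), nrow(ca))
    if (nrow(tr) > 0 && nrow(ca) > 0) {
      for (i in seq_len(nrow(tr))) for (j in seq_len(nrow(ca))) {
        if (tr$contig[i] != ca$contig[j]) next
        inter <- max(0L, min(tr$end[i], ca$end[j]) -
                       max(tr$start[i], ca$start[j]))
        uni <- max(tr$end[i], ca$end[j]) - min(tr$start[i], ca$start[j])
        jac[i, j] <- inter / uni
      }
    }
    pair <- list()
    J <- jac
    while (length(J) > 0 && max(J) >= min_jaccard) {
      k <- which(J == max(J), arr.ind = TRUE)
      k <- k[order(k[, 1], k[, 2]), , drop = FALSE][1, ]
      pair[[length(pair) + 1L]] <- c(k[1], k[2], J[k[1], k[2]])
      J[k[1], ] <- -1; J[, k[2]] <- -1
    }
    mt <- if (length(pair)) do.call(rbind, pair) else
      matrix(numeric(0), ncol = 3)
    n_m <- nrow(mt)
    per_class[[cl]] <- data.frame(
      class = cl, n_truth = nrow(tr), n_calls = nrow(ca), matched = n_m,
      precision = if (nrow(ca) > 0) n_m / nrow(ca) else NA_real_,
      recall = if (nrow(tr) > 0) n_m / nrow(tr) else NA_real_,
      stringsAsFactors = FALSE)
    if (n_m > 0)
      matched[[cl]] <- data.frame(
        class = cl, feature_id = tr$feature_id[mt[, 1]],
        call_start = ca$start[mt[, 2]], call_end = ca$end[mt[, 2]],
        jaccard = mt[, 3], stringsAsFactors = FALSE)
    mi <- setdiff(seq_len(nrow(tr)), mt[, 1])
    if (length(mi))
      missed[[cl]] <- tr[mi, c("feature_id", "class", "contig",
                               "start", "end"), drop = FALSE]
    sp <- setdiff(seq_len(nrow(ca)), mt[, 2])
    if (length(sp)) spur[[cl]] <- ca[sp, , drop = FALSE]
  }
  structure(list(per_class = do.call(rbind,
                                     c(per_class,
                                       list(make.row.names = FALSE))),
                 matched = if (length(matched)) do.call(rbind, matched)
                 else NULL,
                 missed = if (length(missed)) do.call(rbind, missed)
                 else NULL,
                 spurious = if (length(spur)) do.call(rbind, spur)
                 else NULL,
                 min_jaccard = min_jaccard),
            class = "recovery_report")
}
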