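test_that("collapsing tallies distinct sequences and conserves copies", {
  out <- collapse_reads(c("AAC", "AAC", "GGT"))
  expect_equal(out$seq, c("AAC", "GGT"))
  expect_equal(out$count, c(2L, 1L))
  expect_equal(sum(out$count), 3L)

  expect_equal(nrow(collapse_reads(character(0))), 0L)

  # U-alphabet reads are normalised to T; case folded
  out2 <- collapse_reads(c("aacu", "AACT"))
  expect_equal(out2$seq, "AACT")
  expect_equal(out2$count, 2L)
})

test_that("reads containing N are dropped with a warning", {
  expect_warning(out <- collapse_reads(c("ACGT", "ACNT", "ACGT")),
                 "dropped")
  expect_equal(out$count, 2L)
  expect_equal(sum(out$count), 2L)
})

test_that("length profiles total copies or distinct sequences", {
  cr <- collapse_reads(c(rep(strrep("A", 30), 5), strrep("C", 22)))
  by_copy <- length_profile(cr, "by_copy")
  expect_equal(by_copy$n[by_copy$length == 30], 5L)
  expect_equal(sum(by_copy$n), 6L)
  by_unique <- length_profile(cr, "by_unique")
  expect_equal(by_unique$n[by_unique$length == 30], 1L)
  expect_equal(sum(by_unique$n), 2L)
  expect_equal(nrow(length_profile(collapse_reads(character(0)))), 0L)
})

test_that("contaminant filtering honours the 3-mismatch boundary and partitions", {
  set.seed(41)
  ref <- random_seq(120)
  frag <- substr(ref, 31, 60)
  mutate_at <- function(s, k) {
    b <- strsplit(s, "")[[1]]
    for (i in seq_len(k)) {
      pos <- 1 + (i - 1) * 7
      b[pos] <- setdiff(c("A", "C", "G", "T"), b[pos])[1]
    }
    paste(b, collapse = "")
  }
  reads <- c(frag,                      # exact -> removed
             mutate_at(frag, 3),        # exactly 3 subs -> removed
             mutate_at(frag, 4),        # 4 subs -> retained
             revcomp(frag),             # antisense exact -> removed
             random_seq(30))            # unrelated -> retained
  cr <- collapse_reads(reads)
  fl <- filter_annotated(cr, list(tRNA = ref), max_mismatch = 3)
  expect_equal(nrow(fl$removed), 3L)
  expect_equal(unique(fl$removed$class), "tRNA")
  expect_equal(nrow(fl$retained), 2L)
  # partition: retained + removed = input, disjoint
  expect_setequal(c(fl$retained$seq, fl$removed$seq), cr$seq)
  expect_length(intersect(fl$retained$seq, fl$removed$seq), 0L)
  # removal report names the class that claimed the read
  classed <- filter_annotated(cr, list(rRNA = "GGGG", tRNA = ref))
  expect_true(all(classed$removed$class == "tRNA"))
})

test_that("mapping reports exact placements with strand-aware 5' ends", {
  set.seed(42)
  g <- random_seq(1000)
  read <- substr(g, 101, 130)     # 0-based offset 100
  mp <- map_reads(data.frame(seq = read, count = 1L), g)
  plus <- mp[mp$strand == "+", ]
  expect_true(any(plus$start == 100 & plus$mismatches == 0))
  expect_equal(plus$five_prime[plus$start == 100], 100L)

  rc <- revcomp(read)
  mp2 <- map_reads(data.frame(seq = rc, count = 1L), g)
  minus <- mp2[mp2$strand == "-", ]
  expect_true(any(minus$start == 100))
  expect_equal(minus$five_prime[minus$start == 100], 129L)
  expect_equal(minus$three_prime[minus$start == 100], 100L)

  absent <- map_reads(data.frame(seq = strrep("ACGT", 8), count = 1L),
                      strrep("A", 500))
  expect_equal(nrow(absent), 0L)
})

test_that("mapping equals a naive all-offset scan on small genomes", {
  set.seed(43)
  for (mm in c(0L, 1L, 2L)) {
    g <- random_seq(3000)
    reads <- c(substr(g, 501, 524), revcomp(substr(g, 1201, 1230)),
               random_seq(20), substr(g, 2001, 2022))
    cr <- collapse_reads(reads)
    mp <- map_reads(cr, setNames(g, "c1"), max_mismatch = mm)
    for (rs in cr$seq) {
      got <- mp[mp$seq == rs, c("start", "end", "strand", "mismatches")]
      got <- got[order(got$start, got$strand), ]
      rownames(got) <- NULL
      want <- naive_map_scan(rs, g, mm)
      rownames(want) <- NULL
      expect_equal(got, want, info = paste("mm =", mm))
    }
  }
})

test_that("mapping the reverse complement mirrors records with flipped strands", {
  set.seed(44)
  g <- random_seq(2000)
  read <- substr(g, 301, 328)
  a <- map_reads(data.frame(seq = read, count = 1L), g)
  b <- map_reads(data.frame(seq = revcomp(read), count = 1L), g)
  expect_equal(nrow(a), nrow(b))
  expect_equal(sort(a$start), sort(b$start))
  expect_equal(table(a$strand)[["+"]], table(b$strand)[["-"]])
})

test_that("multi-mappers report n_loci across all placements", {
  unit <- random_seq(40)
  g <- paste0(unit, strrep("C", 100), unit)
  mp <- map_reads(data.frame(seq = substr(unit, 5, 30), count = 6L), g)
  expect_true(all(mp$n_loci == nrow(mp)))
  expect_gte(nrow(mp), 2L)
})

test_that("crystal contigs merge anchored reads and only those", {
  set.seed(45)
  locus <- random_seq(200)
  small <- substr(locus, 90, 111)
  greads <- substring(locus, seq(1, 151, by = 10),
                      seq(1, 151, by = 10) + 49)
  out <- assemble_crystal_contigs(greads, small, min_overlap = 20)
  expect_equal(nrow(out), 1L)
  expect_true(grepl(small, out$seq[1], fixed = TRUE))
  # anchored reads are those fully containing the small read (71-120 and
  # 81-130 of the locus); their merge spans exactly that window
  expect_equal(out$seq[1], substr(locus, 71, 130))
  expect_equal(out$n_support[1], 2L)

  # no genomic read contains any small read -> empty, not an error
  none <- assemble_crystal_contigs(greads, strrep("ACGT", 8),
                                   min_overlap = 20)
  expect_equal(nrow(none), 0L)
})

test_that("disjoint anchored loci match the overlap-graph component oracle", {
  set.seed(46)
  for (rep in 1:3) {
    locus1 <- random_seq(150); locus2 <- random_seq(150)
    smalls <- c(substr(locus1, 60, 81), substr(locus2, 40, 63))
    gr <- c(substring(locus1, seq(1, 101, 25), seq(1, 101, 25) + 49),
            substring(locus2, seq(1, 101, 25), seq(1, 101, 25) + 49),
            replicate(5, random_seq(50)))  # unanchored noise
    out <- assemble_crystal_contigs(gr, smalls, min_overlap = 20)
    expect_equal(nrow(out),
                 crystal_component_count(gr, smalls, 20L))
    # soundness: every contig contains an anchoring small read exactly
    for (i in seq_len(nrow(out))) {
      anc <- out$anchors[[i]]
      expect_gt(length(anc), 0)
      rc <- revcomp(out$seq[i])
      expect_true(all(vapply(anc, function(s)
        grepl(s, out$seq[i], fixed = TRUE) || grepl(s, rc, fixed = TRUE),
        logical(1))))
    }
  }
})
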