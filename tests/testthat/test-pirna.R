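# Candidate cluster fixtures: distinct 1T 30-nt reads spread over a span.
even_cluster <- function(n = 25, span = 600, len = 30, counts = 4L) {
  starts <- round(seq(0, span - len, length.out = n))
  make_mappings(starts, len, "+", counts)
}

test_that("the printed criteria accept a well-formed cluster and name each violated filter", {
  set.seed(61)
  base <- even_cluster()
  det <- detect_clusters(base)
  expect_equal(nrow(det$clusters), 1L)
  expect_equal(det$clusters$strand_mode, "plus")
  expect_equal(det$clusters$start, 0L)
  expect_equal(det$clusters$end, 600L)

  # 19 hits: only the hit filter is cited
  few <- even_cluster(n = 19, counts = 1L)
  d19 <- detect_clusters(few)
  expect_equal(nrow(d19$clusters), 0L)
  expect_equal(d19$report$failed, "min_hits")

  # 20 hits: accepted ("a minimum of 20")
  d20 <- detect_clusters(even_cluster(n = 20, counts = 1L))
  expect_equal(nrow(d20$clusters), 1L)

  # one sequence carrying ~80% of the weight: evenness is cited
  skew <- even_cluster(n = 25, counts = 1L)
  skew$count[1] <- 96L   # 96 / 120 = 80%
  dsk <- detect_clusters(skew)
  expect_equal(nrow(dsk$clusters), 0L)
  expect_equal(dsk$report$failed, "evenness")

  # half the sequences 18 nt: the size-range filter is cited
  dsh <- detect_clusters(rbind(even_cluster(n = 15, counts = 2L),
                               make_mappings(round(seq(5, 560, length.out = 15)),
                                             18, "+", 2L)))
  expect_equal(nrow(dsh$clusters), 0L)
  expect_match(dsh$report$failed, "size_range")
})

test_that("strict inequalities hold exactly at the printed boundaries", {
  set.seed(62)
  # span exactly 500 passes ("at least 500 bp"); 499 fails
  at500 <- even_cluster(n = 25, span = 500)
  expect_equal(nrow(detect_clusters(at500)$clusters), 1L)
  at499 <- even_cluster(n = 25, span = 499)
  d499 <- detect_clusters(at499)
  expect_equal(nrow(d499$clusters), 0L)
  expect_equal(d499$report$failed, "min_length")

  # size fraction exactly 75% fails (strict >)
  m <- rbind(even_cluster(n = 15, counts = 1L),
             make_mappings(round(seq(5, 560, length.out = 5)), 18, "+", 1L))
  dsz <- detect_clusters(m)
  expect_equal(dsz$report$size_fraction, 0.75)
  expect_equal(nrow(dsz$clusters), 0L)

  # bias fraction exactly 75% fails (strict >)
  biased <- even_cluster(n = 15, counts = 1L)          # 1T reads
  unbiased <- make_mappings(round(seq(3, 550, length.out = 5)), 30, "+", 1L)
  unbiased$seq <- vapply(seq_len(5), function(i)
    paste0("C", random_seq(8), "C", random_seq(20)), character(1))
  dbias <- detect_clusters(rbind(biased, unbiased))
  expect_equal(dbias$report$bias_or, 0.75)
  expect_equal(nrow(dbias$clusters), 0L)
  expect_equal(dbias$report$failed, "bias")

  # evenness share exactly 75% fails (strict <)
  ten <- even_cluster(n = 10, counts = 1L)
  ten$count[1] <- 27L   # top 10% = 1 sequence; 27 / 36 = 75%
  dev <- detect_clusters(ten)
  expect_equal(dev$report$evenness_share, 0.75)
  expect_equal(nrow(dev$clusters), 0L)
  expect_equal(dev$report$failed, "evenness")
})

test_that("strand mode reflects the minority-strand weight share", {
  set.seed(63)
  minus <- make_mappings(round(seq(0, 570, length.out = 20)), 30, "-", 8L)
  plus_big <- make_mappings(round(seq(10, 560, length.out = 6)), 30, "+", 8L)
  dual <- detect_clusters(rbind(minus, plus_big))$clusters
  expect_equal(dual$strand_mode, "dual")   # minority 23% > 10%

  plus_small <- make_mappings(c(100L, 300L), 30, "+", 1L)
  uni <- detect_clusters(rbind(minus, plus_small))$clusters
  expect_equal(uni$strand_mode, "minus")   # minority ~1%
})

test_that("cluster statistics are invariant to relabeling and count scaling", {
  set.seed(64)
  m <- even_cluster(n = 30, counts = sample(1:6, 30, replace = TRUE))
  d1 <- detect_clusters(m)$clusters
  shuffled <- m[sample(nrow(m)), ]
  d2 <- detect_clusters(shuffled)$clusters
  expect_equal(d1$bias_1t, d2$bias_1t)
  expect_equal(d1$evenness_share, d2$evenness_share)
  scaled <- m; scaled$count <- scaled$count * 7L
  d3 <- detect_clusters(scaled)$clusters
  expect_equal(d1$bias_1t, d3$bias_1t)
  expect_equal(d1$evenness_share, d3$evenness_share)
  expect_equal(d1$size_fraction, d3$size_fraction)
})

test_that("positional base bias weights reads and flags undefined positions", {
  allT <- data.frame(seq = c("TAAA", "TCCC"), count = c(3L, 1L))
  expect_equal(base_bias(allT, 1, "T"), 1.0)
  mixed <- data.frame(seq = c("TAAA", "CAAA"), count = c(3L, 1L))
  expect_equal(base_bias(mixed, 1, "T"), 0.75)
  # reads shorter than the position leave the denominator
  mix_len <- data.frame(seq = c("TAAAAAAAAA", "CCC"), count = c(1L, 50L))
  expect_equal(base_bias(mix_len, 10, "A"), 1.0)
  # no contributing reads: undefined, flagged as NA
  expect_true(is.na(base_bias(data.frame(seq = "ACGTACGTA", count = 2L),
                              10, "A")))
})

test_that("entropy logos hit the analytic anchors", {
  allA <- data.frame(seq = rep("AA", 4), count = 1L)
  lg <- entropy_logo(allA, positions = 1)
  expect_equal(unique(lg$info), 2)
  expect_equal(lg$height[lg$base == "A"], 2)

  unif <- data.frame(seq = c("A", "C", "G", "T"), count = 1L)
  expect_equal(unique(entropy_logo(unif, positions = 1)$info), 0)

  half <- data.frame(seq = c("A", "T"), count = c(2L, 2L))
  expect_equal(unique(entropy_logo(half, positions = 1)$info), 1)

  # information is always within [0, 2] bits
  set.seed(65)
  rnd <- data.frame(seq = replicate(30, random_seq(sample(8:12, 1))),
                    count = sample(1:5, 30, TRUE))
  lg2 <- entropy_logo(rnd)
  expect_true(all(lg2$info >= 0 & lg2$info <= 2))
})

test_that("ping-pong overlaps follow the 5'-5' arithmetic", {
  plus <- make_mappings(100L, 24L, "+")
  minus <- make_mappings(86L, 24L, "-")   # 5' at 109
  pp <- ping_pong_profile(rbind(plus, minus))
  expect_equal(pp$modal_overlap, 10L)
  expect_equal(pp$n_pairs, 1L)
  expect_equal(pp$histogram$weight[pp$histogram$overlap == 10], 1)

  # unistrand: empty histogram, no modal value
  uni <- ping_pong_profile(even_cluster(n = 10))
  expect_equal(uni$n_pairs, 0L)
  expect_true(is.na(uni$modal_overlap))
  expect_true(all(uni$histogram$weight == 0))
})

test_that("ping-pong histograms equal the brute-force pairing on small sets", {
  set.seed(66)
  for (r in 1:4) {
    n <- sample(10:50, 1)
    strands <- sample(c("+", "-"), n, replace = TRUE)
    m <- make_mappings(sample(0:400, n), sample(24:32, n, TRUE), strands,
                       counts = sample(1:5, n, TRUE))
    m$n_loci <- sample(1:3, n, replace = TRUE)
    pp <- ping_pong_profile(m, max_overlap = 32L)
    expect_equal(pp$histogram$weight, brute_pingpong(m, 32L))
  }
})

test_that("phasing profiles record gaps, uridine starts and the next-U rule", {
  g <- Biostrings::DNAStringSet(c(chrT = paste0(
    strrep("C", 100),
    "TACGACGACG",        # read 1: 100..109 (gap 0 to next)
    "TGGGGGGGGG",        # read 2: 110..119
    strrep("C", 200))))
  m <- make_mappings(c(100L, 110L), 10L, "+",
                     seqs = c("TACGACGACG", "TGGGGGGGGG"))
  ph <- phasing_profile(m, g, "+")
  expect_equal(ph$n_pairs, 1L)
  expect_equal(ph$histogram$gap, 0L)
  expect_equal(ph$u_fraction, 1.0)
  expect_equal(ph$rule_fraction, 1.0)

  single <- phasing_profile(make_mappings(100L, 10L, "+"), g, "+")
  expect_equal(single$n_pairs, 0L)

  # a uridine inside the gap breaks the next-U rule
  g2 <- Biostrings::DNAStringSet(c(chrT = paste0(
    strrep("C", 100), "TACGACGACG", "CTC", "TGGGGGGGGG",
    strrep("C", 200))))
  m2 <- make_mappings(c(100L, 113L), 10L, "+",
                      seqs = c("TACGACGACG", "TGGGGGGGGG"))
  ph2 <- phasing_profile(m2, g2, "+")
  expect_equal(ph2$u_fraction, 1.0)     # next 5' is U...
  expect_equal(ph2$rule_fraction, 0.0)  # ...but not the first U past the 3'
})

test_that("strand length distributions flag responder-style bimodality", {
  set.seed(67)
  minus <- make_mappings(round(seq(0, 1500, length.out = 40)),
                         sample(30:32, 40, TRUE), "-", 4L)
  resp_short <- make_mappings(round(seq(5, 700, length.out = 12)),
                              sample(24:26, 12, TRUE), "+", 4L)
  resp_long <- make_mappings(round(seq(750, 1450, length.out = 12)),
                             sample(30:32, 12, TRUE), "+", 4L)
  sl <- strand_length_stats(rbind(minus, resp_short, resp_long))
  expect_false(sl$bimodal[["-"]])
  expect_true(sl$bimodal[["+"]])

  only_minus <- strand_length_stats(make_mappings(c(0L, 50L), 30L, "-"))
  expect_false(only_minus$bimodal[["+"]])
  expect_equal(unique(only_minus$histograms$strand), "-")
})
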