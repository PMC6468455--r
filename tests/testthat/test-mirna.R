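# Shared fixture: a genome with one canonical miRNA locus and its mappings.
mirna_fixture <- function(seed = 21L, homogeneity = 1.0,
                          mature_copies = 100, star_copies = 10,
                          class = "mirna_locus", family = "MIR-1992", ...) {
  cfg <- simulation_config(
    seed = seed, genome_length = 4000L,
    features = list(feature_spec(class, family = family,
                                 homogeneity = homogeneity,
                                 mature_copies = mature_copies,
                                 star_copies = star_copies, ...)),
    n_background_reads = 0L)
  gt <- simulate_genome(cfg)
  rd <- simulate_reads(gt$genome, gt$truth, cfg)
  mp <- map_reads(collapse_reads(rd$reads), gt$genome)
  list(cfg = cfg, gt = gt, mappings = mp)
}

test_that("a planted canonical locus is accepted with the expected geometry", {
  fx <- mirna_fixture()
  ev <- evaluate_locus(fx$mappings, fx$gt$genome,
                       family_table = read_seed_families())
  expect_true(ev$accepted)
  loc <- ev$locus
  expect_equal(loc$overhang_outer, 2)
  expect_equal(loc$overhang_inner, 2)
  expect_gte(loc$duplex_pairs, 16)
  expect_equal(loc$homogeneity, 1.0)
  expect_equal(loc$family, "MIR-1992")
  truth <- fx$gt$truth$features
  expect_equal(loc$start, truth$start)
  expect_equal(loc$end, truth$end)
})

test_that("removing star reads rejects the locus as lacking a star arm", {
  fx <- mirna_fixture()
  info <- fx$gt$truth$mirna_loci$feat01
  star_only_mature <- fx$mappings[
    fx$mappings$start < info$star_interval[1] |
      fx$mappings$end > info$star_interval[2], , drop = FALSE]
  ev <- evaluate_locus(star_only_mature, fx$gt$genome)
  expect_false(ev$accepted)
  expect_equal(ev$reason, "no_star")
})

test_that("a planted long-hairpin locus is accepted at its full precursor length", {
  fx <- mirna_fixture(class = "long_mirna_locus", family = "MIR-750",
                      precursor_length = 386)
  ev <- evaluate_locus(fx$mappings, fx$gt$genome)
  expect_true(ev$accepted)
  expect_equal(ev$locus$precursor_length, 386L)
  # and it is rejected when the precursor cap sits below it
  strict <- mirna_criteria(max_precursor = 300)
  ev2 <- evaluate_locus(fx$mappings, fx$gt$genome, strict)
  expect_false(ev2$accepted)
  expect_equal(ev2$reason, "precursor_too_long")
})

test_that("heterogeneous mature 5' ends are rejected at the homogeneity gate", {
  fx <- mirna_fixture(homogeneity = 0.5, mature_copies = 100)
  ev <- evaluate_locus(fx$mappings, fx$gt$genome)
  expect_false(ev$accepted)
  expect_equal(ev$reason, "five_prime_heterogeneity")
})

test_that("low mature expression is rejected before structural checks", {
  fx <- mirna_fixture(mature_copies = 5, star_copies = 2)
  ev <- evaluate_locus(fx$mappings, fx$gt$genome)
  expect_false(ev$accepted)
  expect_equal(ev$reason, "low_expression")
})

test_that("adding mature reads at the modal 5' end never revokes acceptance", {
  fx <- mirna_fixture()
  ev <- evaluate_locus(fx$mappings, fx$gt$genome)
  expect_true(ev$accepted)
  mp <- fx$mappings
  mature_row <- which(mp$count == max(mp$count))[1]
  for (extra in c(10L, 100L, 1000L)) {
    mp2 <- mp
    mp2$count[mature_row] <- mp2$count[mature_row] + extra
    ev2 <- evaluate_locus(mp2, fx$gt$genome)
    expect_true(ev2$accepted, info = paste("extra =", extra))
  }
})

test_that("windows at the contig edge are rejected as truncated", {
  fx <- mirna_fixture()
  mp <- fx$mappings
  shift <- min(mp$start) - 1L
  mp$start <- mp$start - shift; mp$end <- mp$end - shift
  mp$five_prime <- mp$five_prime - shift
  mp$three_prime <- mp$three_prime - shift
  ev <- evaluate_locus(mp, fx$gt$genome)
  expect_false(ev$accepted)
  expect_equal(ev$reason, "truncated")
})

test_that("minus-strand loci are annotated symmetrically", {
  fx <- mirna_fixture(strand = "-")
  ev <- evaluate_locus(fx$mappings, fx$gt$genome,
                       family_table = read_seed_families())
  expect_true(ev$accepted)
  expect_equal(ev$locus$strand, "-")
  expect_equal(ev$locus$overhang_outer, 2)
  expect_equal(ev$locus$family, "MIR-1992")
})

test_that("family assignment is a pure function of mature positions 2-8", {
  tab <- read_seed_families()
  seed1992 <- tab$seed[tab$family == "MIR-1992"]
  mature <- paste0("T", seed1992, "ACGTACGTACGTAC")
  out <- assign_family(mature, tab)
  expect_equal(out$families, "MIR-1992")
  expect_false(out$ambiguous)
  # only positions 2-8 matter
  mature2 <- paste0("G", seed1992, "GGGGGGGGGGGGGG")
  expect_equal(assign_family(mature2, tab)$families, "MIR-1992")

  novel <- assign_family(paste0("TAAAAAAT", strrep("C", 14)), tab)
  expect_true(novel$novel)
  expect_equal(novel$families, "novel")

  dup <- rbind(tab, data.frame(family = "MIR-TEST", seed = seed1992,
                               node = "Bilateria"))
  amb <- assign_family(mature, dup)
  expect_true(amb$ambiguous)
  expect_setequal(amb$families, c("MIR-1992", "MIR-TEST"))
})

test_that("complement census counts match a brute-force recount", {
  tab <- read_seed_families()
  bilat <- tab$family[tab$node == "Bilateria"]
  full <- presence_absence_matrix(list(tx1 = bilat, tx2 = character(0)),
                                  tab)
  cen <- complement_census(full, tab)
  row1 <- cen[cen$taxon == "tx1" & cen$node == "Bilateria", ]
  expect_equal(row1$present, 31L)
  expect_equal(row1$total, 31L)
  expect_equal(row1$absent[[1]], character(0))
  row2 <- cen[cen$taxon == "tx2" & cen$node == "Bilateria", ]
  expect_equal(row2$present, 0L)
  expect_equal(length(row2$absent[[1]]), 31L)

  set.seed(22)
  for (r in 1:5) {
    pres <- sample(tab$family, sample(0:49, 1))
    m <- presence_absence_matrix(list(tx = pres), tab)
    cen <- complement_census(m, tab)
    for (nd in unique(tab$node)) {
      fams <- tab$family[tab$node == nd]
      expect_equal(cen$present[cen$node == nd], sum(fams %in% pres))
      expect_setequal(cen$absent[cen$node == nd][[1]],
                      setdiff(fams, pres))
    }
  }
})

test_that("family complement differences count the symmetric difference", {
  tab <- read_seed_families()
  flatworm <- lineage_complement(tab, c("Eumetazoa", "Bilateria",
                                        "Protostomia", "Spiralia"))
  nematode <- lineage_complement(tab, c("Eumetazoa", "Bilateria",
                                        "Protostomia", "Ecdysozoa",
                                        "Nematoda"))
  d <- family_set_difference(flatworm, nematode)
  expect_equal(d$count, 6L)
  expect_setequal(d$families, c("MIR-1989", "MIR-1992", "MIR-305",
                                "MIR-54", "MIR-86", "MIR-791"))
  expect_equal(family_set_difference(flatworm, flatworm)$count, 0L)
  expect_equal(family_set_difference(c("a", "b"),
                                     c("c", "d", "e"))$count, 5L)
})
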