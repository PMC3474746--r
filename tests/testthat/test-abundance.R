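# Coverage counting, genome-size normalization, taxon aggregation,
# observed-vs-expected correlation.

mk_aln <- function(qname, mate, ref_id, cigar, pos = 1L)
  mg_alignments(qname, mate = mate, ref_id = ref_id, pos = pos, strand = "+",
                cigar = cigar, nm = 0L)

test_that("coverage counts bases, reads and inserts per reference", {
  refs <- mg_refs(c(a = rand_seq(100), b = rand_seq(200)))
  aln <- mk_aln("r1", 0L, "a", "50M")
  cov <- calculate_coverage(aln, refs)
  expect_equal(cov$base_coverage[cov$ref_id == "a"], 0.5)
  expect_equal(cov$read_count, c(1L, 0L))
  expect_equal(cov$insert_count, c(1L, 0L))
  # both mates of a pair on one reference: 2 reads, 1 insert
  pair <- mk_aln(c("p1", "p1"), c(1L, 2L), "a", "40M", c(1L, 61L))
  cov2 <- calculate_coverage(pair, refs)
  expect_equal(cov2$read_count[1], 2L)
  expect_equal(cov2$insert_count[1], 1L)
  expect_equal(cov2$base_count[1], 80)
  # unknown reference errors
  expect_error(calculate_coverage(mk_aln("r", 0L, "zzz", "10M"), refs), "zzz")
  # no alignments: zero rows flagged
  cov0 <- calculate_coverage(mk_aln(character(), integer(), character(), character()), refs)
  expect_true(all(cov0$read_count == 0))
  expect_true(isTRUE(attr(cov0, "empty")))
})

test_that("base counts are conserved from alignments to coverage rows", {
  cm <- simulate_community(n_genomes = 3, genome_length = 20000, seed = 51)
  sr <- simulate_reads(cm, n_pairs = 800, seed = 52)
  reads <- rbind(sr$pair1, sr$pair2)
  class(reads) <- c("mg_reads", "data.frame")
  aln <- map_reads(reads, build_index(cm$genomes))
  fa <- filter_apply(aln, filter_alignments(aln))
  cov <- calculate_coverage(fa, cm$genomes)
  expect_equal(sum(cov$base_count), sum(aligned_length(fa)))
  expect_equal(sum(cov$read_count), nrow(fa))
  expect_true(all(cov$insert_count <= cov$read_count))
})

test_that("genome normalization divides by summed replicon length", {
  refs <- mg_refs(c(chr1 = rand_seq(1000), chr2 = rand_seq(2000)))
  aln <- mk_aln(paste0("r", 1:20), 0L, rep(c("chr1", "chr2"), each = 10), "50M")
  cov <- calculate_coverage(aln, refs)
  # two genomes, lengths 1000 and 2000, equal read counts -> 2/3 vs 1/3
  ab <- genome_normalize(cov, NULL, "read")
  expect_equal(ab$relative[ab$group == "chr1"], 2 / 3)
  expect_equal(ab$relative[ab$group == "chr2"], 1 / 3)
  expect_equal(sum(ab$relative), 1, tolerance = 1e-9)
  # both replicons in one genome -> single row of 1
  gm <- data.frame(ref_id = c("chr1", "chr2"), genome_id = "g")
  ab1 <- genome_normalize(cov, gm, "read")
  expect_equal(ab1$relative, 1)
  expect_equal(ab1$length, 3000)
  expect_error(genome_normalize(cov, gm[1, ], "read"), "chr2")
})

test_that("uniform 1x base coverage gives equal abundances regardless of length", {
  lens <- c(1000L, 2000L, 4000L)
  refs <- mg_refs(setNames(vapply(lens, rand_seq, ""), c("g1", "g2", "g3")))
  # one synthetic alignment per genome covering it fully = 1x base coverage
  aln <- mk_aln(paste0("r", 1:3), 0L, c("g1", "g2", "g3"),
                paste0(lens, "M"))
  ab <- genome_normalize(calculate_coverage(aln, refs), NULL, "base")
  expect_equal(ab$relative, rep(1 / 3, 3))
})

test_that("taxon aggregation sums fractions and keeps them normalized", {
  ab <- structure(data.frame(group = c("s1", "s2", "s3"),
                             raw_count = c(2, 3, 5), length = c(1, 1, 1),
                             normalized = c(0.2, 0.3, 0.5),
                             relative = c(0.2, 0.3, 0.5)),
                  class = c("abundance_table", "data.frame"))
  tm <- data.frame(genome_id = c("s1", "s2", "s3"),
                   taxon = c("spA", "spA", "spB"))
  tx <- aggregate_by_taxon(ab, tm)
  expect_equal(tx$relative[tx$group == "spA"], 0.5)
  expect_equal(sum(tx$relative), 1)
  # identity map leaves the table unchanged
  idm <- data.frame(genome_id = ab$group, taxon = ab$group)
  expect_equal(aggregate_by_taxon(ab, idm)$relative, ab$relative)
  # all one genus -> single row of 1
  one <- data.frame(genome_id = ab$group, taxon = "genus")
  expect_equal(aggregate_by_taxon(ab, one)$relative, 1)
  expect_error(aggregate_by_taxon(ab, tm[1:2, ]), "s3")
})

test_that("correlations match the closed-form definitions", {
  tab <- function(v) data.frame(group = paste0("g", seq_along(v)), relative = v)
  same <- compare_to_truth(tab(c(0.1, 0.2, 0.3, 0.4)), tab(c(0.1, 0.2, 0.3, 0.4)))
  expect_equal(unname(same), c(1, 1))
  rev5 <- compare_to_truth(tab(c(5, 4, 3, 2, 1) / 15), tab(c(1, 2, 3, 4, 5) / 15))
  expect_equal(unname(rev5["spearman_rho"]), -1)
  # worked 4-genome example against the hand formula
  e <- c(0.1, 0.2, 0.3, 0.4); o <- c(0.12, 0.18, 0.33, 0.37)
  hand_r <- sum((o - mean(o)) * (e - mean(e))) /
    sqrt(sum((o - mean(o))^2) * sum((e - mean(e))^2))
  got <- compare_to_truth(tab(o), tab(e))
  expect_equal(unname(got["pearson_r"]), hand_r)
  expect_error(compare_to_truth(tab(c(.5, .5)), tab(c(.5, .5))), "at least 3")
  expect_error(compare_to_truth(tab(1:3 / 6), data.frame(group = c("a", "b", "c"),
                                                         relative = 1:3 / 6)),
               "different groups")
})

test_that("abundance recovery on a small simulated community is near-perfect", {
  cm <- simulate_community(n_genomes = 5, genome_length = 30000, seed = 53)
  sr <- simulate_reads(cm, n_pairs = 3000, seed = 54)   # >= 50 reads/genome
  reads <- rbind(sr$pair1, sr$pair2)
  class(reads) <- c("mg_reads", "data.frame")
  aln <- map_reads(reads, build_index(cm$genomes))
  cov <- calculate_coverage(filter_apply(aln, filter_alignments(aln)), cm$genomes)
  expected <- data.frame(group = names(cm$abundance),
                         relative = as.numeric(cm$abundance))
  for (what in c("base", "read")) {
    ab <- genome_normalize(cov, cm$genome_map, what)
    cc <- compare_to_truth(ab, expected)
    expect_gte(cc["pearson_r"], 0.99)
  }
})
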