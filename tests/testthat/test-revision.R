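# Pileup construction, consensus/indel correction, breakpoint detection,
# and end-to-end assembly revision on corruption fixtures.

mk_saln <- function(qname, ref, pos, cigar, seq, mate = 0L, strand = "+") {
  a <- mg_alignments(qname, mate = mate, ref_id = ref, pos = pos,
                     strand = strand, cigar = cigar, nm = 0L,
                     mate_mapped = mate > 0L)
  a$seq <- seq
  a
}

test_that("pileup depth, deletions and insertions follow CIGAR semantics", {
  scf <- mg_refs(c(s = rand_seq(20)))
  a <- mk_saln("r1", "s", 1L, "10M", substr(scf[[1]], 1, 10))
  p <- build_pileup(scf, a)
  expect_equal(p$depth$s, c(rep(1L, 10), rep(0L, 10)))
  # 5M2D5M: two deletion columns, depth includes them
  a2 <- mk_saln("r2", "s", 1L, "5M2D5M",
                paste0(substr(scf[[1]], 1, 5), substr(scf[[1]], 8, 12)))
  p2 <- build_pileup(scf, a2)
  expect_equal(p2$deletion_obs$s[6:7], c(1L, 1L))
  expect_equal(p2$depth$s[1:12], rep(1L, 12))
  expect_equal(rowSums(p2$base_counts$s)[6:7], c(0, 0))
  # 5M2I5M: insertion recorded after position 5
  ins_seq <- paste0(substr(scf[[1]], 1, 5), "AC", substr(scf[[1]], 6, 10))
  a3 <- mk_saln("r3", "s", 1L, "5M2I5M", ins_seq)
  p3 <- build_pileup(scf, a3)
  expect_equal(p3$insertions$position, 5L)
  expect_equal(p3$insertions$seq, "AC")
  expect_error(build_pileup(scf, mk_saln("r", "nope", 1L, "5M", "ACGTA")), "unknown")
})

test_that("insert-span coverage counts strictly containing proper pairs", {
  scf <- mg_refs(c(s = rand_seq(300)))
  pair <- rbind(
    mk_saln("p", "s", 1L, "50M", substr(scf[[1]], 1, 50), mate = 1L, strand = "+"),
    mk_saln("p", "s", 151L, "50M", substr(scf[[1]], 151, 200), mate = 2L, strand = "-"))
  class(pair) <- c("mg_alignments", "data.frame")
  p <- build_pileup(scf, pair)
  # outer span 1..200 -> strictly contained positions 2..199
  expect_equal(p$span$s[1], 0L)
  expect_equal(p$span$s[2], 1L)
  expect_equal(p$span$s[199], 1L)
  expect_equal(p$span$s[200], 0L)
})

test_that("consensus correction needs depth and a strict majority", {
  scf <- mg_refs(c(s = paste0("A", rand_seq(19))))
  reads5 <- mk_saln(paste0("r", 1:5), "s", 1L, "10M",
                    c(rep(paste0("G", substr(scf[[1]], 2, 10)), 4),
                      substr(scf[[1]], 1, 10)))
  ev <- consensus_correct(build_pileup(scf, reads5))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$after, "G")
  expect_equal(ev$support_for, 4L)
  # depth 2 disagreement: below min_depth, unchanged
  reads2 <- mk_saln(paste0("r", 1:2), "s", 1L, "10M",
                    rep(paste0("G", substr(scf[[1]], 2, 10)), 2))
  expect_equal(nrow(consensus_correct(build_pileup(scf, reads2))), 0)
  # 2-2 tie keeps the reference
  reads4 <- mk_saln(paste0("r", 1:4), "s", 1L, "10M",
                    c(rep(paste0("G", substr(scf[[1]], 2, 10)), 2),
                      rep(substr(scf[[1]], 1, 10), 2)))
  expect_equal(nrow(consensus_correct(build_pileup(scf, reads4))), 0)
})

test_that("indel correction applies majority-supported indels up to the cap", {
  scf <- mg_refs(c(s = rand_seq(30)))
  with_ins <- paste0(substr(scf[[1]], 1, 10), "AC", substr(scf[[1]], 11, 20))
  reads <- rbind(
    mk_saln(paste0("i", 1:4), "s", 1L, "10M2I10M", rep(with_ins, 4)),
    mk_saln("plain", "s", 1L, "20M", substr(scf[[1]], 1, 20)))
  class(reads) <- c("mg_alignments", "data.frame")
  ev <- indel_correct(build_pileup(scf, reads))
  expect_equal(ev$kind, "insertion")
  expect_equal(ev$position, 10L)
  expect_equal(ev$after, "AC")
  # deletion supported by 1 of 6 reads: unchanged
  del1 <- rbind(
    mk_saln("d", "s", 1L, "5M1D14M",
            paste0(substr(scf[[1]], 1, 5), substr(scf[[1]], 7, 20))),
    mk_saln(paste0("p", 1:5), "s", 1L, "20M", rep(substr(scf[[1]], 1, 20), 5)))
  class(del1) <- c("mg_alignments", "data.frame")
  expect_equal(nrow(indel_correct(build_pileup(scf, del1))), 0)
  # a 15 bp insertion exceeds max_indel 10 and is skipped
  big <- paste0(substr(scf[[1]], 1, 10), rand_seq(15), substr(scf[[1]], 11, 20))
  reads15 <- mk_saln(paste0("b", 1:5), "s", 1L, "10M15I10M", rep(big, 5))
  expect_equal(nrow(indel_correct(build_pileup(scf, reads15))), 0)
})

test_that("revision is a fixed point on a correct assembly", {
  set.seed(71)
  g <- simulate_community(n_genomes = 2, genome_length = 20000, seed = 71)$genomes
  ca <- corrupt_assembly(g, n_subs = 0, n_indels = 0, n_chimeras = 0, seed = 72)
  sr <- simulate_coverage_reads(ca$sources, coverage = 30, seed = 73)
  reads <- rbind(sr$pair1, sr$pair2)
  class(reads) <- c("mg_reads", "data.frame")
  aln <- map_reads(reads, build_index(ca$scaftigs))
  fa <- align_with_seq(filter_apply(aln, filter_alignments(aln, filter_params(30, 90, FALSE))),
                       reads)
  res <- revise_assembly(ca$scaftigs, fa)
  expect_equal(nrow(res$events), 0)
  expect_identical(as.character(unclass(res$scaftigs)),
                   as.character(unclass(ca$scaftigs)))
})

test_that("single-end data makes breakpoint detection a warning no-op", {
  scf <- mg_refs(c(s = rand_seq(400)))
  a <- mk_saln(paste0("r", 1:4), "s", c(1L, 80L, 240L, 320L), "80M",
               substring(scf[[1]], c(1, 80, 240, 320), c(80, 159, 319, 399)))
  p <- build_pileup(scf, a)
  expect_warning(ev <- detect_breakpoints(p), "single-end")
  expect_equal(nrow(ev), 0)
})

test_that("an uncovered tail is end-trimmed", {
  set.seed(74)
  src <- mg_refs(c(s = rand_seq(2000)))
  # reads cover only the first 1700 bp; 300 bp tail has no coverage
  covered <- mg_refs(c(s = substr(src[[1]], 1, 1700)))
  sr <- simulate_coverage_reads(covered, coverage = 25, seed = 75)
  reads <- rbind(sr$pair1, sr$pair2)
  class(reads) <- c("mg_reads", "data.frame")
  aln <- map_reads(reads, build_index(src))
  fa <- align_with_seq(filter_apply(aln, filter_alignments(aln, filter_params(30, 90, FALSE))),
                       reads)
  res <- revise_assembly(src, fa)
  ev <- res$events
  trims <- ev[ev$kind == "end_trim", ]
  expect_equal(nrow(trims), 1)
  expect_equal(trims$position, 1701L)
  expect_equal(nchar(res$scaftigs[["s"]]), 1700L)
})

test_that("corruption fixture: substitutions, indels and chimeras are repaired", {
  fx <- revision_fixture(seed = 2024L)
  res <- revise_assembly(fx$ca$scaftigs, fx$aln)
  ev <- res$events
  tr <- fx$ca$truth
  revised <- res$scaftigs

  # substitutions: >= 90% recovered, no substitution at unperturbed positions
  sub_t <- tr[tr$kind == "substitution", ]
  rec <- vapply(seq_len(nrow(sub_t)), function(k) {
    w <- truth_repair_window(fx$ca$scaftigs[[sub_t$scaftig_id[k]]], sub_t[k, ])
    event_recovered(revised, sub_t$scaftig_id[k], w)
  }, TRUE)
  expect_gte(mean(rec), 0.9)
  sub_e <- ev[ev$kind == "substitution", ]
  expect_true(all(paste(sub_e$scaftig_id, sub_e$position) %in%
                    paste(sub_t$scaftig_id, sub_t$position)))

  # indels: >= 80% repaired (sequence-level, tolerant to equivalent placement)
  ind_t <- tr[tr$kind %in% c("insertion", "deletion"), ]
  irec <- vapply(seq_len(nrow(ind_t)), function(k) {
    w <- truth_repair_window(fx$ca$scaftigs[[ind_t$scaftig_id[k]]], ind_t[k, ])
    event_recovered(revised, ind_t$scaftig_id[k], w)
  }, TRUE)
  expect_gte(mean(irec), 0.8)
  # no indel event far from any injected indel locus
  ind_e <- ev[ev$kind %in% c("insertion", "deletion"), ]
  near_truth <- vapply(seq_len(nrow(ind_e)), function(k) {
    same <- ind_t[ind_t$scaftig_id == ind_e$scaftig_id[k], ]
    nrow(same) > 0 && any(abs(same$position - ind_e$position[k]) <= 10)
  }, TRUE)
  expect_true(all(near_truth))

  # both chimeric junctions split, near the true junction
  sp <- ev[ev$kind == "split", ]
  for (j in seq_len(nrow(fx$ca$junctions))) {
    jn <- fx$ca$junctions[j, ]
    hit <- sp$scaftig_id == jn$scaftig_id & abs(sp$position - jn$position) <= 300
    expect_true(any(hit))
  }
  # no split on non-chimeric scaftigs
  expect_true(all(sp$scaftig_id %in% fx$ca$junctions$scaftig_id))
})

test_that("revision conserves bases up to logged removals and indels", {
  fx <- revision_fixture(seed = 3033L, n_subs = 10L, n_indels = 6L, n_chimeras = 1L)
  res <- revise_assembly(fx$ca$scaftigs, fx$aln)
  ev <- res$events
  removed <- sum(nchar(ev$before[ev$kind %in% c("split", "end_trim")]))
  indel_balance <- sum(nchar(ev$after[ev$kind == "insertion"])) -
    sum(nchar(ev$before[ev$kind == "deletion"]))
  expect_equal(sum(nchar(res$scaftigs)) + sum(res$dropped$length) + removed,
               sum(nchar(fx$ca$scaftigs)) + indel_balance)
})

test_that("replaying the event log reproduces the revised assembly", {
  fx <- revision_fixture(seed = 4044L, n_subs = 8L, n_indels = 5L, n_chimeras = 2L)
  res <- revise_assembly(fx$ca$scaftigs, fx$aln)
  rp <- replay_events(fx$ca$scaftigs, res$events, 60L)
  expect_identical(as.character(unclass(rp$scaftigs)),
                   as.character(unclass(res$scaftigs)))
  expect_identical(names(rp$scaftigs), names(res$scaftigs))
})

test_that("short post-split pieces are dropped and logged", {
  # scaftig whose right part after the junction is only 40 bp of another source
  set.seed(76)
  a <- rand_seq(2000); b <- rand_seq(40)
  scf <- mg_refs(c(chi = paste0(a, b)))
  srcs <- mg_refs(c(chi_a = a, chi_b = b))
  sr <- simulate_coverage_reads(mg_refs(c(chi_a = a)), coverage = 30, seed = 77)
  reads <- rbind(sr$pair1, sr$pair2)
  class(reads) <- c("mg_reads", "data.frame")
  aln <- map_reads(reads, build_index(scf))
  fa <- align_with_seq(filter_apply(aln, filter_alignments(aln, filter_params(30, 90, FALSE))),
                       reads)
  res <- revise_assembly(scf, fa, revision_params(min_scaftig = 60L))
  # the uncovered 40 bp tail is either trimmed or dropped; output is part A only
  expect_equal(length(res$scaftigs), 1L)
  expect_equal(nchar(res$scaftigs[[1]]), 2000L)
})
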