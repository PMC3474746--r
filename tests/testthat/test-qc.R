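# Quality trimming, base-composition profiling, 5' trimming, and the
# combined trim/filter step.

test_that("dynamic_trim keeps the longest all-passing segment, 5'-most on ties", {
  r <- mg_reads(c("a", "b", "c"),
                c("ACGTAC", "ACGTA", "ACGTA"),
                list(c(25, 25, 10, 25, 25, 25), c(30, 30, 30, 30, 30),
                     c(30, 30, 5, 30, 30)))
  out <- dynamic_trim(r, 20)
  expect_equal(out$seq, c("TAC", "ACGTA", "AC"))
  expect_equal(phred_decode(out$qual[1]), c(25, 25, 25))
  # no base qualifies -> empty read
  low <- dynamic_trim(mg_reads("d", "ACG", list(c(5, 5, 5))), 20)
  expect_equal(low$seq, "")
})

test_that("dynamic_trim agrees with exhaustive window search", {
  set.seed(11)
  reads <- random_reads(500, len = 10:40)
  out <- dynamic_trim(reads, 20)
  for (i in seq_len(nrow(reads))) {
    q <- phred_decode(reads$qual[i])
    b <- segment_oracle_exhaustive(q, 20)
    expect_identical(out$seq[i], substr(reads$seq[i], b[1], b[2]))
  }
})

test_that("fastx_trim strips the 3' tail only", {
  r <- mg_reads(c("a", "b", "c"),
                c("ACGTAC", "ACG", "ACG"),
                list(c(30, 30, 15, 30, 12, 11), c(30, 25, 20), c(10, 15, 19)))
  out <- fastx_trim(r, 20)
  expect_equal(nchar(out$seq), c(4L, 3L, 0L))
  expect_equal(out$seq[1], "ACGT")   # interior 15 kept
})

test_that("base composition profile computes per-position frequencies", {
  p <- base_composition_profile(mg_reads(c("a", "b"), c("AC", "AC"),
                                         list(c(30, 30), c(30, 30))))
  expect_equal(unname(p$freq[1, "A"]), 1.0)
  expect_equal(unname(p$freq[2, "C"]), 1.0)
  # single position: sd defined as 0
  p1 <- base_composition_profile(mg_reads("a", "A", list(30)))
  expect_equal(unname(p1$per_base_sd), rep(0, 4))
  expect_error(base_composition_profile(mg_reads(character(), character(), character())),
               "no reads")
})

test_that("uniform random reads have per-base mean frequency near 0.25", {
  set.seed(12)
  p <- base_composition_profile(random_reads(1000, len = 50))
  expect_true(all(abs(p$per_base_mean - 0.25) < 0.03))
  expect_equal(five_prime_trim_length(p), 0L)
})

test_that("5' trim length is the contiguous biased prefix only", {
  freq <- matrix(0.25, nrow = 10, ncol = 4,
                 dimnames = list(NULL, c("A", "C", "G", "T")))
  prof <- structure(list(freq = freq, n_reads_at_position = rep(100L, 10),
                         per_base_mean = colMeans(freq),
                         per_base_sd = setNames(rep(0.02, 4), colnames(freq))),
                    class = "base_composition_profile")
  expect_equal(five_prime_trim_length(prof), 0L)
  # position 1 G biased at 0.50 vs mean 0.25, sd 0.02 -> t = 1
  prof$freq[1, ] <- c(0.2, 0.2, 0.50, 0.10)
  expect_equal(five_prime_trim_length(prof, cap = 0.5), 1L)
  # positions 1-3 biased, 4 compliant, 6 biased -> t = 3 (interior ignored)
  prof$freq[2, ] <- c(0.5, 0.2, 0.2, 0.1)
  prof$freq[3, ] <- c(0.1, 0.5, 0.2, 0.2)
  prof$freq[6, ] <- c(0.1, 0.2, 0.5, 0.2)
  expect_equal(five_prime_trim_length(prof, cap = 0.5), 3L)
  # the cap bounds the trim
  expect_equal(five_prime_trim_length(prof, cap = 0.15), 1L)
})

test_that("read_trim_filter applies 5' trim, method trim, length filter and pairing", {
  set.seed(13)
  good_q <- lapply(1:6, function(i) rep(35L, 50))
  p1 <- mg_reads(paste0("p", 1:6), vapply(rep(50, 6), rand_seq, ""), good_q, 1L)
  p2 <- mg_reads(paste0("p", 1:6), vapply(rep(50, 6), rand_seq, ""), good_q, 2L)
  # make mate2 of pair 3 fail: all low quality
  p2$qual[3] <- phred_encode(rep(5L, 50))
  res <- read_trim_filter(p1, p2, params = qc_params())
  expect_equal(nrow(res$pair1), 5)
  expect_equal(nrow(res$pair2), 5)
  expect_equal(res$single$id, "p3")       # surviving mate1 becomes singleton
  expect_equal(res$single$mate, 0L)
  expect_equal(res$stats$raw_reads, 12)
  expect_equal(res$stats$hq_reads, 11)
  expect_equal(res$stats$pct_reads_retained, 100 * 11 / 12)
  expect_error(read_trim_filter(p1, p2[1:3, ]), "mismatched pair")
})

test_that("every retained read satisfies the quality and length guarantees", {
  set.seed(14)
  p1 <- blocky_reads(300, len = 30:80, prefix = "m")
  p2 <- blocky_reads(300, len = 30:80, prefix = "m")
  sg <- blocky_reads(100, len = 30:80, prefix = "s")
  res <- read_trim_filter(p1, p2, sg, qc_params(20, 30, "solexaqa"))
  all_out <- rbind(res$pair1, res$pair2, res$single)
  expect_gt(nrow(all_out), 0)
  expect_true(all(nchar(all_out$seq) >= 30))
  quals <- unlist(lapply(all_out$qual, phred_decode))
  expect_true(all(quals >= 20))
  # every output read is a contiguous subsequence of an input read
  inputs <- c(setNames(p1$seq, paste0(p1$id, "/1")),
              setNames(p2$seq, paste0(p2$id, "/2")),
              setNames(sg$seq, paste0(sg$id, "/0")))
  orig_mate <- c(rep(1L, 300), rep(2L, 300), rep(0L, 100))
  for (i in seq_len(nrow(all_out))) {
    cand <- inputs[paste0(all_out$id[i], "/", c(0:2))]
    cand <- cand[!is.na(cand)]
    expect_true(any(vapply(cand, function(s) grepl(all_out$seq[i], s, fixed = TRUE), TRUE)))
  }
})

test_that("read_trim_filter is idempotent on its own output", {
  set.seed(15)
  p1 <- blocky_reads(200, len = 40:70)
  p2 <- blocky_reads(200, len = 40:70)
  res1 <- read_trim_filter(p1, p2, params = qc_params())
  res2 <- read_trim_filter(res1$pair1, res1$pair2, res1$single, qc_params())
  expect_reads_equal(res2$pair1, res1$pair1)
  expect_reads_equal(res2$pair2, res1$pair2)
  expect_reads_equal(res2$single, res1$single)
  expect_equal(res2$five_prime_trim_length, 0L)
})

test_that("5' trimming removes the same prefix from every read", {
  set.seed(16)
  n <- 400
  seqs <- vapply(rep(60, n), rand_seq, "")
  substr(seqs, 1, 2) <- "GG"   # strong bias at positions 1-2
  reads <- mg_reads(paste0("r", 1:n), seqs, lapply(rep(60, n), function(L) rep(35L, L)))
  res <- read_trim_filter(single = reads, params = qc_params())
  expect_equal(res$five_prime_trim_length, 2L)
  expect_true(all(nchar(res$single$seq) == 58))
  expect_equal(res$single$seq, substring(seqs, 3))
})
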