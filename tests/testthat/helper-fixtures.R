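# Shared fixture builders.  Everything is generated in code at test time.

rand_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")

# reads with uniformly random bases and qualities
random_reads <- function(n, len = 50L, qmin = 2L, qmax = 40L, prefix = "r") {
  lens <- if (length(len) == 1) rep(len, n) else sample(len, n, TRUE)
  mg_reads(paste0(prefix, seq_len(n)),
           vapply(lens, rand_seq, ""),
           lapply(lens, function(L) sample(qmin:qmax, L, TRUE)))
}

# reads with block-structured qualities (runs of good/bad stretches), the
# shape real quality profiles have; i.i.d. qualities almost never leave a
# 30 bp all-passing segment
blocky_reads <- function(n, len = 30:80, prefix = "b") {
  lens <- sample(len, n, TRUE)
  quals <- lapply(lens, function(L) {
    q <- integer(0)
    while (length(q) < L)
      q <- c(q, rep(sample(c(5L, 15L, 28L, 35L), 1), sample(10:40, 1)))
    q[seq_len(L)]
  })
  mg_reads(paste0(prefix, seq_len(n)), vapply(lens, rand_seq, ""), quals)
}

# independent maximal-segment oracle: enumerate maximal passing runs
segment_oracle_runs <- function(q, cutoff) {
  idx <- which(q >= cutoff)
  if (!length(idx)) return(c(1L, 0L))
  grp <- cumsum(c(1L, diff(idx) > 1L))
  lens <- tabulate(grp)
  g <- which.max(lens)                 # which.max takes the first (5'-most)
  s <- idx[grp == g]
  c(s[1], s[length(s)])
}

# fully exhaustive O(L^2) oracle: try every contiguous window
segment_oracle_exhaustive <- function(q, cutoff) {
  best <- c(1L, 0L); blen <- 0L
  L <- length(q)
  for (i in seq_len(L)) for (j in i:L) {
    if (j - i + 1L > blen && all(q[i:j] >= cutoff)) {
      best <- c(i, j); blen <- j - i + 1L
    }
  }
  best
}

# standard corruption fixture: corrupt, simulate tiling reads, map, filter
revision_fixture <- function(seed = 2024L, n_subs = 20L, n_indels = 10L,
                             n_chimeras = 2L, coverage = 30) {
  g <- simulate_community(n_genomes = 3, genome_length = 40000,
                          seed = seed)$genomes
  ca <- corrupt_assembly(g, n_subs, n_indels, n_chimeras, seed = seed + 1L)
  sr <- simulate_coverage_reads(ca$sources, coverage = coverage, seed = seed + 2L)
  reads <- rbind(sr$pair1, sr$pair2)
  class(reads) <- c("mg_reads", "data.frame")
  aln <- map_reads(reads, build_index(ca$scaftigs))
  kept <- filter_alignments(aln, filter_params(30, 90, FALSE))
  fa <- align_with_seq(filter_apply(aln, kept), reads)
  list(ca = ca, reads = reads, aln = fa)
}

# the locally repaired sequence window around a truth event (positions on the
# corrupted scaftig); used to check recovery robustly to equivalent indel
# placements (a left-shifted deletion of the same bases is the same repair)
truth_repair_window <- function(scaftig_seq, ev, flank = 25L) {
  p <- ev$position
  repaired <- switch(ev$kind,
    substitution = {
      s <- scaftig_seq; substr(s, p, p) <- ev$after; s
    },
    deletion = paste0(substr(scaftig_seq, 1, p - 1L),
                      substring(scaftig_seq, p + nchar(ev$before))),
    insertion = paste0(substr(scaftig_seq, 1, p), ev$after,
                       substring(scaftig_seq, p + 1L)))
  a <- max(1L, p - flank)
  substr(repaired, a, min(nchar(repaired), p + flank))
}

# did the revision reproduce the repair for this truth event?
event_recovered <- function(revised, scaftig_id, window) {
  pieces <- revised[startsWith(names(revised), scaftig_id)]
  any(vapply(pieces, function(s) grepl(window, s, fixed = TRUE), TRUE))
}

expect_reads_equal <- function(a, b) {
  expect_equal(a$id, b$id)
  expect_equal(a$seq, b$seq)
  expect_equal(a$qual, b$qual)
}
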