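# Record types, quality-offset detection, CIGAR arithmetic, format round-trips.

test_that("quality offset detection follows the code-range rules", {
  expect_identical(as.integer(detect_quality_offset(intToUtf8(35:70))), 33L)
  expect_identical(as.integer(detect_quality_offset(intToUtf8(66:104))), 64L)
  amb <- suppressWarnings(detect_quality_offset(intToUtf8(59:74)))
  expect_identical(as.integer(amb), 33L)
  expect_true(attr(amb, "ambiguous"))
  expect_warning(detect_quality_offset(intToUtf8(60:70)), "ambiguous")
  expect_error(detect_quality_offset(character()), "no reads")
})

test_that("alignment identity and aligned length follow the M+I definition", {
  a <- mg_alignments(qname = c("a", "b", "c"), ref_id = "x", pos = 1L,
                     strand = "+", cigar = c("30M", "30M", "10M2I5M3D"),
                     nm = c(3L, 0L, 5L))
  expect_equal(alignment_identity(a), c(90, 100, 100 * 12 / 17))
  expect_equal(aligned_length(a), c(30L, 30L, 17L))
  b <- mg_alignments("u", mapped = FALSE)
  expect_error(alignment_identity(b), "unmapped")
  expect_error(aligned_length(b), "unmapped")
})

test_that("aligned length excludes clips and deletions", {
  a <- mg_alignments(c("a", "b"), ref_id = "x", pos = 1L, strand = "+",
                     cigar = c("5S25M", "10M2I5M3D4S"), nm = 0L)
  expect_equal(aligned_length(a), c(25L, 17L))
})

test_that("identity is bounded and aligned length bounded by read length on random CIGARs", {
  set.seed(101)
  for (i in 1:50) {
    n_ops <- sample(1:6, 1)
    ops <- sample(c("M", "I", "D", "S"), n_ops, TRUE, prob = c(.6, .15, .15, .1))
    lens <- sample(1:20, n_ops, TRUE)
    cig <- paste0(lens, ops, collapse = "")
    qlen <- sum(lens[ops %in% c("M", "I", "S")])
    alq <- sum(lens[ops %in% c("M", "I")])
    if (alq == 0) next
    a <- mg_alignments("r", ref_id = "x", pos = 1L, strand = "+", cigar = cig,
                       nm = sample(0:alq, 1))
    expect_gte(alignment_identity(a), 0)
    expect_lte(alignment_identity(a), 100)
    expect_lte(aligned_length(a), qlen)
  }
})

test_that("FASTQ round-trips and validates records", {
  set.seed(7)
  reads <- random_reads(100, len = 20:80)
  fq <- tempfile(fileext = ".fq")
  write_fastq(reads, fq)
  back <- read_fastq(fq)
  expect_reads_equal(reads, back)
  # Phred+64 round-trip
  write_fastq(reads, fq, offset = 64L)
  back64 <- read_fastq(fq)          # auto-detected
  expect_reads_equal(reads, back64)

  writeLines(c("@r1", "ACGT", "+", "II"), fq)
  expect_error(read_fastq(fq), "length")
  writeLines(c("r1", "ACGT", "+", "IIII"), fq)
  expect_error(read_fastq(fq), "@")
  writeLines(c("@r1", "ACGT", "+", "IIII", "@r2"), fq)
  expect_error(read_fastq(fq), "multiple of 4")
})

test_that("FASTA round-trips through Biostrings with 80-column wrapping", {
  set.seed(8)
  refs <- mg_refs(setNames(vapply(c(10, 200, 95), rand_seq, ""), c("a", "b", "c")))
  fa <- tempfile(fileext = ".fasta")
  write_fasta(refs, fa)
  expect_equal(as.character(unclass(read_fasta(fa))), as.character(unclass(refs)))
  expect_lte(max(nchar(readLines(fa))), 80)
})

test_that("SAM round-trips records and flags unmapped reads", {
  refs <- mg_refs(c(chr = rand_seq(500)))
  aln <- mg_alignments(qname = c("a", "a", "b", "c"), mate = c(1L, 2L, 0L, 0L),
                       mapped = c(TRUE, TRUE, TRUE, FALSE),
                       ref_id = c("chr", "chr", "chr", NA),
                       pos = c(10L, 210L, 50L, NA),
                       strand = c("+", "-", "+", NA),
                       cigar = c("50M", "40M2I8M", "30M", NA),
                       nm = c(0L, 3L, 1L, NA),
                       mate_mapped = c(TRUE, TRUE, FALSE, FALSE),
                       tlen = c(250L, -250L, 0L, 0L))
  sam <- tempfile(fileext = ".sam")
  write_sam(aln, refs, sam)
  back <- read_sam(sam)
  expect_equal(back$qname, aln$qname)
  expect_equal(back$mapped, aln$mapped)
  expect_equal(back$pos, aln$pos)
  expect_equal(back$strand, aln$strand)
  expect_equal(back$cigar, aln$cigar)
  expect_equal(back$nm, aln$nm)
  expect_equal(back$mate, aln$mate)
  expect_equal(attr(back, "refs"), c(chr = 500L))
  expect_false(back$mapped[4])
})

test_that("GFF gene records carry completeness from partial/completeness attributes", {
  gff <- tempfile(fileext = ".gff")
  writeLines(c(
    "##gff-version 3",
    "s1\tprod\tCDS\t10\t309\t.\t+\t0\tID=g1;partial=00",
    "s1\tprod\tCDS\t400\t600\t.\t-\t0\tID=g2;partial=10",
    "s2\tprod\tgene\t1\t90\t.\t+\t.\tID=g3;completeness=fragment",
    "s2\tprod\tregion\t1\t999\t.\t+\t.\tID=ignored"), gff)
  g <- read_gff(gff)
  expect_equal(nrow(g), 3)
  expect_equal(g$completeness, c("complete", "missing_start", "fragment"))
  expect_equal(g$end - g$start + 1L, c(300L, 201L, 90L))
})

test_that("chunked FASTQ streaming sees every record once, in order", {
  set.seed(9)
  reads <- random_reads(25, len = 30)
  fq <- tempfile(fileext = ".fq")
  write_fastq(reads, fq)
  ids <- unlist(lapply(fastq_chunk_apply(fq, function(ch) ch$id, chunk_size = 4L),
                       identity))
  expect_equal(ids, reads$id)
})
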