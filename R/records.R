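# Core record containers.  Reads and alignments are plain data.frames with a
# class tag so that thousands to millions of records stay vectorized; all
# coordinates are 1-based inclusive (SAM/GFF convention).

#' Construct a set of sequencing reads
#'
#' A read set is a `data.frame` with columns `id`, `seq` (bases over
#' A/C/G/T/N), `qual` (Phred+33-encoded quality string, one character per
#' base) and `mate` (`0` = single, `1`/`2` = mate role in a pair).
#'
#' @param id character vector of read identifiers.
#' @param seq character vector of base sequences.
#' @param qual either a character vector of Phred+33 quality strings or a
#'   list of integer Phred scores per read.
#' @param mate integer vector (recycled) giving the mate role.
#' @return An object of class `mg_reads` (a `data.frame`).
#' @examples
#' r <- mg_reads("r1", "ACGT", list(c(30, 30, 30, 30)))
#' read_lengths(r)
#' @export
mg_reads <- function(id, seq, qual, mate = 0L) {
  if (is.list(qual)) qual <- vapply(qual, phred_encode, "", USE.NAMES = FALSE)
  stopifnot(length(id) == length(seq), length(seq) == length(qual))
  bad <- which(nchar(seq) != nchar(qual))
  if (length(bad))
    stop("read ", id[bad[1]], ": sequence length ", nchar(seq[bad[1]]),
         " != quality length ", nchar(qual[bad[1]]))
  x <- data.frame(id = as.character(id), seq = toupper(as.character(seq)),
                  qual = as.character(qual),
                  mate = rep_len(as.integer(mate), length(id)))
  class(x) <- c("mg_reads", "data.frame")
  x
}

#' @export
print.mg_reads <- function(x, ...) {
  cat("<mg_reads> ", nrow(x), " reads, ", sum(nchar(x$seq)), " bases\n", sep = "")
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 6))
  invisible(x)
}

#' Read lengths of a read set
#' @param reads an `mg_reads` object.
#' @return Integer vector of per-read lengths.
#' @export
read_lengths <- function(reads) nchar(reads$seq)

#' Decode / encode Phred quality strings
#'
#' @param qual a single quality string.
#' @param offset ASCII offset (33 or 64).
#' @return `phred_decode`: integer Phred scores; `phred_encode`: a string.
#' @export
phred_decode <- function(qual, offset = 33L) utf8ToInt(qual) - as.integer(offset)

#' @param scores integer vector of Phred scores in \[0, 93\].
#' @rdname phred_decode
#' @export
phred_encode <- function(scores, offset = 33L) {
  if (length(scores) == 0) return("")
  stopifnot(all(scores >= 0), all(scores + offset <= 126))
  intToUtf8(as.integer(scores) + as.integer(offset))
}

#' Detect the FASTQ quality-score ASCII offset
#'
#' Inspects raw quality characters: any code below 59 forces Phred+33; codes
#' above 74 (and none below 59) force Phred+64.  If every code falls in the
#' overlap 59--74 the configured default is returned and the result carries
#' an `ambiguous` attribute (with a warning).
#'
#' @param qual_strings character vector of raw quality strings.
#' @param default offset assumed when the evidence is ambiguous.
#' @return 33 or 64 (integer), with attribute `ambiguous` (logical).
#' @export
detect_quality_offset <- function(qual_strings, default = 33L) {
  qual_strings <- qual_strings[nzchar(qual_strings)]
  if (length(qual_strings) == 0) stop("no reads")
  codes <- utf8ToInt(paste(qual_strings, collapse = ""))
  off <- if (any(codes < 59)) 33L else if (any(codes > 74)) 64L else NA_integer_
  amb <- is.na(off)
  if (amb) {
    warning("quality encoding ambiguous (all codes in 59..74); assuming Phred+",
            default)
    off <- as.integer(default)
  }
  attr(off, "ambiguous") <- amb
  off
}

#' Construct a set of reference sequences
#'
#' @param seqs named character vector of sequences (names are reference ids),
#'   or a `Biostrings::DNAStringSet`.
#' @return An object of class `mg_refs`: a named character vector.
#' @export
mg_refs <- function(seqs) {
  if (methods::is(seqs, "DNAStringSet")) seqs <- setNames(as.character(seqs), names(seqs))
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("reference sequences must be named")
  if (anyDuplicated(names(seqs))) stop("duplicated reference ids")
  seqs <- toupper(seqs)
  class(seqs) <- "mg_refs"
  seqs
}

#' @export
print.mg_refs <- function(x, ...) {
  cat("<mg_refs> ", length(x), " sequences, ", sum(nchar(x)), " bp\n", sep = "")
  invisible(x)
}

#' Construct an alignment table
#'
#' One row per alignment record.  Unmapped reads keep a row with
#' `mapped = FALSE` and `NA` coordinates so that screening can partition the
#' full read set.
#'
#' @param qname,mate read id and mate role (0/1/2).
#' @param mapped logical; `FALSE` rows may have `NA` coordinates.
#' @param ref_id,pos,strand,cigar,nm alignment coordinates: reference id,
#'   1-based leftmost reference position, `"+"`/`"-"`, CIGAR string over
#'   M/I/D/S/H, and edit distance (NM).
#' @param is_primary,mate_mapped,tlen flags and signed template length.
#' @return An object of class `mg_alignments` (a `data.frame`).
#' @export
mg_alignments <- function(qname, mate = 0L, mapped = TRUE, ref_id = NA_character_,
                          pos = NA_integer_, strand = NA_character_,
                          cigar = NA_character_, nm = NA_integer_,
                          is_primary = TRUE, mate_mapped = FALSE,
                          tlen = 0L) {
  n <- length(qname)
  x <- data.frame(qname = as.character(qname),
                  mate = rep_len(as.integer(mate), n),
                  mapped = rep_len(as.logical(mapped), n),
                  ref_id = rep_len(as.character(ref_id), n),
                  pos = rep_len(as.integer(pos), n),
                  strand = rep_len(as.character(strand), n),
                  cigar = rep_len(as.character(cigar), n),
                  nm = rep_len(as.integer(nm), n),
                  is_primary = rep_len(as.logical(is_primary), n),
                  mate_mapped = rep_len(as.logical(mate_mapped), n),
                  tlen = rep_len(as.integer(tlen), n))
  bad <- which(x$mapped & !is.na(x$pos) & x$pos < 1)
  if (length(bad)) stop("alignment ", bad[1], ": ref position must be >= 1")
  class(x) <- c("mg_alignments", "data.frame")
  x
}

#' @export
print.mg_alignments <- function(x, ...) {
  cat("<mg_alignments> ", nrow(x), " records (", sum(x$mapped), " mapped)\n",
      sep = "")
  if (nrow(x)) print.data.frame(head(as.data.frame(x), 6))
  invisible(x)
}
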