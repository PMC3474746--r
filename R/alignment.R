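# CIGAR arithmetic and derived alignment quantities.

#' Parse a CIGAR string
#'
#' @param cigar a single CIGAR string, e.g. `"10M2I5M3D"`.
#' @return A data.frame with columns `op` and `len`, in order.
#' @export
parse_cigar <- function(cigar) {
  stopifnot(length(cigar) == 1, !is.na(cigar))
  m <- gregexpr("(\\d+)([MIDSHNP=X])", cigar, perl = TRUE)
  if (m[[1]][1] == -1 || sum(attr(m[[1]], "match.length")) != nchar(cigar))
    stop("malformed CIGAR: ", cigar)
  toks <- regmatches(cigar, m)[[1]]
  data.frame(op = substring(toks, nchar(toks), nchar(toks)),
             len = as.integer(substring(toks, 1, nchar(toks) - 1)))
}

cigar_stats <- function(cigars) .mg_cigar_stats(as.character(cigars))

#' Aligned query length of alignment records
#'
#' Number of query bases taking part in the alignment: the sum of M and I
#' operation lengths.  Soft/hard clips and reference-only operations (D) are
#' excluded.
#'
#' @param aln an `mg_alignments` table; all records must be mapped.
#' @return Integer vector, one value per record.
#' @export
aligned_length <- function(aln) {
  if (any(!aln$mapped)) stop("aligned_length is undefined for unmapped records")
  as.vector(cigar_stats(aln$cigar)[, "aligned_q"])
}

#' Percent identity of alignment records
#'
#' Defined as `100 * (aligned_query_length - edit_distance) /
#' aligned_query_length`, with the aligned query length counted over M and I
#' CIGAR operations and the edit distance taken from the NM field.  Aligner
#' documentation varies in how identity is defined (per aligned column vs per
#' query base); this per-query-base definition is used consistently for
#' filtering.
#'
#' @param aln an `mg_alignments` table; all records must be mapped.
#' @return Numeric vector of percentages in \[0, 100\].
#' @export
alignment_identity <- function(aln) {
  if (any(!aln$mapped)) stop("alignment_identity is undefined for unmapped records")
  al <- as.vector(cigar_stats(aln$cigar)[, "aligned_q"])
  pmax(0, 100 * (al - aln$nm) / al)
}

#' Reference span (end position) of alignment records
#'
#' @param aln an `mg_alignments` table (mapped records).
#' @return Integer vector of 1-based inclusive end positions on the reference.
#' @export
alignment_end <- function(aln) {
  aln$pos + as.vector(cigar_stats(aln$cigar)[, "ref_span"]) - 1L
}
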