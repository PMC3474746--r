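# Built-in seed-and-extend read mapper.  Exact k-mer seeds on both strands,
# diagonal voting, then a glocal (query-global, reference-free-ends) banded
# extension with match +1 / mismatch -1 / gap -2.  One primary alignment per
# read; ties broken deterministically (lowest reference, leftmost position,
# forward strand).

#' Mapping parameters
#'
#' @param seed_k exact-seed k-mer size (default 15, minimum 8).
#' @param band alignment band half-width in bp (default 10); also the
#'   diagonal-merging tolerance.
#' @param max_hits_per_seed seeds hitting more loci than this are skipped as
#'   repetitive (default 50).
#' @param seed_stride spacing of query seed offsets (default 10; the final
#'   offset is always seeded).
#' @param max_candidates candidate loci extended per read (default 8).
#' @return A list of class `map_params`.
#' @export
map_params <- function(seed_k = 15L, band = 10L, max_hits_per_seed = 50L,
                       seed_stride = 10L, max_candidates = 8L) {
  stopifnot(seed_k >= 8, band >= 1, max_hits_per_seed >= 1, seed_stride >= 1,
            max_candidates >= 1)
  structure(list(seed_k = as.integer(seed_k), band = as.integer(band),
                 max_hits_per_seed = as.integer(max_hits_per_seed),
                 seed_stride = as.integer(seed_stride),
                 max_candidates = as.integer(max_candidates)),
            class = "map_params")
}

#' Build a seed index over reference sequences
#'
#' Indexes every k-mer window of every reference on both strands (k-mers
#' containing N are skipped).
#'
#' @param refs an [mg_refs] object (or named character vector).
#' @param params a [map_params()] list.
#' @return An object of class `seed_index`.
#' @export
build_index <- function(refs, params = map_params()) {
  refs <- mg_refs(refs)
  if (length(refs) == 0) stop("no reference sequences to index")
  if (max(nchar(refs)) < params$seed_k)
    stop("no reference sequence is at least seed_k = ", params$seed_k, " bp")
  ptr <- .mg_index_build(names(refs), as.character(unclass(refs)), params$seed_k)
  structure(list(ptr = ptr, refs = refs, params = params), class = "seed_index")
}

#' @export
print.seed_index <- function(x, ...) {
  s <- .mg_index_stats(x$ptr)
  cat("<seed_index> k=", s$k, ", ", s$n_refs, " refs, ",
      format(s$n_forward_seeds, big.mark = ","), " forward seeds\n", sep = "")
  invisible(x)
}

#' Index seed statistics
#' @param index a [build_index()] result.
#' @return List with `k`, `n_refs`, `n_forward_seeds`, `n_reverse_seeds`,
#'   `n_distinct_kmers`.
#' @export
index_stats <- function(index) .mg_index_stats(index$ptr)

#' Map reads against an indexed reference
#'
#' @param reads an [mg_reads] object.
#' @param index a [build_index()] result.
#' @return An [mg_alignments] table with one primary record per read (in
#'   input order); reads without an alignment-worthy hit are `mapped = FALSE`.
#'   `mate_mapped`/`tlen` are filled for read pairs whose mates share a
#'   reference.
#' @export
map_reads <- function(reads, index) {
  p <- index$params
  res <- .mg_map_batch(index$ptr, reads$seq, p$band, p$max_hits_per_seed,
                       p$seed_stride, p$max_candidates)
  ref_names <- names(index$refs)
  aln <- mg_alignments(
    qname = reads$id, mate = reads$mate, mapped = res$mapped,
    ref_id = ifelse(res$mapped, ref_names[res$ref_i], NA_character_),
    pos = res$pos, strand = res$strand, cigar = res$cigar, nm = res$nm,
    is_primary = TRUE, mate_mapped = FALSE, tlen = 0L)
  pair_annotate(aln)
}

# fill mate_mapped and the signed outer template length for proper pairs
pair_annotate <- function(aln) {
  paired <- aln$mate > 0L
  if (!any(paired)) return(aln)
  key <- aln$qname
  idx1 <- which(paired & aln$mate == 1L)
  idx2 <- which(paired & aln$mate == 2L)
  m <- match(key[idx1], key[idx2])
  has <- !is.na(m)
  i1 <- idx1[has]; i2 <- idx2[m[has]]
  aln$mate_mapped[i1] <- aln$mapped[i2]
  aln$mate_mapped[i2] <- aln$mapped[i1]
  both <- aln$mapped[i1] & aln$mapped[i2] &
    aln$ref_id[i1] == aln$ref_id[i2] & aln$strand[i1] != aln$strand[i2]
  if (any(both)) {
    j1 <- i1[both]; j2 <- i2[both]
    ends <- cigar_stats(aln$cigar)[, "ref_span"]
    left <- pmin(aln$pos[j1], aln$pos[j2])
    right <- pmax(aln$pos[j1] + ends[j1] - 1L, aln$pos[j2] + ends[j2] - 1L)
    span <- right - left + 1L
    aln$tlen[j1] <- ifelse(aln$pos[j1] <= aln$pos[j2], span, -span)
    aln$tlen[j2] <- -aln$tlen[j1]
  }
  aln
}

#' Map a single read
#'
#' Convenience wrapper over [map_reads()] for one read.
#'
#' @param read a one-row [mg_reads].
#' @param index a [build_index()] result.
#' @return A one-row [mg_alignments] table.
#' @export
map_read <- function(read, index) map_reads(read[1, , drop = FALSE], index)
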