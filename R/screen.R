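# Screening and filtering: length/identity alignment filters with optional
# pair-level semantics, reference screening in remove/extract mode, and
# local-alignment screening against an adapter FASTA.

#' Alignment filter parameters
#'
#' @param min_aligned_length minimum aligned query length in bp (default 30).
#' @param min_identity minimum percent identity (default 90); both bounds
#'   are inclusive.
#' @param paired_end_filtering if `TRUE`, a pair passes as a unit when at
#'   least one mate passes.
#' @return A list of class `filter_params`.
#' @export
filter_params <- function(min_aligned_length = 30L, min_identity = 90,
                          paired_end_filtering = TRUE) {
  stopifnot(min_identity >= 0, min_identity <= 100, min_aligned_length >= 0)
  structure(list(min_aligned_length = as.integer(min_aligned_length),
                 min_identity = min_identity,
                 paired_end_filtering = paired_end_filtering),
            class = "filter_params")
}

#' Filter alignment records by length and identity
#'
#' A record passes when it is a mapped primary alignment with
#' `aligned_length >= min_aligned_length` and
#' `alignment_identity >= min_identity`.  With paired-end filtering, a pair
#' passes when at least one mate passes, and then both mates are kept.
#'
#' @param aln an [mg_alignments] table.
#' @param params a [filter_params()] list.
#' @return Character vector of kept read keys (`qname/mate`, e.g.
#'   `"r1/1"`; `"r1/0"` for singletons).  Use [filter_apply()] to subset the
#'   alignment table itself.
#' @export
filter_alignments <- function(aln, params = filter_params()) {
  pass <- aln$mapped & aln$is_primary
  if (any(pass)) {
    sub <- aln[pass, , drop = FALSE]
    ok <- aligned_length(sub) >= params$min_aligned_length &
      alignment_identity(sub) >= params$min_identity
    pass[pass] <- ok
  }
  if (params$paired_end_filtering) {
    paired <- aln$mate > 0L
    pair_pass <- tapply(pass[paired], aln$qname[paired], any)
    idx <- paired & as.logical(pair_pass[aln$qname])
    idx[is.na(idx)] <- FALSE
    pass <- pass | idx
  }
  if (!any(pass)) return(character(0))
  paste0(aln$qname[pass], "/", aln$mate[pass])
}

read_keys <- function(x, mate = NULL) {
  id <- if (is.null(mate)) x$qname else x$id
  if (length(id) == 0) return(character(0))
  paste0(id, "/", if (is.null(mate)) x$mate else mate)
}

#' Subset an alignment table to the records kept by a filter
#'
#' @param aln an [mg_alignments] table.
#' @param kept keys returned by [filter_alignments()].
#' @return The kept subset of `aln` (mapped primary records only).
#' @export
filter_apply <- function(aln, kept) {
  out <- aln[paste0(aln$qname, "/", aln$mate) %in% kept & aln$mapped & aln$is_primary, ,
             drop = FALSE]
  class(out) <- c("mg_alignments", "data.frame")
  out
}

#' Screen reads against a reference database
#'
#' Maps reads with the internal mapper, applies the length/identity filter,
#' and partitions the input: in `remove` mode the retained output is the
#' reads NOT matching the database (e.g. host decontamination); in
#' `extract` mode it is the reads that match.
#'
#' @param reads an [mg_reads] object.
#' @param refs an [mg_refs] database (or a prebuilt [build_index()]).
#' @param params a [filter_params()] list.
#' @param mode `"remove"` or `"extract"`.
#' @param map_params a [map_params()] list for the internal mapper.
#' @return A list of class `screen_result`: `retained` and `matched`
#'   ([mg_reads], an exact disjoint partition of the input), `alignments`
#'   (all primary records), `kept_keys`, and `per_ref_counts` (data.frame of
#'   filtered read counts per reference).
#' @export
screen <- function(reads, refs, params = filter_params(),
                   mode = c("remove", "extract"), map_params = mgpipe::map_params()) {
  mode <- match.arg(mode)
  index <- if (inherits(refs, "seed_index")) refs else build_index(mg_refs(refs), map_params)
  aln <- map_reads(reads, index)
  kept <- filter_alignments(aln, params)
  matched_key <- read_keys(reads, reads$mate) %in% kept
  matched <- reads[matched_key, , drop = FALSE]
  retained <- reads[!matched_key, , drop = FALSE]
  if (mode == "extract") { tmp <- retained; retained <- matched; matched <- tmp }
  class(retained) <- class(matched) <- c("mg_reads", "data.frame")
  fa <- filter_apply(aln, kept)
  counts <- table(factor(fa$ref_id, levels = names(index$refs)))
  structure(list(retained = retained, matched = matched, alignments = aln,
                 kept_keys = kept, mode = mode,
                 per_ref_counts = data.frame(ref_id = names(counts),
                                             reads = as.integer(counts))),
            class = "screen_result")
}

#' @export
print.screen_result <- function(x, ...) {
  cat("<screen_result> mode=", x$mode, ": ", nrow(x$retained), " retained, ",
      nrow(x$matched), " matched\n", sep = "")
  invisible(x)
}

#' Screen reads against an adapter FASTA
#'
#' Flags a read when a local (Smith-Waterman; match +1, mismatch -1,
#' gap -2) alignment against any adapter sequence, either orientation,
#' reaches `min_score`.  The default of 16 corresponds to a ~16 bp
#' near-exact adapter match, the score a chance hit practically never
#' reaches on ~100 bp reads.
#'
#' @param reads an [mg_reads] object.
#' @param adapters an [mg_refs]/named character vector of adapter sequences.
#' @param min_score flagging threshold (default 16).
#' @return A list of class `adapter_screen_result`: `clean` and `flagged`
#'   ([mg_reads]) plus the per-read `scores`.
#' @export
screen_fastafile <- function(reads, adapters, min_score = 16L) {
  if (length(adapters) == 0) stop("empty adapter file")
  scores <- .mg_sw_best(reads$seq, as.character(unclass(adapters)), 1L, -1L, -2L)
  flag <- scores >= min_score
  clean <- reads[!flag, , drop = FALSE]; flagged <- reads[flag, , drop = FALSE]
  class(clean) <- class(flagged) <- c("mg_reads", "data.frame")
  structure(list(clean = clean, flagged = flagged, scores = scores),
            class = "adapter_screen_result")
}
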