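# Pileup-based assembly revision: consensus substitution and short-indel
# correction plus chimera splitting from insert-span coverage.  All event
# positions are 1-based coordinates on the INPUT scaftig; the event log is
# sufficient to reproduce the revised output from the input.

#' Revision parameters
#'
#' @param min_depth minimum pileup depth for any correction (default 3).
#' @param majority strict majority fraction in (0.5, 1\] a variant must
#'   exceed (default 0.5; ties keep the reference).
#' @param max_indel maximum corrected indel length in bp (default 10).
#' @param span_window bp of positive insert-span coverage required on both
#'   flanks of a candidate break region (default 100).
#' @param min_scaftig minimum scaftig length kept after revision (default 60).
#' @return A list of class `revision_params`.
#' @export
revision_params <- function(min_depth = 3L, majority = 0.5, max_indel = 10L,
                            span_window = 100L, min_scaftig = 60L) {
  stopifnot(majority >= 0.5, majority <= 1, max_indel >= 1, min_depth >= 1)
  structure(list(min_depth = as.integer(min_depth), majority = majority,
                 max_indel = as.integer(max_indel),
                 span_window = as.integer(span_window),
                 min_scaftig = as.integer(min_scaftig)),
            class = "revision_params")
}

#' Build a pileup over scaftigs
#'
#' Walks primary mapped alignments producing, per scaftig position: depth,
#' per-base counts, deletion observations (depth = base counts + deletions),
#' aggregated insertion observations (inserted sequence attached to the
#' position it follows), and insert-span coverage (number of proper pairs
#' whose outer span strictly contains the position).
#'
#' @param scaftigs an [mg_refs] object.
#' @param aln an [mg_alignments] table aligned to `scaftigs`.
#' @return A list of class `mg_pileup`: `scaftigs`, `base_counts` (list of
#'   L x 5 matrices, columns A/C/G/T/N), `deletion_obs`, `depth`,
#'   `insertions` (data.frame `scaftig_id`, `position`, `seq`, `count`),
#'   `span` (list of integer vectors), `paired` (logical).
#' @export
build_pileup <- function(scaftigs, aln) {
  scaftigs <- mg_refs(scaftigs)
  a <- aln[aln$mapped & aln$is_primary, , drop = FALSE]
  unknown <- setdiff(unique(a$ref_id), names(scaftigs))
  if (length(unknown))
    stop("alignments to unknown scaftig(s): ", paste(unknown, collapse = ", "))
  ref_i <- match(a$ref_id, names(scaftigs))
  seqs <- if (nrow(a)) aligned_query_seq(a) else character(0)
  pp <- .mg_pileup(ref_i, a$pos, a$cigar, seqs, nchar(scaftigs))
  depth <- lapply(seq_along(scaftigs), function(r)
    rowSums(pp$base_counts[[r]]) + pp$deletion_obs[[r]])
  span <- span_coverage(a, scaftigs)
  ins <- data.frame(scaftig_id = names(scaftigs)[pp$ins_ref_i],
                    position = pp$ins_pos, seq = as.character(pp$ins_seq),
                    count = pp$ins_count)
  structure(list(scaftigs = scaftigs,
                 base_counts = setNames(pp$base_counts, names(scaftigs)),
                 deletion_obs = setNames(pp$deletion_obs, names(scaftigs)),
                 depth = setNames(depth, names(scaftigs)),
                 insertions = ins,
                 span = span,
                 paired = any(aln$mate > 0L)),
            class = "mg_pileup")
}

# SEQ column for pileup: the query sequence in reference orientation.  The
# alignment table does not carry sequences, so callers pass reads through
# `aln$seq`; when absent we fall back to the reference (base-identical reads).
aligned_query_seq <- function(a) {
  if (!is.null(a$seq)) return(a$seq)
  stop("alignments must carry a 'seq' column (reference-oriented read bases) ",
       "to build a pileup; see align_with_seq()")
}

#' Attach reference-oriented read sequences to alignments
#'
#' Adds a `seq` column holding each read's bases in reference orientation
#' (reverse-complemented for minus-strand records), as required by
#' [build_pileup()].
#'
#' @param aln an [mg_alignments] table.
#' @param reads the [mg_reads] the alignments came from.
#' @return `aln` with a `seq` column.
#' @export
align_with_seq <- function(aln, reads) {
  key <- paste(reads$id, reads$mate)
  m <- match(paste(aln$qname, aln$mate), key)
  if (anyNA(m[aln$mapped])) stop("some alignments have no matching read")
  seq <- reads$seq[m]
  rc <- which(aln$mapped & aln$strand == "-")
  if (length(rc))
    seq[rc] <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq[rc])))
  aln$seq <- seq
  aln
}

span_coverage <- function(a, scaftigs) {
  span <- lapply(nchar(scaftigs), function(L) integer(L))
  names(span) <- names(scaftigs)
  p <- a[a$mate > 0L, , drop = FALSE]
  if (nrow(p) == 0) return(span)
  p$end <- alignment_end(p)
  one <- p[p$mate == 1L, , drop = FALSE]
  two <- p[p$mate == 2L, , drop = FALSE]
  m <- match(one$qname, two$qname)
  ok <- !is.na(m)
  one <- one[ok, , drop = FALSE]; two <- two[m[ok], , drop = FALSE]
  proper <- one$ref_id == two$ref_id & one$strand != two$strand
  one <- one[proper, , drop = FALSE]; two <- two[proper, , drop = FALSE]
  if (nrow(one) == 0) return(span)
  left <- pmin(one$pos, two$pos); right <- pmax(one$end, two$end)
  for (r in unique(one$ref_id)) {
    L <- nchar(scaftigs[[r]])
    sel <- one$ref_id == r
    # strict containment: positions left+1 .. right-1
    lo <- pmin(pmax(left[sel] + 1L, 1L), L + 1L)
    hi <- pmin(right[sel] - 1L, L)
    d <- integer(L + 1L)
    for (j in seq_along(lo)) if (lo[j] <= hi[j]) {
      d[lo[j]] <- d[lo[j]] + 1L
      d[hi[j] + 1L] <- d[hi[j] + 1L] - 1L
    }
    span[[r]] <- cumsum(d[seq_len(L)])
  }
  span
}

empty_events <- function()
  data.frame(kind = character(), scaftig_id = character(), position = integer(),
             before = character(), after = character(), support_for = integer(),
             depth = integer())

#' Consensus substitution correction
#'
#' At columns with depth at least `min_depth`, substitutes the reference
#' base when a different base holds a strict majority of the column.
#'
#' @param pileup a [build_pileup()] result.
#' @param params a [revision_params()] list.
#' @return A data.frame of substitution events (kind, scaftig_id, position,
#'   before, after, support_for, depth).
#' @export
consensus_correct <- function(pileup, params = revision_params()) {
  out <- list()
  bases <- c("A", "C", "G", "T")
  for (id in names(pileup$scaftigs)) {
    bc <- pileup$base_counts[[id]][, 1:4, drop = FALSE]
    depth <- pileup$depth[[id]]
    refb <- strsplit(pileup$scaftigs[[id]], "")[[1]]
    top_i <- max.col(bc, ties.method = "first")
    top_n <- bc[cbind(seq_len(nrow(bc)), top_i)]
    cand <- which(depth >= params$min_depth &
                    top_n / depth > params$majority &
                    bases[top_i] != refb)
    if (length(cand))
      out[[id]] <- data.frame(kind = "substitution", scaftig_id = id,
                              position = cand, before = refb[cand],
                              after = bases[top_i[cand]],
                              support_for = top_n[cand], depth = depth[cand])
  }
  if (length(out)) do.call(rbind, c(out, make.row.names = FALSE)) else empty_events()
}

#' Consensus short-indel correction
#'
#' Inserts a sequence after a position when the insertion is observed in a
#' strict majority of the reads at that column (and is at most `max_indel`
#' bp); deletes a position when a strict majority of its column consists of
#' deletion observations.
#'
#' @inheritParams consensus_correct
#' @return A data.frame of insertion/deletion events.
#' @export
indel_correct <- function(pileup, params = revision_params()) {
  out <- list()
  ins <- pileup$insertions
  if (nrow(ins)) {
    depth <- mapply(function(id, p) pileup$depth[[id]][p], ins$scaftig_id, ins$position)
    ok <- depth >= params$min_depth & ins$count / depth > params$majority &
      nchar(ins$seq) <= params$max_indel
    if (any(ok))
      out$ins <- data.frame(kind = "insertion", scaftig_id = ins$scaftig_id[ok],
                            position = ins$position[ok], before = "",
                            after = ins$seq[ok], support_for = ins$count[ok],
                            depth = as.integer(depth[ok]))
  }
  for (id in names(pileup$scaftigs)) {
    del <- pileup$deletion_obs[[id]]
    depth <- pileup$depth[[id]]
    cand <- which(depth >= params$min_depth & del / depth > params$majority)
    if (length(cand)) {
      refb <- strsplit(pileup$scaftigs[[id]], "")[[1]]
      out[[paste0("del_", id)]] <-
        data.frame(kind = "deletion", scaftig_id = id, position = cand,
                   before = refb[cand], after = "", support_for = del[cand],
                   depth = depth[cand])
    }
  }
  if (length(out)) do.call(rbind, c(out, make.row.names = FALSE)) else empty_events()
}

#' Detect chimeric break regions and unsupported ends
#'
#' Chimeric junctions leave no read pair spanning them: a break region is a
#' maximal internal run of zero insert-span coverage flanked on both sides
#' by at least `span_window` bp of positive span coverage.  Zero-depth
#' positions inside a break region are removed; otherwise the scaftig is
#' split at the region's minimum-depth position (leftmost on ties).
#' Terminal zero-depth runs are trimmed (`end_trim`).  Requires paired-end
#' data; with single-end input the operation is a no-op with a warning.
#'
#' @inheritParams consensus_correct
#' @return A data.frame of split/end_trim events.  For `split` events with a
#'   removed interval, `before` holds the removed sequence starting at
#'   `position`; a pure split has empty `before` and cuts after `position`.
#' @export
detect_breakpoints <- function(pileup, params = revision_params()) {
  if (!pileup$paired) {
    warning("single-end data: breakpoint detection skipped")
    return(empty_events())
  }
  out <- list()
  for (id in names(pileup$scaftigs)) {
    d <- pileup$depth[[id]]
    s <- pileup$span[[id]]
    L <- length(d)
    seqc <- pileup$scaftigs[[id]]
    ev <- list()
    # terminal zero-depth runs
    lead <- if (d[1] == 0) rle(d == 0)$lengths[1] else 0L
    trail <- if (d[L] == 0) tail(rle(d == 0)$lengths, 1) else 0L
    if (lead > 0 && lead < L)
      ev[[length(ev) + 1L]] <- data.frame(kind = "end_trim", scaftig_id = id,
                                          position = 1L,
                                          before = substr(seqc, 1, lead),
                                          after = "", support_for = 0L,
                                          depth = 0L)
    if (trail > 0 && trail < L)
      ev[[length(ev) + 1L]] <- data.frame(kind = "end_trim", scaftig_id = id,
                                          position = L - trail + 1L,
                                          before = substr(seqc, L - trail + 1L, L),
                                          after = "", support_for = 0L,
                                          depth = 0L)
    # internal zero-span regions with span-positive flanks
    r <- rle(s == 0)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    w <- params$span_window
    for (j in which(r$values)) {
      a <- starts[j]; b <- ends[j]
      if (a - w < 1L || b + w > L) next
      if (any(s[(a - w):(a - 1L)] == 0L) || any(s[(b + 1L):(b + w)] == 0L)) next
      dz <- which(d[a:b] == 0L)
      if (length(dz)) {
        ra <- a + min(dz) - 1L; rb <- a + max(dz) - 1L
        ev[[length(ev) + 1L]] <- data.frame(kind = "split", scaftig_id = id,
                                            position = ra,
                                            before = substr(seqc, ra, rb),
                                            after = "", support_for = 0L,
                                            depth = 0L)
      } else {
        cut <- a + which.min(d[a:b]) - 1L
        ev[[length(ev) + 1L]] <- data.frame(kind = "split", scaftig_id = id,
                                            position = cut, before = "",
                                            after = "", support_for = 0L,
                                            depth = as.integer(d[cut]))
      }
    }
    if (length(ev)) out[[id]] <- do.call(rbind, ev)
  }
  if (length(out)) do.call(rbind, c(out, make.row.names = FALSE)) else empty_events()
}

#' Apply a revision event log to scaftigs
#'
#' Replays substitution, insertion, deletion, split and end-trim events
#' (positions on the input scaftigs) and applies the minimum-length filter.
#' [revise_assembly()] uses this same replay, so applying its logged events
#' to its input reproduces its output exactly.
#'
#' @param scaftigs an [mg_refs] object.
#' @param events an event data.frame (see [revise_assembly()]).
#' @param min_scaftig minimum piece length kept.
#' @return A list: `scaftigs` (revised [mg_refs]) and `dropped`
#'   (data.frame of pieces removed by the length filter).
#' @export
replay_events <- function(scaftigs, events, min_scaftig = 60L) {
  out_ids <- character(0); out_seq <- character(0)
  dropped <- list()
  for (id in names(scaftigs)) {
    s <- scaftigs[[id]]
    L <- nchar(s)
    ev <- events[events$scaftig_id == id, , drop = FALSE]
    # removed intervals from end trims and interval-removing splits
    rm_iv <- matrix(integer(0), ncol = 2)
    cuts <- integer(0)  # piece boundary after this position
    for (k in seq_len(nrow(ev))) {
      e <- ev[k, ]
      if (e$kind == "end_trim") {
        rm_iv <- rbind(rm_iv, c(e$position, e$position + nchar(e$before) - 1L))
      } else if (e$kind == "split") {
        if (nzchar(e$before)) {
          rm_iv <- rbind(rm_iv, c(e$position, e$position + nchar(e$before) - 1L))
          cuts <- c(cuts, e$position - 1L)
        } else cuts <- c(cuts, e$position)
      }
    }
    # kept intervals of [1, L]
    keep <- rep(TRUE, L)
    if (nrow(rm_iv)) for (k in seq_len(nrow(rm_iv)))
      keep[rm_iv[k, 1]:rm_iv[k, 2]] <- FALSE
    boundary <- rep(FALSE, L)
    boundary[cuts[cuts >= 1 & cuts <= L]] <- TRUE
    # piece = maximal kept run, further divided at cut positions
    pieces <- list()
    p <- 1L
    while (p <= L) {
      if (!keep[p]) { p <- p + 1L; next }
      q <- p
      while (q < L && keep[q + 1L] && !boundary[q]) q <- q + 1L
      pieces[[length(pieces) + 1L]] <- c(p, q)
      p <- q + 1L
    }
    subs <- ev[ev$kind == "substitution", , drop = FALSE]
    inss <- ev[ev$kind == "insertion", , drop = FALSE]
    dels <- ev[ev$kind == "deletion", , drop = FALSE]
    piece_seqs <- vapply(pieces, function(iv) {
      ps <- substr(s, iv[1], iv[2])
      off <- iv[1] - 1L
      sub_in <- subs[subs$position >= iv[1] & subs$position <= iv[2], , drop = FALSE]
      for (k in seq_len(nrow(sub_in)))
        substr(ps, sub_in$position[k] - off, sub_in$position[k] - off) <- sub_in$after[k]
      indel_in <- rbind(inss[inss$position >= iv[1] & inss$position <= iv[2], , drop = FALSE],
                        dels[dels$position >= iv[1] & dels$position <= iv[2], , drop = FALSE])
      if (nrow(indel_in)) {
        indel_in <- indel_in[order(-indel_in$position), , drop = FALSE]
        for (k in seq_len(nrow(indel_in))) {
          p0 <- indel_in$position[k] - off
          if (indel_in$kind[k] == "insertion")
            ps <- paste0(substr(ps, 1, p0), indel_in$after[k],
                         substr(ps, p0 + 1L, nchar(ps)))
          else
            ps <- paste0(substr(ps, 1, p0 - 1L), substr(ps, p0 + 1L, nchar(ps)))
        }
      }
      ps
    }, "")
    n_pieces <- length(pieces)
    ids <- if (n_pieces == 1L) id else paste0(id, "_", seq_len(n_pieces))
    long <- nchar(piece_seqs) >= min_scaftig
    if (any(!long))
      dropped[[id]] <- data.frame(scaftig_id = ids[!long],
                                  length = nchar(piece_seqs)[!long])
    out_ids <- c(out_ids, ids[long])
    out_seq <- c(out_seq, piece_seqs[long])
  }
  list(scaftigs = mg_refs(setNames(out_seq, out_ids)),
       dropped = if (length(dropped)) do.call(rbind, c(dropped, make.row.names = FALSE))
                 else data.frame(scaftig_id = character(), length = integer()))
}

#' Revise an assembly from read alignments
#'
#' Builds a pileup, applies consensus substitution correction, short-indel
#' correction and breakpoint detection (in that order, one pass), replays
#' the resulting event log on the input scaftigs and re-applies the
#' minimum-length filter.  Revising an assembly that perfectly matches its
#' reads is a fixed point: no events, output identical to input.
#'
#' @param scaftigs an [mg_refs] object.
#' @param aln an [mg_alignments] table with a `seq` column (see
#'   [align_with_seq()]), typically pre-filtered with [filter_alignments()].
#' @param params a [revision_params()] list.
#' @return A list of class `revision_result`: `scaftigs` (revised),
#'   `events` (the full log), `dropped` (length-filtered pieces) and
#'   `stats` (event counts by kind).
#' @export
revise_assembly <- function(scaftigs, aln, params = revision_params()) {
  pileup <- build_pileup(scaftigs, aln)
  events <- rbind(consensus_correct(pileup, params),
                  indel_correct(pileup, params),
                  detect_breakpoints(pileup, params))
  rp <- replay_events(mg_refs(scaftigs), events, params$min_scaftig)
  stats <- as.list(table(factor(events$kind,
                                levels = c("substitution", "insertion", "deletion",
                                           "split", "end_trim"))))
  stats$dropped <- nrow(rp$dropped)
  structure(list(scaftigs = rp$scaftigs, events = events, dropped = rp$dropped,
                 stats = stats),
            class = "revision_result")
}

#' @export
print.revision_result <- function(x, ...) {
  cat("<revision_result> ", length(x$scaftigs), " scaftigs out; events: ",
      paste(names(x$stats), unlist(x$stats), sep = "=", collapse = ", "), "\n",
      sep = "")
  invisible(x)
}
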