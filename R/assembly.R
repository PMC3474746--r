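# Run-time assembly parameter estimation, scaftig extraction and assembly
# statistics.  The assembler itself is external; this module computes the
# parameters it needs and post-processes its output.

#' Estimate the assembly k-mer size from the average read length
#'
#' The smallest odd integer `k` with `k >= avg_read_length / 2`.
#'
#' @param avg_read_length mean high-quality read length in bp (>= 2).
#' @return An odd integer.
#' @examples
#' estimate_kmer(44)   # 23
#' estimate_kmer(100)  # 51
#' @export
estimate_kmer <- function(avg_read_length) {
  stopifnot(avg_read_length >= 2)
  k <- as.integer(ceiling(avg_read_length / 2))
  if (k %% 2L == 0L) k <- k + 1L
  k
}

#' Estimate the library insert size from proper pairs
#'
#' A proper pair has both mates mapped to the same reference on opposite
#' strands.  The outer distance is the span from the leftmost to the
#' rightmost mapped base of the pair, inclusive.  The location estimate is
#' the median and the spread the (raw, unscaled) median absolute deviation
#' -- both robust to chimeric or mis-mapped pairs.
#'
#' @param aln an [mg_alignments] table with paired records (e.g. from
#'   [map_reads()]).
#' @param min_pairs minimum number of proper pairs required (default 100).
#' @return A list of class `insert_size_estimate`: `median`, `mad`,
#'   `n_pairs`, and the vector of `outer_distances`.
#' @export
estimate_insert_size <- function(aln, min_pairs = 100L) {
  d <- outer_distances(aln)
  if (length(d) < min_pairs)
    stop("insufficient pairs: ", length(d), " proper pairs < ", min_pairs)
  structure(list(median = median(d), mad = mad(d, constant = 1),
                 n_pairs = length(d), outer_distances = d),
            class = "insert_size_estimate")
}

#' @export
print.insert_size_estimate <- function(x, ...) {
  cat("<insert_size_estimate> median ", x$median, " bp (MAD ", x$mad, ", n=",
      x$n_pairs, " pairs)\n", sep = "")
  invisible(x)
}

outer_distances <- function(aln) {
  a <- aln[aln$mapped & aln$is_primary & aln$mate > 0L, , drop = FALSE]
  if (nrow(a) == 0) return(numeric(0))
  a$end <- alignment_end(a)
  one <- a[a$mate == 1L, , drop = FALSE]
  two <- a[a$mate == 2L, , drop = FALSE]
  m <- match(one$qname, two$qname)
  ok <- !is.na(m)
  one <- one[ok, , drop = FALSE]; two <- two[m[ok], , drop = FALSE]
  proper <- one$ref_id == two$ref_id & one$strand != two$strand
  one <- one[proper, , drop = FALSE]; two <- two[proper, , drop = FALSE]
  pmax(one$end, two$end) - pmin(one$pos, two$pos) + 1
}

#' Assembly preparation summary
#'
#' Bundles the run-time assembly parameters: average high-quality read
#' length, the estimated k-mer, and the insert-size estimate obtained by
#' mapping a sample of pairs to a reference (marker genes, draft contigs, or
#' any FASTA).
#'
#' @param reads an [mg_reads] object of high-quality reads.
#' @param aln paired alignments for insert estimation, or `NULL` to skip.
#' @param min_pairs passed to [estimate_insert_size()].
#' @return A list of class `assembly_prep`: `avg_read_length`, `kmer`,
#'   `insert_size_estimate`, `insert_size_spread`.
#' @export
assembly_prep <- function(reads, aln = NULL, min_pairs = 100L) {
  avg <- mean(read_lengths(reads))
  est <- if (!is.null(aln)) estimate_insert_size(aln, min_pairs) else NULL
  structure(list(avg_read_length = avg, kmer = estimate_kmer(avg),
                 insert_size_estimate = if (is.null(est)) NA_real_ else est$median,
                 insert_size_spread = if (is.null(est)) NA_real_ else est$mad),
            class = "assembly_prep")
}

#' Extract scaftigs from scaffolds
#'
#' Splits every scaffold at each maximal run of one or more `N`s and keeps
#' the resulting N-free pieces of at least `min_length` bp, in order, with
#' ids `<scaffold>_1`, `<scaffold>_2`, ...
#'
#' @param scaffolds an [mg_refs] object (sequences may contain N).
#' @param min_length minimum scaftig length in bp (default 60).
#' @return An [mg_refs] object of scaftigs, with attribute `source` (a
#'   data.frame mapping each scaftig to its scaffold interval).
#' @export
extract_scaftigs <- function(scaffolds, min_length = 60L) {
  out <- character(0); ids <- character(0)
  src <- list()
  for (i in seq_along(scaffolds)) {
    s <- scaffolds[[i]]
    sc_id <- names(scaffolds)[i]
    n_pos <- gregexpr("N+", s)[[1]]
    if (n_pos[1] == -1) {
      starts <- 1L; ends <- nchar(s)
    } else {
      nl <- attr(n_pos, "match.length")
      starts <- c(1L, n_pos + nl)
      ends <- c(n_pos - 1L, nchar(s))
    }
    w <- ends - starts + 1L
    keep <- w >= 1L
    starts <- starts[keep]; ends <- ends[keep]
    pieces <- substring(s, starts, ends)
    long <- nchar(pieces) >= min_length
    if (!any(long)) next
    serial <- seq_len(sum(long))
    ids <- c(ids, paste0(sc_id, "_", serial))
    out <- c(out, pieces[long])
    src[[length(src) + 1L]] <- data.frame(scaffold = sc_id,
                                          start = starts[long], end = ends[long])
  }
  res <- mg_refs(setNames(out, ids))
  attr(res, "source") <- if (length(src)) do.call(rbind, src) else
    data.frame(scaffold = character(), start = integer(), end = integer())
  res
}

#' Assembly statistics
#'
#' @param scaftigs an [mg_refs] object with at least one sequence.
#' @return List with `count`, `total_bp`, `max_len`, `mean_len` and `N50`
#'   (the length of the shortest piece in the smallest set of longest
#'   pieces covering at least half of `total_bp`).
#' @export
assembly_stats <- function(scaftigs) {
  if (length(scaftigs) == 0) stop("no scaftigs")
  len <- sort(nchar(scaftigs), decreasing = TRUE)
  total <- sum(len)
  n50 <- len[which(cumsum(len) >= total / 2)[1]]
  list(count = length(len), total_bp = total, max_len = len[1],
       mean_len = mean(len), N50 = as.integer(n50))
}
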